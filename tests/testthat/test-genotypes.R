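writePedMap <- function(pedLines, mapLines) {
  pedF <- tempfile(fileext = ".ped")
  mapF <- tempfile(fileext = ".map")
  writeLines(pedLines, pedF)
  writeLines(mapLines, mapF)
  list(ped = pedF, map = mapF)
}

test_that("PED/MAP parsing recodes to counted-allele dosages", {
  f <- writePedMap(
    c("fam1 i1 0 0 2 -9 A A A B",
      "fam1 i2 0 0 2 -9 A B B B"),
    c("1 snp1 0 100", "1 snp2 0 200"))
  p <- readGenotypes(f$ped, "ped_map", mapPath = f$map)
  # snp1: B is minor (1 of 4) -> dosages 0,1 ; snp2: A minor -> 1,0
  expect_equal(unname(dosages(p)), matrix(c(0, 1, 1, 0), 2))
  expect_equal(individualIds(p), c("i1", "i2"))

  # missing genotype code "0 0"
  f2 <- writePedMap(c("f i1 0 0 1 -9 0 0", "f i2 0 0 1 -9 A B"),
                    c("1 s1 0 1"))
  expect_true(is.na(dosages(readGenotypes(f2$ped, "ped_map",
                                          mapPath = f2$map))[1, 1]))

  # a third allele is an error
  f3 <- writePedMap(c("f i1 0 0 1 -9 A C", "f i2 0 0 1 -9 A B"),
                    c("1 s1 0 1"))
  expect_error(readGenotypes(f3$ped, "ped_map", mapPath = f3$map),
               "more than two alleles")
})

test_that("dosage matrix CSV round-trips exactly", {
  set.seed(4)
  dos <- matrix(sample(c(0:2, NA), 30, replace = TRUE), 5, 6)
  p <- genotypePanel(dos, paste0("c", 1:5), paste0("m", 1:6))
  f <- tempfile(fileext = ".csv")
  writeGenotypes(p, f)
  p2 <- readGenotypes(f, "dosage_matrix")
  expect_equal(dosages(p2), dosages(p))
  expect_equal(locusIds(p2), locusIds(p))
})

test_that("Hardy-Weinberg chi-square behaves at the reference points", {
  expect_equal(hweTest(25, 50, 25), 1)           # exact HWE proportions
  expect_lt(hweTest(50, 0, 50), 1e-22)           # chi-square 100
  expect_equal(hweTest(10, 0, 0), 1)             # monomorphic convention
  # chi-square value check: (50,0,50) expected (25,50,25)
  chi2 <- sum((c(50, 0, 50) - c(25, 50, 25))^2 / c(25, 50, 25))
  expect_equal(chi2, 100)
  expect_equal(hweTest(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
})

test_that("QC filters match a brute-force per-rule enumeration", {
  # 10 individuals x 5 SNPs, constructed cases:
  #  snp1 MAF 0.04-ish? use exact boundary checks below; here a mixed panel
  set.seed(11)
  dos <- matrix(rbinom(50, 2, 0.4), 10, 5)
  dos[1, 1:3] <- NA                 # individual 1 call rate 0.4 -> removed
  dos[, 2] <- c(rep(0, 9), 2)       # MAF 0.1 among 9 retained: boundary-ish
  dos[, 3] <- c(0, rep(c(0, 2), length.out = 9))  # HWE-hostile
  dos[2:6, 4] <- NA                 # snp4 call rate 0.44 among retained
  p <- genotypePanel(dos)
  res <- qcFilter(p, mafMin = 0.05, snpCallMin = 0.90, indCallMin = 0.90,
                  hweAlpha = 1e-4)
  # independent enumeration of the same rules, same order
  keepInd <- rowMeans(!is.na(dos)) >= 0.90
  d <- dos[keepInd, ]
  keepSnp <- colMeans(!is.na(d)) >= 0.90
  d <- d[, keepSnp, drop = FALSE]
  maf <- pmin(colMeans(d, na.rm = TRUE) / 2, 1 - colMeans(d, na.rm = TRUE) / 2)
  d <- d[, maf >= 0.05, drop = FALSE]
  hwe <- apply(d, 2, function(g)
    hweTest(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
            sum(g == 2, na.rm = TRUE)))
  d <- d[, hwe >= 1e-4, drop = FALSE]
  expect_equal(unname(dosages(res$panel)), unname(d))
  expect_equal(sum(res$report$removed),
               nrow(dos) - nrow(d) + ncol(dos) - ncol(d))

  # idempotence
  res2 <- qcFilter(res$panel)
  expect_equal(dosages(res2$panel), dosages(res$panel))
})

test_that("QC thresholds are boundary-exact", {
  # 50 individuals: MAF 0.04 removed, 0.06 kept
  n <- 50
  dos <- cbind(snpA = c(rep(1, 4), rep(0, 46)),   # MAF 4/100 = 0.04
               snpB = c(rep(1, 6), rep(0, 44)),   # MAF 0.06
               snpC = rbinom(n, 2, 0.5))
  p <- genotypePanel(dos)
  kept <- locusIds(qcFilter(p, hweAlpha = 0)$panel)
  expect_false("snpA" %in% kept)
  expect_true("snpB" %in% kept)

  # individual call rate 0.85 removed, 0.95 kept (20 loci)
  dos2 <- matrix(rbinom(20 * 20, 2, 0.5), 20, 20)
  dos2[1, 1:3] <- NA   # 0.85
  dos2[2, 1] <- NA     # 0.95
  res <- qcFilter(genotypePanel(dos2, paste0("i", 1:20)), mafMin = 0,
                  snpCallMin = 0, hweAlpha = 0)
  expect_false("i1" %in% individualIds(res$panel))
  expect_true("i2" %in% individualIds(res$panel))
})

test_that("VanRaden G matches hand computation and basic invariants", {
  p <- genotypePanel(matrix(c(0, 2, 2, 0), 2, 2), c("a", "b"), c("s1", "s2"))
  expect_equal(unname(relValues(buildG(p))),
               matrix(c(2, -2, -2, 2), 2))

  # identical genotypes everywhere -> all entries of G equal
  same <- genotypePanel(matrix(rep(c(0, 1, 2, 1), each = 3), 3, 4))
  expect_error(relValues(buildG(same)), NA)
  Gs <- relValues(buildG(same))
  expect_equal(max(Gs) - min(Gs), 0)

  # permutation equivariance
  set.seed(2)
  dos <- matrix(rbinom(200, 2, 0.3), 10, 20)
  ids <- paste0("x", 1:10)
  G1 <- relValues(buildG(genotypePanel(dos, ids)))
  perm <- sample(10)
  G2 <- relValues(buildG(genotypePanel(dos[perm, ], ids[perm])))
  expect_equal(G2[ids, ids], G1[ids, ids])

  # PSD up to tolerance, and mean(diag) -> 1 under HWE with many loci
  pan <- simulatePanel(200, 5000, c(0.05, 0.95), seed = 17)
  G <- relValues(buildG(pan))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)

  # all-monomorphic panel has a zero denominator
  expect_error(buildG(genotypePanel(matrix(2, 4, 3))), "monomorphic")
})

test_that("missing dosages are mean-imputed before centering", {
  dos <- matrix(c(0, 2, NA, 2, 0, 1), 3, 2)
  G <- relValues(buildG(genotypePanel(dos)))
  # imputed entry contributes zero to Z: row 3 locus 1 centered to 0
  pj <- c(mean(c(0, 2)) / 2, mean(c(2, 0, 1)) / 2)
  Z <- cbind(c(0, 2, 2 * pj[1]) - 2 * pj[1], c(2, 0, 1) - 2 * pj[2])
  expect_equal(unname(G), unname(tcrossprod(Z) / (2 * sum(pj * (1 - pj)))))
})
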