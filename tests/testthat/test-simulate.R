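smallCfg <- function(...) {
  defaults <- list(nFounders = 50, nGenerations = 2, nOffspringPerGen = 100,
                   nSnps = 150, nQtl = 50, nHerds = 4, nSiresPerGen = 6,
                   genotypedFraction = 0.25, importedSireFraction = 0,
                   parentMissingRate = 0, seed = 42)
  do.call(simConfig, utils::modifyList(defaults, list(...)))
}

test_that("one seed drives all randomness: identical configs, identical data", {
  cfg <- smallCfg()
  a <- simulatePopulation(cfg)
  b <- simulatePopulation(cfg)
  expect_identical(pedigree(a$ped), pedigree(b$ped))
  expect_identical(dosages(a$panel), dosages(b$panel))
  expect_identical(a$trueBv, b$trueBv)
  expect_identical(simulatePhenotypes(a, cfg), simulatePhenotypes(b, cfg))
  # a different seed changes the data
  c2 <- simulatePopulation(smallCfg(seed = 43))
  expect_false(identical(a$trueBv, c2$trueBv))
})

test_that("founder breeding-value variance hits the target", {
  cfg <- simConfig(nFounders = 2000, nGenerations = 1, nOffspringPerGen = 50,
                   nSnps = 400, nQtl = 150, importedSireFraction = 0,
                   parentMissingRate = 0, seed = 7)
  pop <- simulatePopulation(cfg)
  founders <- pedigree(pop$ped)$animal[pedigree(pop$ped)$sire_code == 0]
  v <- var(pop$trueBv[founders])
  expect_lt(abs(v - cfg@sigma2a) / cfg@sigma2a, 0.05)
})

test_that("purely polygenic architecture leaves markers uninformative", {
  cfg <- smallCfg(nQtl = 0, markerFraction = 0)
  pop <- simulatePopulation(cfg)
  dos <- dosages(pop$panel)
  cc <- abs(cor(pop$trueBv[individualIds(pop$panel)], dos[, 1:50]))
  expect_lt(mean(cc, na.rm = TRUE), 0.15)
})

test_that("realized heritability matches the target via dam-offspring regression", {
  cfg <- simConfig(nFounders = 3000, nGenerations = 1,
                   nOffspringPerGen = 10000, nSnps = 2, nQtl = 0,
                   markerFraction = 0, recordsPerCow = 1,
                   importedSireFraction = 0, parentMissingRate = 0, seed = 8)
  pop <- simulatePopulation(cfg)
  ph <- simulatePhenotypes(pop, cfg, fixedEffects = FALSE)
  y <- setNames(ph$milk_kg, ph$cow)
  p <- pedigree(pop$ped)
  off <- p[p$dam_code > 0, ]
  ok <- off$animal %in% names(y) & off$dam %in% names(y)
  slope <- coef(lm(y[off$animal[ok]] ~ y[off$dam[ok]]))[2]
  h2 <- cfg@sigma2a / (cfg@sigma2a + cfg@sigma2pe + cfg@sigma2e)
  expect_lt(abs(2 * slope - h2), 0.03)
})

test_that("repeated records correlate at the repeatability", {
  cfg <- simConfig(nFounders = 2000, nGenerations = 1, nOffspringPerGen = 2000,
                   nSnps = 2, nQtl = 0, markerFraction = 0, recordsPerCow = 3,
                   importedSireFraction = 0, parentMissingRate = 0, seed = 9)
  pop <- simulatePopulation(cfg)
  ph <- simulatePhenotypes(pop, cfg, fixedEffects = FALSE)
  p1 <- ph[ph$parity == 1, c("cow", "milk_kg")]
  p2 <- ph[ph$parity == 2, c("cow", "milk_kg")]
  both <- merge(p1, p2, by = "cow")
  rep_target <- (cfg@sigma2a + cfg@sigma2pe) /
    (cfg@sigma2a + cfg@sigma2pe + cfg@sigma2e)
  expect_lt(abs(cor(both$milk_kg.x, both$milk_kg.y) - rep_target), 0.05)
})

test_that("generated records pass the standard edits untouched", {
  cfg <- smallCfg()
  pop <- simulatePopulation(cfg)
  ph <- simulatePhenotypes(pop, cfg)
  res <- editLactations(ph)
  expect_equal(sum(res$report$removed), 0L)
  expect_equal(nrow(res$data), nrow(ph))
})

test_that("panel allele frequencies reflect the drawing distribution", {
  cfg <- smallCfg(nFounders = 400, nSnps = 500, genotypedFraction = 0.5)
  pop <- simulatePopulation(cfg)
  f <- alleleFreqs(pop$panel)
  expect_lt(abs(mean(f) - mean(cfg@mafRange)), 0.03)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("true accuracy is a guarded correlation against simulated truth", {
  bv <- setNames(rnorm(2000), paste0("a", 1:2000))
  expect_equal(trueAccuracy(bv, bv), 1)
  set.seed(1)
  noise <- setNames(rnorm(2000), names(bv))
  expect_lt(abs(trueAccuracy(noise, bv)), 0.1)
  expect_error(trueAccuracy(bv[1:2], bv), "3 animals")
  expect_error(trueAccuracy(setNames(1:5, paste0("x", 1:5)), bv), "covered")
})

test_that("simulator output round-trips through the file readers", {
  cfg <- smallCfg()
  pop <- simulatePopulation(cfg)
  pf <- tempfile(fileext = ".csv")
  writePedigree(pop$ped, pf)
  ped2 <- readPedigree(pf)
  o1 <- pedigree(pop$ped)[, c("animal", "sire", "dam")]
  o2 <- pedigree(ped2)[, c("animal", "sire", "dam")]
  expect_equal(o2[order(o2$animal), ], o1[order(o1$animal), ],
               ignore_attr = TRUE)

  pedF <- tempfile(fileext = ".ped"); mapF <- tempfile(fileext = ".map")
  writePedMap(pop$panel, pedF, mapF)
  counted <- setNames(rep("A", length(locusIds(pop$panel))),
                      locusIds(pop$panel))
  p2 <- readGenotypes(pedF, "ped_map", mapPath = mapF,
                      countedAlleles = counted)
  expect_equal(dosages(p2), dosages(pop$panel))
})
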