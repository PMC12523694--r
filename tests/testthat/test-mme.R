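library(Matrix)

# dense generalized-least-squares oracle for the equivalent model:
# y ~ N(Xb, ZKZ's2a + WW's2pe + I s2e); BLUP via V-inverse projections
glsOracle <- function(design, K, spec) {
  X <- as.matrix(design@X); Z <- as.matrix(design@Z); W <- as.matrix(design@W)
  y <- design@y
  V <- Z %*% K %*% t(Z) * spec@sigma2a + tcrossprod(W) * spec@sigma2pe +
    diag(length(y)) * spec@sigma2e
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  a <- spec@sigma2a * K %*% t(Z) %*% Vi %*% r
  pe <- spec@sigma2pe * t(W) %*% Vi %*% r
  list(b = as.numeric(b), a = setNames(as.numeric(a), design@animalIds),
       pe = as.numeric(pe))
}

toyDesign <- function(seed = 1, nRec = 24, nAn = 14) {
  set.seed(seed)
  ped <- randomPedigree(nAn, seed = seed)
  ids <- pedigree(ped)$animal
  cows <- sample(ids, 8)
  rec <- data.frame(cow = sample(cows, nRec, replace = TRUE))
  rec$cg_id <- sample(c("g1", "g2", "g3"), nRec, replace = TRUE)
  rec$parity <- sample(1:2, nRec, replace = TRUE)
  rec$age_months <- ifelse(rec$parity == 1, sample(20:40, nRec, TRUE),
                           sample(30:50, nRec, TRUE))
  rec$milk_kg <- rnorm(nRec, 20, 4)
  list(ped = ped, rec = rec,
       design = buildDesign(rec, ped, modelSpec(2, 1.5, 4)))
}

test_that("design matrices cross-tabulate records correctly", {
  t <- toyDesign(3)
  d <- t$design
  # Z rows sum to one and point at the record's cow
  expect_true(all(Matrix::rowSums(d@Z) == 1))
  expect_equal(ncol(d@Z), nAnimals(t$ped))
  # repeated records of one cow share a Z column and a W column
  cowTab <- table(t$rec$cow)
  rc <- names(cowTab)[which.max(cowTab)]
  rows <- which(t$rec$cow == rc)
  zc <- apply(as.matrix(d@Z[rows, , drop = FALSE]), 1, which.max)
  expect_equal(length(unique(zc)), 1L)
  # X'X diagonal equals hand-counted cross-tabulation for CG contrasts
  XtX <- as.matrix(crossprod(d@X))
  cgCounts <- table(t$rec$cg_id)
  expect_equal(unname(diag(XtX)[grep("^cg", d@fixedNames)]),
               unname(c(cgCounts[-1])))
  # one CG level only -> confounded error
  rec1 <- t$rec; rec1$cg_id <- "g1"
  expect_error(buildDesign(rec1, t$ped, modelSpec()), "confounded")
})

test_that("a fixed-mean-only model returns the sample mean", {
  y <- c(3, 5, 10)
  d <- new("DesignSet", X = Matrix(1, 3, 1), Z = Matrix(0, 3, 0),
           W = Matrix(0, 3, 0), y = y, animalIds = character(0),
           peIds = character(0), fixedNames = "mu")
  fit <- solveMME(d, spec = modelSpec())
  expect_equal(fit@fixed$solution, mean(y))
})

test_that("MME solutions match the dense GLS oracle", {
  for (seed in c(2, 5)) {
    t <- toyDesign(seed)
    spec <- modelSpec(2, 1.5, 4)
    Ai <- buildAInverse(t$ped)
    fit <- solveMME(t$design, Ai, spec)
    or <- glsOracle(t$design, as.matrix(relValues(buildA(t$ped))), spec)
    expect_lt(max(abs(ebv(fit) - or$a)), 1e-8)
    expect_lt(max(abs(fit@fixed$solution - or$b)), 1e-8)
    expect_lt(max(abs(fit@pe - or$pe)), 1e-8)
  }
})

test_that("adding a constant to phenotypes leaves EBVs unchanged", {
  t <- toyDesign(7)
  spec <- modelSpec(2, 1.5, 4)
  Ai <- buildAInverse(t$ped)
  f1 <- solveMME(t$design, Ai, spec)
  d2 <- t$design
  d2@y <- d2@y + 100
  f2 <- solveMME(d2, Ai, spec)
  expect_lt(max(abs(ebv(f1) - ebv(f2))), 1e-8)
})

test_that("ssGBLUP with Gb = A22 reproduces ABLUP solutions", {
  t <- toyDesign(9)
  spec <- modelSpec(2, 1.5, 4)
  Ai <- buildAInverse(t$ped)
  A <- buildA(t$ped)
  gid <- sample(relIndex(A), 6)
  sub <- extractA22(A, gid)
  Gbinv <- new("RelationshipMatrix", values = relValues(sub$A22inv),
               index = gid, role = "G_blended_inverse")
  Hi <- assembleHInverse(Ai, sub$A22inv, Gbinv)
  fa <- solveMME(t$design, Ai, spec)
  fh <- solveMME(t$design, Hi, spec)
  expect_lt(max(abs(ebv(fa) - ebv(fh))), 1e-8)
})

test_that("PCG agrees with the direct solver", {
  t <- toyDesign(11)
  spec <- modelSpec(2, 1.5, 4)
  Ai <- buildAInverse(t$ped)
  fd <- solveMME(t$design, Ai, spec, method = "direct")
  fp <- solveMME(t$design, Ai, spec, method = "pcg")
  expect_lt(max(abs(ebv(fd) - ebv(fp))), 1e-6)
  expect_error(solveMME(t$design, Ai, spec, method = "pcg",
                        computePev = TRUE), "direct")
})

test_that("PEV-based accuracy follows its closed form", {
  expect_equal(individualAccuracy(0, 0, 2), 1)
  expect_equal(individualAccuracy(2, 0, 2), 0)
  expect_equal(individualAccuracy(0.36 * 2, 0, 2), 0.8)
  expect_equal(individualAccuracy(1.25, 0.25, 1), sqrt(1 - 1.25 / 1.25) + 0)
  expect_error(individualAccuracy(0.1, 0, 0), "sigma2a")
  # PEV from the inverted coefficient matrix yields accuracies in [0, 1]
  t <- toyDesign(13)
  spec <- modelSpec(2, 1.5, 4)
  fit <- solveMME(t$design, buildAInverse(t$ped), spec, computePev = TRUE,
                  inbreedingF = inbreeding(t$ped))
  expect_true(all(pev(fit) >= 0))
  expect_true(all(accuracies(fit) >= 0 & accuracies(fit) <= 1))
  # animals with records are predicted more accurately than isolated founders
  withRec <- unique(t$rec$cow)
  expect_gt(mean(accuracies(fit)[withRec]),
            mean(accuracies(fit)[setdiff(names(ebv(fit)), withRec)]))
})
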