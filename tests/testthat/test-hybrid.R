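relMat <- function(v, role, ids = letters[seq_len(nrow(v))]) {
  dimnames(v) <- list(ids, ids)
  new("RelationshipMatrix", values = v, index = ids, role = role)
}

meanOff <- function(M) (sum(M) - sum(diag(M))) / (nrow(M) * (nrow(M) - 1))

test_that("tuning options satisfy their defining mean identities", {
  pan <- simulatePanel(120, 400, seed = 21)
  G <- buildG(pan)
  ped <- randomPedigree(200, seed = 21)
  A22 <- extractA22(buildA(ped), relIndex(buildA(ped))[81:200],
                    inverse = FALSE)$A22
  A22@index <- relIndex(G)       # align labels for the algebraic check
  dimnames(A22@values) <- list(relIndex(G), relIndex(G))

  expect_equal(relValues(tuneG(G, option = "TG0"))[, ], relValues(G)[, ])

  t1 <- relValues(tuneG(G, option = "TG1"))
  expect_equal(mean(diag(t1)), 1, tolerance = 1e-12)
  expect_lt(abs(meanOff(t1)), 1e-10)

  t2 <- relValues(tuneG(G, A22, "TG2"))
  expect_equal(mean(diag(t2)), mean(diag(relValues(A22))), tolerance = 1e-12)
  expect_equal(meanOff(t2), meanOff(relValues(A22)), tolerance = 1e-10)

  t3 <- relValues(tuneG(G, A22, "TG3"))
  expect_equal(mean(t3), mean(relValues(A22)), tolerance = 1e-12)

  t4 <- relValues(tuneG(G, A22, "TG4"))
  s <- mean(relValues(A22)) - mean(relValues(G))
  expect_equal(t4, (1 - s / 2) * relValues(G) + s, tolerance = 1e-12)
})

test_that("TG2 on the two-animal toy solves the 2x2 linear system", {
  G <- relMat(matrix(c(1.2, 0.1, 0.1, 1.1), 2), "G")
  A22 <- relMat(matrix(c(1.0, 0.25, 0.25, 1.05), 2), "A22")
  v <- relValues(tuneG(G, A22, "TG2"))
  expect_equal(mean(diag(v)), 1.025)
  expect_equal(v[1, 2], 0.25)
})

test_that("degenerate tuning errors instead of dividing by zero", {
  flat <- relMat(matrix(1, 3, 3), "G")
  A22 <- relMat(diag(3), "A22")
  expect_error(tuneG(flat, option = "TG1"), "degenerate")
  expect_error(tuneG(flat, A22, "TG2"), "degenerate")
})

test_that("blending is a convex combination with exact limits", {
  G <- relMat(matrix(c(1.2, 0.3, 0.3, 1.1), 2), "G")
  A22 <- relMat(diag(2), "A22")
  expect_equal(relValues(blendG(G, A22, beta = 1))[, ], relValues(A22)[, ])
  expect_equal(relValues(blendG(G, A22, beta = 0))[, ], relValues(G)[, ])
  expect_equal(unname(relValues(blendG(G, A22, beta = 0.5))),
               matrix(c(1.1, 0.15, 0.15, 1.05), 2))
  # beta = 0 with singular G names the smallest eigenvalue
  sing <- relMat(matrix(1, 2, 2), "G")
  expect_error(blendG(sing, A22, beta = 0), "eigenvalue")
})

test_that("matrix and literal-inverse blending agree exactly when G = A22", {
  ped <- randomPedigree(40, seed = 8)
  A <- buildA(ped)
  gid <- relIndex(A)[31:40]
  A22 <- extractA22(A, gid)$A22
  Gsame <- new("RelationshipMatrix", values = relValues(A22), index = gid,
               role = "G")
  b1 <- blendG(Gsame, A22, 0.3, "matrix")
  b2 <- blendG(Gsame, A22, 0.3, "literal_inverse")
  expect_equal(relValues(b1), relValues(b2), tolerance = 1e-10)
})

test_that("H inverse reduces to A inverse in the identity limits", {
  ped <- randomPedigree(30, seed = 12)
  Ai <- buildAInverse(ped)
  # no genotyped animals
  H0 <- assembleHInverse(Ai)
  expect_equal(as.matrix(relValues(H0)), as.matrix(relValues(Ai)))
  # Gb = A22, tau = omega = 1
  A <- buildA(ped)
  gid <- relIndex(A)[21:30]
  sub <- extractA22(A, gid)
  Gbinv <- new("RelationshipMatrix", values = relValues(sub$A22inv),
               index = gid, role = "G_blended_inverse")
  H1 <- assembleHInverse(Ai, sub$A22inv, Gbinv)
  expect_equal(as.matrix(relValues(H1)), as.matrix(relValues(Ai)),
               tolerance = 1e-12)
})

test_that("H inverse inverts to the dense joint-distribution H", {
  for (seed in 1:5) {
    set.seed(seed + 100)
    n <- sample(20:50, 1)
    ped <- randomPedigree(n, seed = seed + 40)
    A <- buildA(ped)
    ng <- sample(3:min(20, n - 2), 1)
    gid <- sample(relIndex(A), ng)
    sub <- extractA22(A, gid)
    L <- matrix(rnorm(ng * ng), ng)
    Gb <- relValues(sub$A22) + 0.3 * tcrossprod(L) / ng
    Gb <- relMat((Gb + t(Gb)) / 2, "G_blended", gid)
    Hi <- assembleHInverse(buildAInverse(ped), sub$A22inv, relInverse(Gb))
    Hd <- denseH(A, Gb, gid)
    ids <- relIndex(A)
    expect_lt(max(abs(solve(as.matrix(relValues(Hi)))[ids, ids] -
                        Hd[ids, ids])), 1e-8)
    # symmetric and positive definite
    Hm <- as.matrix(relValues(Hi))
    expect_equal(Hm, t(Hm))
    expect_gt(min(eigen(Hm, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("blending towards the pedigree shrinks H to A monotonically", {
  ped <- randomPedigree(30, seed = 31)
  A <- buildA(ped)
  Ai <- buildAInverse(ped)
  gid <- relIndex(A)[20:30]
  sub <- extractA22(A, gid)
  set.seed(32)
  L <- matrix(rnorm(121), 11)
  G <- relMat(relValues(sub$A22) + 0.5 * tcrossprod(L) / 11, "G", gid)
  dev <- vapply(c(0.5, 0.9, 1.0), function(b) {
    Gb <- blendG(G, sub$A22, b)
    Hi <- assembleHInverse(Ai, sub$A22inv, relInverse(Gb))
    max(abs(solve(as.matrix(relValues(Hi))) - as.matrix(relValues(A))))
  }, numeric(1))
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[3], 1e-10)
})

test_that("tau and omega scale the genotyped-block correction linearly", {
  ped <- randomPedigree(25, seed = 77)
  A <- buildA(ped)
  Ai <- buildAInverse(ped)
  gid <- relIndex(A)[16:25]
  sub <- extractA22(A, gid)
  set.seed(78)
  L <- matrix(rnorm(100), 10)
  Gb <- relMat(relValues(sub$A22) + 0.2 * tcrossprod(L) / 10, "G_blended", gid)
  Gbi <- relInverse(Gb)
  H <- function(tau, omega)
    as.matrix(relValues(assembleHInverse(Ai, sub$A22inv, Gbi,
                                         tau = tau, omega = omega)))
  lhs <- H(0.6, 0.8) - as.matrix(relValues(Ai))
  rhs <- matrix(0, 25, 25, dimnames = dimnames(lhs))
  pos <- match(gid, relIndex(A))
  rhs[pos, pos] <- 0.6 * as.matrix(relValues(Gbi)) -
    0.8 * as.matrix(relValues(sub$A22inv))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
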