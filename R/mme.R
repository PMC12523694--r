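## Single-trait repeatability animal model: y = Xb + Za + Wpe + e.

#' Build incidence structures for the repeatability model
#'
#' Fixed effects are contemporary group (reference-coded, one level dropped
#' for identifiability), parity, and age at calving fitted as a linear
#' covariate nested within parity (centered within parity). Z maps records to
#' animal codes over the full pedigree (so ancestors without records get
#' equations); W maps records to the permanent-environment level of the cow.
#'
#' @param edited lactation table carrying \code{cg_id} (from
#'   [formContemporaryGroups()]).
#' @param ped a [PedigreeTable-class]; every cow must be in it.
#' @param spec a [ModelSpec-class]; selects the trait column
#'   (\code{milk_kg}, \code{protein_kg} or \code{fat_kg}).
#' @return A [DesignSet-class].
#' @export
buildDesign <- function(edited, ped, spec = modelSpec()) {
  stopifnot(is(ped, "PedigreeTable"), is(spec, "ModelSpec"))
  d <- edited
  ycol <- paste0(spec@trait, "_kg")
  if (!ycol %in% names(d)) stop("trait column missing: ", ycol)
  p <- pedigree(ped)
  code <- p$code[match(as.character(d$cow), p$animal)]
  if (anyNA(code))
    stop("cows absent from pedigree: ",
         paste(utils::head(unique(d$cow[is.na(code)]), 5), collapse = ", "))
  cg <- factor(d$cg_id)
  if (nlevels(cg) < 2)
    stop("contemporary groups confounded: fewer than two CG levels remain")
  parity <- factor(d$parity, levels = sort(unique(d$parity)))
  ageC <- stats::ave(as.numeric(d$age_months), parity,
                     FUN = function(x) x - mean(x))
  mf <- data.frame(cg = cg, parity = parity, ageC = ageC)
  form <- if (nlevels(parity) > 1) ~ cg + parity + parity:ageC else ~ cg + ageC
  X <- Matrix(stats::model.matrix(form, mf), sparse = TRUE)
  nrec <- nrow(d)
  Z <- sparseMatrix(i = seq_len(nrec), j = code, x = 1,
                    dims = c(nrec, nrow(p)))
  colnames(Z) <- p$animal
  peIds <- sort(unique(as.character(d$cow)))
  W <- sparseMatrix(i = seq_len(nrec), j = match(as.character(d$cow), peIds),
                    x = 1, dims = c(nrec, length(peIds)))
  colnames(W) <- peIds
  new("DesignSet", X = X, Z = Z, W = W, y = as.numeric(d[[ycol]]),
      animalIds = p$animal, peIds = peIds, fixedNames = colnames(X))
}

## Jacobi-preconditioned conjugate gradients for C s = r.
.pcgSolve <- function(C, r, tol = 1e-10, maxit = 10000L) {
  n <- length(r)
  Minv <- 1 / Matrix::diag(C)
  x <- numeric(n)
  res <- r
  z <- Minv * res
  pvec <- z
  rz <- sum(res * z)
  r0 <- sqrt(sum(r^2))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(C %*% pvec)
    alpha <- rz / sum(pvec * Ap)
    x <- x + alpha * pvec
    res <- res - alpha * Ap
    rel <- sqrt(sum(res^2)) / r0
    if (rel < tol) return(list(x = x, iterations = it, residual = rel))
    z <- Minv * res
    rzNew <- sum(res * z)
    pvec <- z + (rzNew / rz) * pvec
    rz <- rzNew
  }
  stop(sprintf("PCG did not converge in %d iterations (relative residual %.3e)",
               maxit, rel))
}

#' Solve the mixed model equations
#'
#' Solves Henderson's equations for the repeatability model,
#' \deqn{\begin{pmatrix} X'X & X'Z & X'W \\ Z'X & Z'Z + K^{-1}\lambda_a & Z'W
#' \\ W'X & W'Z & W'W + I\lambda_{pe} \end{pmatrix}
#' \begin{pmatrix} b \\ a \\ pe \end{pmatrix} =
#' \begin{pmatrix} X'y \\ Z'y \\ W'y \end{pmatrix}}
#' with \eqn{\lambda_a = \sigma^2_e/\sigma^2_a},
#' \eqn{\lambda_{pe} = \sigma^2_e/\sigma^2_{pe}}, where \eqn{K^{-1}} is either
#' \eqn{A^{-1}} (ABLUP) or \eqn{H^{-1}} (ssGBLUP) over the full pedigree.
#'
#' @param design a [DesignSet-class].
#' @param Kinv a [RelationshipMatrix-class] with role \code{"A_inverse"} or
#'   \code{"H_inverse"}, indexed like \code{design@animalIds}.
#' @param spec a [ModelSpec-class].
#' @param method \code{"direct"} (sparse Cholesky; permits PEV) or
#'   \code{"pcg"} (Jacobi-preconditioned conjugate gradients, relative
#'   residual tolerance \code{tol}; no PEV).
#' @param computePev invert the coefficient matrix and return per-animal
#'   prediction-error variances (direct method only; costly for large
#'   systems).
#' @param inbreedingF optional named inbreeding coefficients (from
#'   [inbreeding()]) used in the accuracy denominator; zero when omitted.
#' @param tol PCG convergence tolerance (relative residual).
#' @return A [ModelFit-class].
#' @export
solveMME <- function(design, Kinv = NULL, spec = modelSpec(),
                     method = c("direct", "pcg"), computePev = FALSE,
                     inbreedingF = NULL, tol = 1e-10) {
  method <- match.arg(method)
  X <- design@X; Z <- design@Z; W <- design@W; y <- design@y
  nb <- ncol(X); na <- ncol(Z); np <- ncol(W)
  lambdaA <- spec@sigma2e / spec@sigma2a
  lambdaPe <- spec@sigma2e / spec@sigma2pe
  if (na > 0) {
    stopifnot(is(Kinv, "RelationshipMatrix"),
              relRole(Kinv) %in% c("A_inverse", "H_inverse"))
    if (!identical(relIndex(Kinv), design@animalIds))
      stop("Kinv index must match the design's animal ids")
  }
  M <- cbind(X, Z, W)
  blocks <- list(Matrix(0, nb, nb, sparse = TRUE))
  if (na > 0)
    blocks <- c(blocks, lambdaA * Matrix(relValues(Kinv), sparse = TRUE))
  if (np > 0) blocks <- c(blocks, lambdaPe * Diagonal(np))
  C <- forceSymmetric(crossprod(M) + Matrix::bdiag(blocks))
  rhs <- as.numeric(crossprod(M, y))
  logInfo <- list(method = method)
  if (method == "direct") {
    sol <- as.numeric(solve(C, rhs))
  } else {
    pcg <- .pcgSolve(C, rhs, tol = tol)
    sol <- pcg$x
    logInfo$iterations <- pcg$iterations
    logInfo$residual <- pcg$residual
  }
  b <- sol[seq_len(nb)]
  a <- if (na > 0) setNames(sol[nb + seq_len(na)], design@animalIds) else
    setNames(numeric(0), character(0))
  pe <- if (np > 0) setNames(sol[nb + na + seq_len(np)], design@peIds) else
    setNames(numeric(0), character(0))
  pevv <- setNames(rep(NA_real_, na), design@animalIds)
  acc <- setNames(rep(NA_real_, na), design@animalIds)
  if (computePev && na > 0) {
    if (method != "direct")
      stop("PEV requires the direct method (coefficient-matrix inverse)")
    Ci <- solve(C)
    pevv[] <- pmax(0, Matrix::diag(Ci)[nb + seq_len(na)]) * spec@sigma2e
    Fv <- rep(0, na)
    if (!is.null(inbreedingF)) Fv <- inbreedingF[design@animalIds]
    acc[] <- individualAccuracy(pevv, Fv, spec@sigma2a)
  }
  new("ModelFit",
      fixed = data.frame(effect = design@fixedNames, solution = b,
                         stringsAsFactors = FALSE),
      ebv = a, pe = pe, pev = pevv, accuracy = acc, spec = spec,
      log = logInfo)
}

#' PEV-based individual accuracy
#'
#' \deqn{r_i = \sqrt{\max(0, 1 - PEV_i / ((1 + F_i)\,\sigma^2_a))}}
#' clipped to [0, 1]: the accuracy is 1 when the prediction-error variance is
#' zero and 0 when it equals the animal's genetic variance.
#'
#' @param pevValues non-negative prediction-error variances.
#' @param F per-animal inbreeding coefficients (default 0).
#' @param sigma2a additive genetic variance (> 0).
#' @return Numeric accuracies in [0, 1].
#' @examples
#' individualAccuracy(0.36 * 2, F = 0, sigma2a = 2)  # sqrt(1 - 0.36) = 0.8
#' @export
individualAccuracy <- function(pevValues, F = 0, sigma2a) {
  if (sigma2a <= 0) stop("sigma2a must be > 0")
  stopifnot(all(pevValues >= 0 | is.na(pevValues)))
  r <- sqrt(pmax(0, 1 - pevValues / ((1 + F) * sigma2a)))
  pmin(1, r)
}
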