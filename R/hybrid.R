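## Blending, tuning and scaling of the hybrid relationship matrix.

.meanDiag <- function(M) mean(Matrix::diag(M))
.meanOffdiag <- function(M) {
  n <- nrow(M)
  if (n < 2) stop("off-diagonal mean undefined for a 1x1 matrix")
  (sum(M) - sum(Matrix::diag(M))) / (n * (n - 1))
}

#' Tune G towards compatibility with A22
#'
#' Rebase/rescale the genomic relationship matrix so that it refers to the
#' same genetic base as the pedigree block of the genotyped animals. Options:
#' \describe{
#'   \item{TG0}{no adjustment.}
#'   \item{TG1}{affine transform \eqn{a + bG} such that mean(diag) = 1 and
#'     mean(offdiag) = 0.}
#'   \item{TG2}{affine transform matching mean(diag) and mean(offdiag) of
#'     \eqn{A_{22}} (the BLUPF90 standard).}
#'   \item{TG3}{additive shift \eqn{G + aJ} matching the overall mean of
#'     \eqn{A_{22}}.}
#'   \item{TG4}{Fst-style rescale \eqn{G^* = (1 - s/2) G + s J} with
#'     \eqn{s = mean(A_{22}) - mean(G)}, interpreting s as the drift
#'     correction between the genomic and pedigree bases.}
#' }
#' TG1/TG2 are undefined (error) when mean(diag(G)) equals mean(offdiag(G)).
#'
#' @param G a [RelationshipMatrix-class] with role \code{"G"}.
#' @param A22 matching [RelationshipMatrix-class] with role \code{"A22"}
#'   (ignored for TG0/TG1).
#' @param option \code{"TG0"} to \code{"TG4"}.
#' @return The tuned G (role \code{"G"}).
#' @export
tuneG <- function(G, A22 = NULL, option = c("TG2", "TG0", "TG1", "TG3", "TG4")) {
  option <- match.arg(option)
  stopifnot(is(G, "RelationshipMatrix"), relRole(G) == "G")
  g <- as.matrix(relValues(G))
  if (option %in% c("TG2", "TG3", "TG4")) {
    stopifnot(is(A22, "RelationshipMatrix"), relRole(A22) == "A22")
    if (!identical(relIndex(G), relIndex(A22)))
      stop("G and A22 must be indexed over the same animals, same order")
    a22 <- as.matrix(relValues(A22))
  }
  n <- nrow(g)
  out <- switch(option,
    TG0 = g,
    TG1 = {
      md <- .meanDiag(g); mo <- .meanOffdiag(g)
      if (abs(md - mo) < 1e-12)
        stop("TG1 degenerate: mean(diag(G)) equals mean(offdiag(G))")
      b <- 1 / (md - mo); a <- -b * mo
      a + b * g
    },
    TG2 = {
      md <- .meanDiag(g); mo <- .meanOffdiag(g)
      if (abs(md - mo) < 1e-12)
        stop("TG2 degenerate: mean(diag(G)) equals mean(offdiag(G))")
      b <- (.meanDiag(a22) - .meanOffdiag(a22)) / (md - mo)
      a <- .meanDiag(a22) - b * md
      a + b * g
    },
    TG3 = g + (mean(a22) - mean(g)),
    TG4 = {
      s <- mean(a22) - mean(g)
      (1 - s / 2) * g + s
    })
  out <- (out + t(out)) / 2
  dimnames(out) <- list(relIndex(G), relIndex(G))
  new("RelationshipMatrix", values = out, index = relIndex(G), role = "G")
}

#' Blend G with the pedigree block A22
#'
#' Gives weight \eqn{\beta} to the residual polygenic (pedigree) component.
#' Two modes:
#' \describe{
#'   \item{matrix (default)}{\eqn{G_b = (1-\beta) G + \beta A_{22}}, the
#'     standard BLUPF90 behaviour; the inverse is taken downstream.}
#'   \item{literal_inverse}{blends the inverses directly,
#'     \eqn{G_b^{-1} = (1-\beta) G^{-1} + \beta A_{22}^{-1}}, and returns the
#'     matrix whose inverse that is. The two modes coincide when
#'     \eqn{G = A_{22}} and differ otherwise.}
#' }
#'
#' @param Gt tuned G ([RelationshipMatrix-class], role \code{"G"}).
#' @param A22 matching pedigree block (role \code{"A22"}).
#' @param beta blending fraction in [0, 1].
#' @param blendMode \code{"matrix"} or \code{"literal_inverse"}.
#' @return A [RelationshipMatrix-class] with role \code{"G_blended"}.
#' @export
blendG <- function(Gt, A22, beta = 0.05,
                   blendMode = c("matrix", "literal_inverse")) {
  blendMode <- match.arg(blendMode)
  stopifnot(is(Gt, "RelationshipMatrix"), is(A22, "RelationshipMatrix"),
            relRole(A22) == "A22", beta >= 0, beta <= 1)
  if (!identical(relIndex(Gt), relIndex(A22)))
    stop("G and A22 must be indexed identically")
  g <- as.matrix(relValues(Gt)); a22 <- as.matrix(relValues(A22))
  if (beta == 0) {
    ev <- min(eigen(g, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 1e-8)
      stop(sprintf("beta = 0 with (near-)singular G: smallest eigenvalue %.3e", ev))
  }
  gb <- if (blendMode == "matrix") {
    (1 - beta) * g + beta * a22
  } else {
    solve((1 - beta) * solve(g) + beta * solve(a22))
  }
  gb <- (gb + t(gb)) / 2
  dimnames(gb) <- list(relIndex(Gt), relIndex(Gt))
  new("RelationshipMatrix", values = gb, index = relIndex(Gt),
      role = "G_blended")
}

#' Assemble the single-step hybrid inverse
#'
#' \deqn{H^{-1} = A^{-1} + \begin{pmatrix} 0 & 0 \\ 0 & \tau G_b^{-1} -
#' \omega A_{22}^{-1} \end{pmatrix}}
#' scattering the genotyped-block correction into the positions of the
#' genotyped animals within the full-pedigree matrix. With \eqn{\tau = \omega
#' = 1} and \eqn{G_b = A_{22}} the correction cancels and \eqn{H^{-1} =
#' A^{-1}} exactly.
#'
#' @param Ainv full-pedigree inverse (role \code{"A_inverse"}).
#' @param A22inv genotyped-block inverse (role \code{"A22_inverse"}).
#' @param Gbinv blended-G inverse (role \code{"G_blended_inverse"} or
#'   \code{"G_inverse"}).
#' @param tau,omega positive scaling weights on \eqn{G_b^{-1}} and
#'   \eqn{A_{22}^{-1}}.
#' @return A [RelationshipMatrix-class] with role \code{"H_inverse"} (sparse
#'   symmetric), indexed like \code{Ainv}.
#' @export
assembleHInverse <- function(Ainv, A22inv = NULL, Gbinv = NULL,
                             tau = 1, omega = 1) {
  stopifnot(is(Ainv, "RelationshipMatrix"), relRole(Ainv) == "A_inverse",
            tau > 0, omega > 0)
  H <- Matrix(relValues(Ainv), sparse = TRUE)
  if (is.null(Gbinv) || length(relIndex(Gbinv)) == 0L) {
    ## no genotyped animals: H^-1 is A^-1
    return(new("RelationshipMatrix", values = forceSymmetric(H),
               index = relIndex(Ainv), role = "H_inverse"))
  }
  stopifnot(is(A22inv, "RelationshipMatrix"), relRole(A22inv) == "A22_inverse")
  gid <- relIndex(Gbinv)
  if (!identical(gid, relIndex(A22inv)))
    stop("Gb inverse and A22 inverse must be indexed identically")
  pos <- match(gid, relIndex(Ainv))
  if (anyNA(pos))
    stop("genotyped animal absent from pedigree: ",
         paste(utils::head(gid[is.na(pos)], 5), collapse = ", "))
  corr <- tau * as.matrix(relValues(Gbinv)) - omega * as.matrix(relValues(A22inv))
  H[pos, pos] <- H[pos, pos] + corr
  H <- forceSymmetric((H + Matrix::t(H)) / 2)
  new("RelationshipMatrix", values = H, index = relIndex(Ainv),
      role = "H_inverse")
}

#' Build H inverse from data in one call
#'
#' Convenience wrapper chaining [tuneG()], [blendG()], inversion and
#' [assembleHInverse()] for one [HybridParams-class] configuration.
#'
#' @param Ainv,A,A22,A22inv,G precomputed pieces ([RelationshipMatrix-class]);
#'   \code{A22}/\code{A22inv} as returned by [extractA22()].
#' @param params a [HybridParams-class].
#' @return A [RelationshipMatrix-class] with role \code{"H_inverse"}.
#' @export
hybridInverse <- function(Ainv, A22, A22inv, G, params = hybridParams()) {
  Gt <- tuneG(G, A22, params@tuning)
  Gb <- blendG(Gt, A22, params@beta, params@blendMode)
  assembleHInverse(Ainv, A22inv, relInverse(Gb),
                   tau = params@tau, omega = params@omega)
}
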