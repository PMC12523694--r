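## Pedigree reading, renumbering, and numerator relationship matrices.

#' Read and renumber a pedigree
#'
#' Reads a pedigree CSV (columns \code{animal,sire,dam} and optionally
#' \code{birth_date}, ISO-8601), validates it, appends animals that appear only
#' as parents as founders, maps unknown parents to internal code 0, and
#' renumbers all animals 1..n in a parents-before-offspring order.
#'
#' @param file path to the CSV, or a data.frame with the same columns.
#' @param unknownCodes labels treated as "unknown parent"; \code{NA} is always
#'   unknown.
#' @return A [PedigreeTable-class].
#' @details Unknown parents are treated as unrelated base-population animals;
#'   no unknown-parent groups are fitted. A cycle (an animal among its own
#'   ancestors) or a duplicated animal label is an error.
#' @examples
#' ped <- readPedigree(data.frame(animal = c("S", "D", "O"),
#'                                sire   = c(NA, NA, "S"),
#'                                dam    = c(NA, NA, "D")))
#' pedigree(ped)
#' @export
readPedigree <- function(file, unknownCodes = c("0", "", "NA")) {
  df <- if (is.data.frame(file)) file else
    read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree needs columns animal, sire, dam")
  an <- as.character(df$animal)
  if (anyDuplicated(an))
    stop("duplicate animal label: ", an[duplicated(an)][1])
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% unknownCodes] <- NA_character_
    x
  }
  si <- clean(df$sire); da <- clean(df$dam)
  bd <- if ("birth_date" %in% names(df)) as.Date(df$birth_date) else
    as.Date(rep(NA, length(an)))

  ## append implicit founders (labels only ever seen as parents)
  implied <- setdiff(stats::na.omit(unique(c(si, da))), an)
  if (length(implied)) {
    an <- c(an, implied)
    si <- c(si, rep(NA_character_, length(implied)))
    da <- c(da, rep(NA_character_, length(implied)))
    bd <- c(bd, as.Date(rep(NA, length(implied))))
  }
  n <- length(an)
  idx <- setNames(seq_len(n), an)
  sp <- ifelse(is.na(si), 0L, idx[si])
  dp <- ifelse(is.na(da), 0L, idx[da])

  ## Kahn topological sort, parents before offspring
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sp[i], dp[i])) if (p > 0L) {
      indeg[i] <- indeg[i] + 1L
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    bad <- setdiff(seq_len(n), ord)
    stop("pedigree cycle detected involving animal '", an[bad[1]], "'")
  }
  code <- integer(n); code[ord] <- seq_len(n)
  mapCode <- function(v) {
    out <- integer(length(v))
    out[v > 0L] <- code[v[v > 0L]]
    out
  }
  ped <- data.frame(code = code[ord],
                    animal = an[ord],
                    sire = si[ord], dam = da[ord],
                    sire_code = mapCode(sp[ord]),
                    dam_code  = mapCode(dp[ord]),
                    birth_date = bd[ord],
                    stringsAsFactors = FALSE)
  rownames(ped) <- NULL
  new("PedigreeTable", ped = ped)
}

## parent code vectors in internal order
.pedCodes <- function(ped) {
  p <- pedigree(ped)
  list(sire = p$sire_code, dam = p$dam_code, animal = p$animal)
}

#' Inbreeding coefficients by the Meuwissen--Luo algorithm
#'
#' Computes per-animal inbreeding F (and the Mendelian-sampling variances d)
#' without forming the full relationship matrix, by accumulating each animal's
#' row of the Cholesky factor L over its ancestors.
#'
#' @param ped a [PedigreeTable-class].
#' @return Named numeric vector of F, in pedigree order.
#' @examples
#' ped <- readPedigree(data.frame(animal = c("S", "D", "O"),
#'                                sire = c(NA, NA, "S"), dam = c(NA, NA, "D")))
#' inbreeding(ped)   # all zero: parents unrelated
#' @export
inbreeding <- function(ped) {
  ml <- .meuwissenLuo(ped)
  setNames(ml$F, .pedCodes(ped)$animal)
}

## Meuwissen & Luo recursion: F and Mendelian-sampling variances d.
## F of an unknown parent enters the d formula as -1, which reproduces
## d = 1 (no parents) and d = 0.75 - 0.25 F_p (one parent).
.meuwissenLuo <- function(ped) {
  pc <- .pedCodes(ped)
  s <- pc$sire; d <- pc$dam
  n <- length(s)
  Fi <- numeric(n); dv <- numeric(n)
  for (i in seq_len(n)) {
    fs <- if (s[i] > 0) Fi[s[i]] else -1
    fd <- if (d[i] > 0) Fi[d[i]] else -1
    dv[i] <- 0.5 - 0.25 * (fs + fd)
    if (s[i] == 0 || d[i] == 0) { Fi[i] <- 0; next }
    L <- numeric(i)
    L[i] <- 1
    acc <- -1
    for (j in i:1) {
      lj <- L[j]
      if (lj != 0) {
        if (s[j] > 0) L[s[j]] <- L[s[j]] + 0.5 * lj
        if (d[j] > 0) L[d[j]] <- L[d[j]] + 0.5 * lj
        acc <- acc + lj * lj * dv[j]
      }
    }
    Fi[i] <- acc
  }
  list(F = Fi, d = dv)
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense additive relationship matrix A by the tabular recursion:
#' \eqn{a_{ij} = (a_{sj} + a_{dj})/2} and
#' \eqn{a_{ii} = 1 + a_{sd}/2} when both parents are known.
#'
#' @param ped a [PedigreeTable-class].
#' @return A [RelationshipMatrix-class] with role \code{"A"}.
#' @export
buildA <- function(ped) {
  pc <- .pedCodes(ped)
  s <- pc$sire; d <- pc$dam
  n <- length(s)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- seq_len(i - 1L)
    if (s[i] > 0 && d[i] > 0) {
      if (i > 1) A[i, js] <- 0.5 * (A[s[i], js] + A[d[i], js])
      A[i, i] <- 1 + 0.5 * A[s[i], d[i]]
    } else if (s[i] > 0 || d[i] > 0) {
      p <- max(s[i], d[i])
      if (i > 1) A[i, js] <- 0.5 * A[p, js]
      A[i, i] <- 1
    } else {
      A[i, i] <- 1
    }
    if (i > 1) A[js, i] <- A[i, js]
  }
  dimnames(A) <- list(pc$animal, pc$animal)
  new("RelationshipMatrix", values = A, index = pc$animal, role = "A")
}

#' Sparse inverse of A by Henderson's rules with inbreeding
#'
#' Constructs \eqn{A^{-1}} directly from the pedigree using Mendelian-sampling
#' variances computed from parental inbreeding (Meuwissen--Luo), without ever
#' forming A. Equals the dense inverse of [buildA()] output.
#'
#' @param ped a [PedigreeTable-class].
#' @return A [RelationshipMatrix-class] with role \code{"A_inverse"} holding a
#'   sparse symmetric matrix.
#' @export
buildAInverse <- function(ped) {
  pc <- .pedCodes(ped)
  s <- pc$sire; d <- pc$dam
  n <- length(s)
  ml <- .meuwissenLuo(ped)
  alpha <- 1 / ml$d
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    a <- alpha[i]
    add(i, i, a)
    par <- c(s[i], d[i])
    par <- par[par > 0]
    for (p in par) {
      add(i, p, -a / 2); add(p, i, -a / 2)
      add(p, p, a / 4)
    }
    if (length(par) == 2) {
      add(par[1], par[2], a / 4); add(par[2], par[1], a / 4)
    }
  }
  Ainv <- sparseMatrix(i = ii[seq_len(k)], j = jj[seq_len(k)],
                       x = xx[seq_len(k)], dims = c(n, n),
                       dimnames = list(pc$animal, pc$animal))
  Ainv <- forceSymmetric(drop0(Ainv))
  new("RelationshipMatrix", values = Ainv, index = pc$animal,
      role = "A_inverse")
}

#' Extract the genotyped block A22 (and invert it)
#'
#' Takes the principal submatrix of A for the genotyped animals, in the order
#' given (which must be the order used for G). This is the correct A22 of the
#' joint pedigree -- it retains relationships transmitted through ungenotyped
#' ancestors, unlike building A on a pruned genotyped-only pedigree.
#'
#' @param A a [RelationshipMatrix-class] with role \code{"A"} over the full
#'   pedigree.
#' @param genotypedIds animal labels, a subset of the pedigree.
#' @param inverse also compute the dense inverse (default TRUE).
#' @return A list with elements \code{A22} and (if requested) \code{A22inv},
#'   both [RelationshipMatrix-class] objects.
#' @export
extractA22 <- function(A, genotypedIds, inverse = TRUE) {
  stopifnot(is(A, "RelationshipMatrix"), relRole(A) == "A")
  miss <- setdiff(genotypedIds, relIndex(A))
  if (length(miss))
    stop("genotyped animals absent from pedigree: ",
         paste(utils::head(miss, 5), collapse = ", "))
  pos <- match(genotypedIds, relIndex(A))
  A22 <- as.matrix(relValues(A))[pos, pos, drop = FALSE]
  dimnames(A22) <- list(genotypedIds, genotypedIds)
  out <- list(A22 = new("RelationshipMatrix", values = A22,
                        index = as.character(genotypedIds), role = "A22"))
  if (inverse) {
    A22i <- tryCatch(solve(A22), error = function(e)
      stop("A22 is singular (duplicate or copy animals?): ",
           conditionMessage(e)))
    A22i <- (A22i + t(A22i)) / 2
    out$A22inv <- new("RelationshipMatrix", values = A22i,
                      index = as.character(genotypedIds), role = "A22_inverse")
  }
  out
}

#' Invert a relationship matrix
#'
#' Dense inversion with role bookkeeping (A -> A_inverse, G_blended ->
#' G_blended_inverse, ...).
#'
#' @param x a [RelationshipMatrix-class].
#' @return The inverse as a [RelationshipMatrix-class].
#' @export
relInverse <- function(x) {
  stopifnot(is(x, "RelationshipMatrix"))
  role <- relRole(x)
  newRole <- if (grepl("_inverse$", role)) sub("_inverse$", "", role)
             else paste0(role, "_inverse")
  if (!newRole %in% .REL_ROLES)
    stop("cannot invert a matrix with role ", role)
  v <- as.matrix(relValues(x))
  inv <- solve(v)
  inv <- (inv + t(inv)) / 2
  dimnames(inv) <- dimnames(v)
  new("RelationshipMatrix", values = inv, index = relIndex(x), role = newRole)
}
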