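## Plain-text matrix export and flat YAML configuration.

#' Write / read a relationship matrix as symmetric coordinate text
#'
#' Upper triangle only, whitespace-separated columns \code{i j value} with
#' 1-based indices in matrix order; a header line carries the role and the
#' animal index.
#'
#' @param x a [RelationshipMatrix-class].
#' @param path output file.
#' @return \code{writeRelMatrix}: the path, invisibly; \code{readRelMatrix}:
#'   the reconstructed [RelationshipMatrix-class].
#' @export
writeRelMatrix <- function(x, path) {
  stopifnot(is(x, "RelationshipMatrix"))
  v <- as.matrix(relValues(x))
  up <- which(upper.tri(v, diag = TRUE) & v != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# role=", relRole(x), " index=",
                    paste(relIndex(x), collapse = ",")), con)
  writeLines(sprintf("%d %d %.17g", up[, 1], up[, 2], v[up]), con)
  invisible(path)
}

#' @rdname writeRelMatrix
#' @export
readRelMatrix <- function(path) {
  hdr <- readLines(path, n = 1)
  role <- sub("^# role=(\\S+).*$", "\\1", hdr)
  index <- strsplit(sub("^.*index=", "", hdr), ",")[[1]]
  dat <- read.table(path, skip = 1, col.names = c("i", "j", "x"))
  n <- length(index)
  v <- matrix(0, n, n)
  v[cbind(dat$i, dat$j)] <- dat$x
  v[cbind(dat$j, dat$i)] <- dat$x
  dimnames(v) <- list(index, index)
  new("RelationshipMatrix", values = v, index = index, role = role)
}

#' Write a pedigree CSV
#'
#' Columns \code{animal,sire,dam,birth_date} with unknown parents as "0";
#' round-trips through [readPedigree()].
#'
#' @param ped a [PedigreeTable-class].
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writePedigree <- function(ped, path) {
  p <- pedigree(ped)
  out <- data.frame(animal = p$animal,
                    sire = ifelse(is.na(p$sire), "0", p$sire),
                    dam = ifelse(is.na(p$dam), "0", p$dam),
                    birth_date = as.character(p$birth_date),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a panel as PLINK text PED/MAP
#'
#' The counted allele is written as "A" and the other as "B"; missing calls
#' as "0 0". Reading back with \code{countedAlleles = "A"} per locus restores
#' the panel.
#'
#' @param panel a [GenotypePanel-class].
#' @param pedPath,mapPath output paths.
#' @return \code{pedPath}, invisibly.
#' @export
writePedMap <- function(panel, pedPath, mapPath) {
  dos <- dosages(panel)
  m <- ncol(dos)
  map <- data.frame(chr = 1, snp = locusIds(panel), cm = 0, bp = seq_len(m))
  utils::write.table(map, mapPath, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  gstr <- matrix("0 0", nrow(dos), m)
  gstr[!is.na(dos) & dos == 0] <- "B B"
  gstr[!is.na(dos) & dos == 1] <- "A B"
  gstr[!is.na(dos) & dos == 2] <- "A A"
  lines <- paste(1, individualIds(panel), 0, 0, 0, -9,
                 apply(gstr, 1, paste, collapse = " "))
  writeLines(lines, pedPath)
  invisible(pedPath)
}

#' Write model solutions as CSV
#'
#' One row per effect level: fixed effects, then per-animal additive
#' solutions (with PEV and accuracy where computed), then
#' permanent-environment solutions.
#'
#' @param fit a [ModelFit-class].
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writeSolutions <- function(fit, path) {
  fx <- data.frame(effect_type = "fixed", level = fit@fixed$effect,
                   solution = fit@fixed$solution, pev = NA_real_,
                   accuracy = NA_real_, stringsAsFactors = FALSE)
  an <- data.frame(effect_type = "animal", level = names(fit@ebv),
                   solution = unname(fit@ebv), pev = unname(fit@pev),
                   accuracy = unname(fit@accuracy), stringsAsFactors = FALSE)
  pe <- data.frame(effect_type = "pe", level = names(fit@pe),
                   solution = unname(fit@pe), pev = NA_real_,
                   accuracy = NA_real_, stringsAsFactors = FALSE)
  write.csv(rbind(fx, an, pe), path, row.names = FALSE)
  invisible(path)
}

#' Read a flat YAML study configuration
#'
#' Keys recognised: \code{hybrid} (beta, tuning, tau, omega, blend_mode),
#' \code{grids} (beta/tuning/tau/omega value lists), \code{varcomp}
#' (sigma2_a, sigma2_pe, sigma2_e), \code{validation} (n or fraction),
#' \code{seed}. Missing sections fall back to package defaults.
#'
#' @param path YAML file.
#' @return A list: \code{params} ([HybridParams-class]), \code{grids},
#'   \code{varcomp} (numeric triple), \code{validation}, \code{seed}.
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  h <- y$hybrid
  params <- hybridParams(
    beta = if (is.null(h$beta)) 0.05 else h$beta,
    tuning = if (is.null(h$tuning)) "TG2" else h$tuning,
    tau = if (is.null(h$tau)) 1 else h$tau,
    omega = if (is.null(h$omega)) 1 else h$omega,
    blendMode = if (is.null(h$blend_mode)) "matrix" else h$blend_mode)
  grids <- utils::modifyList(sweepGrids(), y$grids %||% list())
  vc <- y$varcomp
  varcomp <- c(vc$sigma2_a %||% 0.28, vc$sigma2_pe %||% 0.17,
               vc$sigma2_e %||% 0.55)
  list(params = params, grids = grids, varcomp = varcomp,
       validation = y$validation, seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
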