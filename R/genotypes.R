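## Genotype I/O, SNP/animal quality control, VanRaden G.

.newPanel <- function(dos, ids, loci) {
  storage.mode(dos) <- "double"
  dimnames(dos) <- list(ids, loci)
  new("GenotypePanel", dosages = dos, individualIds = as.character(ids),
      locusIds = as.character(loci))
}

#' Read SNP genotypes
#'
#' Reads either whitespace-delimited PLINK text PED/MAP files or a headered
#' dosage-matrix CSV (rows = individuals, first column = id, remaining columns
#' = loci with entries 0/1/2 or NA).
#'
#' For PED/MAP input, each locus must be biallelic; dosages count the minor
#' allele (or the allele given in \code{countedAlleles}). The missing genotype
#' code is \code{0 0}.
#'
#' @param path PED file or dosage CSV path.
#' @param format \code{"ped_map"} or \code{"dosage_matrix"}.
#' @param mapPath MAP file path (defaults to \code{path} with extension
#'   \code{.map}).
#' @param countedAlleles optional named character vector (locus -> allele) to
#'   force the counted allele; otherwise the minor allele is counted, ties
#'   broken alphabetically.
#' @return A [GenotypePanel-class].
#' @export
readGenotypes <- function(path, format = c("ped_map", "dosage_matrix"),
                          mapPath = NULL, countedAlleles = NULL) {
  format <- match.arg(format)
  if (format == "dosage_matrix") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    dos <- as.matrix(df[, -1, drop = FALSE])
    bad <- !(is.na(dos) | dos %in% 0:2)
    if (any(bad)) stop("dosage matrix entries must be 0, 1, 2 or NA")
    return(.newPanel(dos, ids, colnames(df)[-1]))
  }
  if (is.null(mapPath)) mapPath <- sub("\\.ped$", ".map", path)
  map <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  loci <- as.character(map[[2]])
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  m <- length(loci)
  if (ncol(ped) != 6 + 2 * m)
    stop("PED has ", ncol(ped), " columns; expected ", 6 + 2 * m,
         " for ", m, " mapped loci")
  ids <- ped[[2]]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  dos <- matrix(NA_real_, nrow(ped), m)
  for (j in seq_len(m)) {
    als <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(als) > 2)
      stop("locus ", loci[j], " has more than two alleles: ",
           paste(als, collapse = "/"))
    if (length(als) == 0) next
    counted <- if (!is.null(countedAlleles) && loci[j] %in% names(countedAlleles)) {
      countedAlleles[[loci[j]]]
    } else if (length(als) == 1) {
      als[1]
    } else {
      cnt <- c(sum(a1[, j] == als[1], na.rm = TRUE) +
                 sum(a2[, j] == als[1], na.rm = TRUE),
               sum(a1[, j] == als[2], na.rm = TRUE) +
                 sum(a2[, j] == als[2], na.rm = TRUE))
      als[which.min(cnt)]           # minor allele; ties -> first alphabetically
    }
    dos[, j] <- (a1[, j] == counted) + (a2[, j] == counted)
  }
  .newPanel(dos, ids, loci)
}

#' Write a dosage matrix CSV
#'
#' @param panel a [GenotypePanel-class].
#' @param path output CSV path (first column \code{id}, then one column per
#'   locus). Round-trips through [readGenotypes()].
#' @return \code{path}, invisibly.
#' @export
writeGenotypes <- function(panel, path) {
  df <- data.frame(id = individualIds(panel), check.names = FALSE)
  df <- cbind(df, as.data.frame(dosages(panel), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Chi-square test for Hardy--Weinberg equilibrium
#'
#' One-degree-of-freedom goodness-of-fit test of genotype counts against the
#' expected Hardy--Weinberg proportions at the observed allele frequency.
#' A monomorphic locus returns p = 1 by convention.
#'
#' @param aa,ab,bb genotype counts (non-negative, total > 0).
#' @return The p-value.
#' @examples
#' hweTest(25, 50, 25)   # exact HWE proportions: p = 1
#' hweTest(50, 0, 50)    # total heterozygote deficit: p << 1e-22
#' @export
hweTest <- function(aa, ab, bb) {
  stopifnot(aa >= 0, ab >= 0, bb >= 0)
  n <- aa + ab + bb
  if (n <= 0) stop("total genotype count must be > 0")
  p <- (2 * aa + ab) / (2 * n)
  if (p == 0 || p == 1) return(1)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(aa, ab, bb) - e)^2 / e)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

.mafOf <- function(dos) {
  p <- colMeans(dos, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

.hwePerLocus <- function(dos) {
  vapply(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    hweTest(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
            sum(g == 2, na.rm = TRUE))
  }, numeric(1))
}

#' Genotype quality control
#'
#' Applies the standard panel edits in a fixed order mirroring common PLINK
#' practice (\code{--mind} before \code{--geno}/\code{--maf}/\code{--hwe}):
#' \enumerate{
#'   \item individuals with call rate below \code{indCallMin} removed;
#'   \item SNPs with call rate below \code{snpCallMin} (among retained
#'     individuals) removed;
#'   \item SNPs with minor allele frequency below \code{mafMin} removed;
#'   \item SNPs with Hardy--Weinberg chi-square p below \code{hweAlpha}
#'     removed.
#' }
#' Thresholds are applied as strict removals: a call rate of exactly 0.90 or a
#' MAF of exactly 0.05 is retained.
#'
#' @param panel a [GenotypePanel-class].
#' @param mafMin minimum minor allele frequency (default 0.05).
#' @param snpCallMin minimum SNP call rate (default 0.90).
#' @param indCallMin minimum individual call rate (default 0.90).
#' @param hweAlpha HWE p-value threshold (default 1e-4).
#' @return A list: \code{panel} (filtered [GenotypePanel-class]) and
#'   \code{report}, a data.frame with one row per step (\code{step},
#'   \code{removed}, \code{remaining_individuals}, \code{remaining_loci}).
#'   Applying the filter twice is a no-op.
#' @export
qcFilter <- function(panel, mafMin = 0.05, snpCallMin = 0.90,
                     indCallMin = 0.90, hweAlpha = 1e-4) {
  dos <- dosages(panel)
  rep_ <- function(step, removed, d)
    data.frame(step = step, removed = removed,
               remaining_individuals = nrow(d), remaining_loci = ncol(d),
               stringsAsFactors = FALSE)
  icr <- rowMeans(!is.na(dos))
  keepInd <- icr >= indCallMin
  d1 <- dos[keepInd, , drop = FALSE]
  report <- rep_("individual_call_rate", sum(!keepInd), d1)

  scr <- colMeans(!is.na(d1))
  keepSnp <- scr >= snpCallMin
  d2 <- d1[, keepSnp, drop = FALSE]
  report <- rbind(report, rep_("snp_call_rate", sum(!keepSnp), d2))

  maf <- .mafOf(d2)
  keepMaf <- !is.na(maf) & maf >= mafMin
  d3 <- d2[, keepMaf, drop = FALSE]
  report <- rbind(report, rep_("maf", sum(!keepMaf), d3))

  hwe <- .hwePerLocus(d3)
  keepHwe <- hwe >= hweAlpha
  d4 <- d3[, keepHwe, drop = FALSE]
  report <- rbind(report, rep_("hwe", sum(!keepHwe), d4))

  if (ncol(d4) == 0)
    stop("all loci removed by QC; relax mafMin/snpCallMin/hweAlpha")
  list(panel = .newPanel(d4, rownames(d4), colnames(d4)), report = report)
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' \deqn{G = Z Z' / (2 \sum_j p_j (1 - p_j))}
#' where Z is the dosage matrix column-centered by \eqn{2 p_j} and \eqn{p_j}
#' the counted-allele frequency observed in the genotyped set. Missing dosages
#' are imputed to the per-locus mean before centering (so they contribute zero
#' to Z).
#'
#' @param panel a [GenotypePanel-class], normally after [qcFilter()].
#' @return A [RelationshipMatrix-class] with role \code{"G"}.
#' @examples
#' p <- genotypePanel(matrix(c(0, 2, 2, 0), 2, 2), c("a", "b"), c("s1", "s2"))
#' relValues(buildG(p))    # [[2, -2], [-2, 2]]
#' @export
buildG <- function(panel) {
  M <- dosages(panel)
  p <- colMeans(M, na.rm = TRUE) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= .Machine$double.eps)
    stop("all loci monomorphic: VanRaden denominator is zero")
  for (j in which(colSums(is.na(M)) > 0))      # mean imputation
    M[is.na(M[, j]), j] <- 2 * p[j]
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(individualIds(panel), individualIds(panel))
  new("RelationshipMatrix", values = G, index = individualIds(panel),
      role = "G")
}

#' Construct a GenotypePanel from a matrix
#'
#' @param dosages numeric matrix (individuals x loci) with entries 0/1/2/NA.
#' @param individualIds,locusIds labels (defaults: row/column names or
#'   generated).
#' @return A [GenotypePanel-class].
#' @export
genotypePanel <- function(dosages,
                          individualIds = rownames(dosages),
                          locusIds = colnames(dosages)) {
  if (is.null(individualIds)) individualIds <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(locusIds)) locusIds <- paste0("snp", seq_len(ncol(dosages)))
  .newPanel(as.matrix(dosages), individualIds, locusIds)
}
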