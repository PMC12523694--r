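#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom Matrix Matrix sparseMatrix forceSymmetric Diagonal t crossprod solve diag drop0 bdiag
#' @importFrom stats pchisq cor rbinom rnorm runif var sd setNames
#' @importFrom utils read.csv write.csv read.table
NULL

setClassUnion("AnyMatrix", c("matrix", "Matrix"))
setClassUnion("characterOrNULL", c("character", "NULL"))

## ---------------------------------------------------------------------------
## PedigreeTable
## ---------------------------------------------------------------------------

#' Renumbered pedigree
#'
#' Holds a pedigree after validation and renumbering: animals carry 1-based
#' internal codes in a parents-before-offspring (topological) order, unknown
#' parents are coded 0, and animals that appeared only as parents have been
#' appended as founders.
#'
#' @slot ped data.frame with columns \code{code}, \code{animal}, \code{sire},
#'   \code{dam} (external labels, \code{NA} for unknown), \code{sire_code},
#'   \code{dam_code} (internal, 0 = unknown) and \code{birth_date}
#'   (\code{Date}, may be \code{NA}).
#'
#' @seealso [readPedigree()], [buildA()], [buildAInverse()], [inbreeding()]
#' @export
setClass("PedigreeTable", representation(ped = "data.frame"))

setValidity("PedigreeTable", function(object) {
  p <- object@ped
  need <- c("code", "animal", "sire_code", "dam_code")
  if (!all(need %in% names(p)))
    return(paste("missing columns:", paste(setdiff(need, names(p)), collapse = ", ")))
  n <- nrow(p)
  if (n == 0L) return(TRUE)
  if (!identical(sort(p$code), seq_len(n)))
    return("internal codes must be a permutation of 1..n")
  if (anyDuplicated(p$animal)) return("duplicate animal labels")
  ord <- order(p$code)
  s <- p$sire_code[ord]; d <- p$dam_code[ord]
  i <- seq_len(n)
  if (any(s >= i & s > 0) || any(d >= i & d > 0))
    return("every known parent must precede its offspring (code smaller)")
  TRUE
})

## ---------------------------------------------------------------------------
## GenotypePanel
## ---------------------------------------------------------------------------

#' SNP dosage panel
#'
#' Individuals-by-loci matrix of counted-allele dosages in {0, 1, 2, NA}, with
#' individual labels matching the pedigree and per-locus allele frequencies of
#' the counted allele (computed over non-missing calls).
#'
#' @slot dosages numeric matrix, rows = individuals, columns = loci; entries
#'   0/1/2 or \code{NA} for a missing call.
#' @slot individualIds character, row labels.
#' @slot locusIds character, column labels.
#'
#' @seealso [readGenotypes()], [qcFilter()], [buildG()]
#' @export
setClass("GenotypePanel",
         representation(dosages = "matrix",
                        individualIds = "character",
                        locusIds = "character"))

setValidity("GenotypePanel", function(object) {
  d <- object@dosages
  if (nrow(d) != length(object@individualIds))
    return("nrow(dosages) != length(individualIds)")
  if (ncol(d) != length(object@locusIds))
    return("ncol(dosages) != length(locusIds)")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% 0:2))
    return("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(object@individualIds))
    return("duplicate individual ids")
  TRUE
})

## ---------------------------------------------------------------------------
## RelationshipMatrix
## ---------------------------------------------------------------------------

.REL_ROLES <- c("A", "A_inverse", "A22", "A22_inverse", "G", "G_inverse",
                "G_blended", "G_blended_inverse", "H_inverse")

#' Tagged relationship matrix
#'
#' A symmetric relationship (or inverse-relationship) matrix together with the
#' ordered animal index it is defined over and its role in the single-step
#' system: pedigree \eqn{A}, its inverse, the genotyped block \eqn{A_{22}},
#' genomic \eqn{G}, blended \eqn{G_b}, or the hybrid \eqn{H^{-1}}.
#'
#' @slot values symmetric matrix (base or \pkg{Matrix} sparse).
#' @slot index character vector of animal labels, in matrix order.
#' @slot role one of \code{"A"}, \code{"A_inverse"}, \code{"A22"},
#'   \code{"A22_inverse"}, \code{"G"}, \code{"G_inverse"}, \code{"G_blended"},
#'   \code{"G_blended_inverse"}, \code{"H_inverse"}.
#'
#' @export
setClass("RelationshipMatrix",
         representation(values = "AnyMatrix", index = "character",
                        role = "character"))

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (nrow(v) != length(object@index)) return("index length != matrix order")
  if (length(object@role) != 1L || !object@role %in% .REL_ROLES)
    return(paste("role must be one of:", paste(.REL_ROLES, collapse = ", ")))
  if (nrow(v) > 0) {
    asym <- max(abs(v - Matrix::t(v)))
    if (asym > 1e-10) return(sprintf("matrix not symmetric (max asymmetry %g)", asym))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## HybridParams
## ---------------------------------------------------------------------------

#' Parameters of one ssGBLUP variant
#'
#' Bundles the levers applied when merging genomic and pedigree information:
#' the polygenic blending fraction \eqn{\beta}, the tuning option (TG0--TG4),
#' the scaling weights \eqn{\tau} (on \eqn{G_b^{-1}}) and \eqn{\omega}
#' (on \eqn{A_{22}^{-1}}), and whether blending acts on the matrices
#' (BLUPF90-style, default) or literally on their inverses.
#'
#' Defaults are the standard configuration: \eqn{\beta = 0.05}, tuning TG2,
#' \eqn{\tau = \omega = 1}.
#'
#' @slot beta numeric in [0, 1].
#' @slot tuning one of \code{"TG0" ... "TG4"}.
#' @slot tau,omega positive scalars.
#' @slot blendMode \code{"matrix"} or \code{"literal_inverse"}.
#'
#' @export
setClass("HybridParams",
         representation(beta = "numeric", tuning = "character",
                        tau = "numeric", omega = "numeric",
                        blendMode = "character"),
         prototype(beta = 0.05, tuning = "TG2", tau = 1, omega = 1,
                   blendMode = "matrix"))

setValidity("HybridParams", function(object) {
  if (length(object@beta) != 1 || object@beta < 0 || object@beta > 1)
    return("beta must be a single value in [0, 1]")
  if (!object@tuning %in% paste0("TG", 0:4))
    return("tuning must be one of TG0..TG4")
  if (object@tau <= 0 || object@omega <= 0)
    return("tau and omega must be positive")
  if (!object@blendMode %in% c("matrix", "literal_inverse"))
    return("blendMode must be 'matrix' or 'literal_inverse'")
  TRUE
})

#' @rdname HybridParams-class
#' @param beta polygenic blending fraction in [0, 1].
#' @param tuning tuning option, \code{"TG0"} to \code{"TG4"}.
#' @param tau,omega positive scaling weights inside the hybrid inverse.
#' @param blendMode \code{"matrix"} (blend G and A22, then invert) or
#'   \code{"literal_inverse"} (blend the inverses directly).
#' @return A \code{HybridParams} object.
#' @examples
#' hybridParams()                       # standard: beta 0.05, TG2, tau = omega = 1
#' hybridParams(beta = 0.3, tuning = "TG0")
#' @export
hybridParams <- function(beta = 0.05, tuning = "TG2", tau = 1, omega = 1,
                         blendMode = c("matrix", "literal_inverse")) {
  blendMode <- match.arg(blendMode)
  new("HybridParams", beta = beta, tuning = tuning, tau = tau, omega = omega,
      blendMode = blendMode)
}

## ---------------------------------------------------------------------------
## ModelSpec
## ---------------------------------------------------------------------------

#' Variance components and trait for the repeatability model
#'
#' @slot sigma2a additive genetic variance (trait units squared).
#' @slot sigma2pe permanent-environment variance.
#' @slot sigma2e residual variance.
#' @slot trait one of \code{"milk"}, \code{"protein"}, \code{"fat"}.
#'
#' @details Heritability is \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe}
#' + \sigma^2_e)} and must lie in (0, 1). The shipped defaults use
#' \eqn{h^2 = 0.28} with repeatability 0.45 on a unit phenotypic variance, an
#' illustrative configuration for milk yield; variance components are always
#' user inputs, not estimated here.
#'
#' @export
setClass("ModelSpec",
         representation(sigma2a = "numeric", sigma2pe = "numeric",
                        sigma2e = "numeric", trait = "character"),
         prototype(sigma2a = 0.28, sigma2pe = 0.17, sigma2e = 0.55,
                   trait = "milk"))

setValidity("ModelSpec", function(object) {
  if (object@sigma2a <= 0 || object@sigma2pe <= 0 || object@sigma2e <= 0)
    return("all variance components must be > 0")
  h2 <- object@sigma2a / (object@sigma2a + object@sigma2pe + object@sigma2e)
  if (h2 <= 0 || h2 >= 1) return("heritability must be in (0, 1)")
  if (!object@trait %in% c("milk", "protein", "fat"))
    return("trait must be milk, protein or fat")
  TRUE
})

#' @rdname ModelSpec-class
#' @param sigma2a,sigma2pe,sigma2e variance components (> 0).
#' @param trait trait name.
#' @return A \code{ModelSpec}.
#' @export
modelSpec <- function(sigma2a = 0.28, sigma2pe = 0.17, sigma2e = 0.55,
                      trait = c("milk", "protein", "fat")) {
  new("ModelSpec", sigma2a = sigma2a, sigma2pe = sigma2pe, sigma2e = sigma2e,
      trait = match.arg(trait))
}

## ---------------------------------------------------------------------------
## DesignSet, ModelFit
## ---------------------------------------------------------------------------

#' Incidence structures of the repeatability model
#'
#' Produced by [buildDesign()]: the fixed-effect matrix X (reference-coded
#' contemporary groups, parity, and an age-at-calving covariate nested within
#' parity), the animal incidence Z over the full pedigree, the
#' permanent-environment incidence W over cows with records, and the
#' observation vector y.
#'
#' @slot X,Z,W sparse incidence matrices (records in rows).
#' @slot y numeric observations.
#' @slot animalIds character, one per pedigree animal (columns of Z).
#' @slot peIds character, one per cow with records (columns of W).
#' @slot fixedNames character, column labels of X.
#' @export
setClass("DesignSet",
         representation(X = "AnyMatrix", Z = "AnyMatrix", W = "AnyMatrix",
                        y = "numeric", animalIds = "character",
                        peIds = "character", fixedNames = "character"))

#' Solutions of the mixed model equations
#'
#' @slot fixed data.frame of fixed-effect solutions (\code{effect},
#'   \code{solution}).
#' @slot ebv named numeric, additive solutions for every pedigree animal.
#' @slot pe named numeric, permanent-environment solutions per cow.
#' @slot pev named numeric, prediction-error variance per animal (NA when the
#'   coefficient-matrix inverse was not formed).
#' @slot accuracy named numeric, per-animal accuracy
#'   \eqn{\sqrt{1 - PEV/((1+F)\sigma^2_a)}} (NA when PEV is NA).
#' @slot spec the \code{ModelSpec} used.
#' @slot log list with solver metadata (method, iterations, residual norm).
#' @export
setClass("ModelFit",
         representation(fixed = "data.frame", ebv = "numeric", pe = "numeric",
                        pev = "numeric", accuracy = "numeric",
                        spec = "ModelSpec", log = "list"))

## ---------------------------------------------------------------------------
## ValidationPlan
## ---------------------------------------------------------------------------

#' Forward-validation split
#'
#' Validation cows are genotyped cows with at least one lactation record,
#' chosen from the most recent birth dates; all of their records are masked
#' from the reduced data set.
#'
#' @slot validationIds character, masked cow labels.
#' @slot full,reduced lactation data.frames (reduced = full minus every record
#'   of the validation cows).
#' @export
setClass("ValidationPlan",
         representation(validationIds = "character", full = "data.frame",
                        reduced = "data.frame"))

setValidity("ValidationPlan", function(object) {
  if (any(object@validationIds %in% object@reduced$cow))
    return("validation cows must have no records in the reduced data")
  if (!all(object@validationIds %in% object@full$cow))
    return("every validation cow must have a record in the full data")
  TRUE
})

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Synthetic dairy-population configuration
#'
#' Defines a multi-generation random-mating population with a small genotyped
#' subset nested in a large phenotyped cow population, 1--3 repeated lactation
#' records per cow, herd-year-season fixed structure, and an additive genetic
#' architecture split between unlinked SNP markers and a residual polygenic
#' term. All randomness flows from \code{seed}.
#'
#' @slot nFounders,nGenerations,nOffspringPerGen pedigree shape.
#' @slot femaleFraction fraction of animals that are female (dairy recording
#'   keeps few males).
#' @slot nSiresPerGen number of males used as sires each generation
#'   (half-sib family structure).
#' @slot nSnps,mafRange,nQtl marker panel: loci are unlinked, founder allele
#'   frequencies drawn Uniform(mafRange); nQtl of the SNPs carry effects.
#' @slot markerFraction fraction of sigma2a explained by the markers (the rest
#'   is residual polygenic), default 0.7.
#' @slot sigma2a,sigma2pe,sigma2e variance components on the standardized
#'   scale; defaults give h2 = 0.28, repeatability 0.45.
#' @slot sigmaCg standard deviation of herd-year-season effects.
#' @slot nHerds,baseYear,yearsPerGen herd and calendar structure.
#' @slot recordsPerCow maximum parities per cow (1--3; each cow draws
#'   uniformly from 1..recordsPerCow).
#' @slot genotypedFraction fraction of cows genotyped.
#' @slot recencyBias exponent biasing genotyping towards recent generations
#'   (0 = uniform).
#' @slot importedSireFraction fraction of final-generation matings sired by
#'   imported bulls: pedigree founders with no domestic records and only a
#'   few domestic daughters each, emulating the heavy use of foreign AI
#'   semen in national dairy populations. This is what leaves the youngest
#'   (validation) cows weakly connected to the phenotyped pedigree, so that
#'   pedigree-only prediction of them is poor while genomic relationships
#'   still reach them.
#' @slot nImportedSires size of the imported-bull pool for the final
#'   generation.
#' @slot importedDamFraction among imported-sire matings of the final
#'   generation, the fraction whose dam is likewise an imported founder
#'   female (embryo/heifer imports common in elite genotyped herds).
#'   Imported females carry no domestic lactation records and are not
#'   candidates for genotyping.
#' @slot nImportedDams size of the imported-female pool.
#' @slot genotypeSires also genotype every sire used (national genomic
#'   programmes genotype the proven bulls; the bulls' accurate progeny-based
#'   information then anchors the genomic reference).
#' @slot parentMissingRate probability that a parent of a non-genotyped
#'   animal goes unrecorded in the pedigree (applied independently per
#'   parent; genotyped animals keep full parentage, as is typical of national
#'   data where genotyped animals are the best-recorded). Gene dropping and
#'   true breeding values always use the true parents.
#' @slot traitMean,traitSd scale mapping the standardized phenotype to kg of
#'   milk; defaults 7940 and 2615 kg.
#' @slot seed integer master seed.
#' @export
setClass("SimConfig",
         representation(nFounders = "numeric", nGenerations = "numeric",
                        nOffspringPerGen = "numeric", femaleFraction = "numeric",
                        nSiresPerGen = "numeric",
                        nSnps = "numeric", mafRange = "numeric", nQtl = "numeric",
                        markerFraction = "numeric",
                        sigma2a = "numeric", sigma2pe = "numeric",
                        sigma2e = "numeric", sigmaCg = "numeric",
                        nHerds = "numeric", baseYear = "numeric",
                        yearsPerGen = "numeric", recordsPerCow = "numeric",
                        genotypedFraction = "numeric", recencyBias = "numeric",
                        parentMissingRate = "numeric",
                        genotypeSires = "logical",
                        importedSireFraction = "numeric",
                        nImportedSires = "numeric",
                        importedDamFraction = "numeric",
                        nImportedDams = "numeric",
                        traitMean = "numeric", traitSd = "numeric",
                        seed = "numeric"),
         prototype(nFounders = 300, nGenerations = 5, nOffspringPerGen = 640,
                   femaleFraction = 0.85, nSiresPerGen = 25,
                   nSnps = 1000, mafRange = c(0.05, 0.95), nQtl = 200,
                   markerFraction = 0.7,
                   sigma2a = 0.28, sigma2pe = 0.17, sigma2e = 0.55,
                   sigmaCg = 0.5, nHerds = 25, baseYear = 2000,
                   yearsPerGen = 3, recordsPerCow = 3,
                   genotypedFraction = 0.10, recencyBias = 3,
                   parentMissingRate = 0.3, genotypeSires = TRUE,
                   importedSireFraction = 0.6, nImportedSires = 120,
                   importedDamFraction = 0.5, nImportedDams = 300,
                   traitMean = 7940, traitSd = 2615, seed = 1))

setValidity("SimConfig", function(object) {
  if (object@sigma2a <= 0 || object@sigma2pe <= 0 || object@sigma2e <= 0)
    return("variance components must be > 0")
  if (object@genotypedFraction <= 0 || object@genotypedFraction > 1)
    return("genotypedFraction must be in (0, 1]")
  if (object@markerFraction < 0 || object@markerFraction > 1)
    return("markerFraction must be in [0, 1]")
  if (object@parentMissingRate < 0 || object@parentMissingRate >= 1)
    return("parentMissingRate must be in [0, 1)")
  if (!object@recordsPerCow %in% 1:3)
    return("recordsPerCow must be 1, 2 or 3")
  if (length(object@mafRange) != 2 || any(object@mafRange <= 0) ||
      any(object@mafRange >= 1) || diff(object@mafRange) < 0)
    return("mafRange must be an increasing pair inside (0, 1)")
  if (object@seed != round(object@seed)) return("seed must be an integer")
  TRUE
})

#' @rdname SimConfig-class
#' @param ... slot values overriding the defaults (see slots above).
#' @return A \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nFounders = 40, nGenerations = 3, nOffspringPerGen = 60,
#'                  nSnps = 200, seed = 42)
#' @export
simConfig <- function(...) new("SimConfig", ...)
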