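## Generics and accessors for the core S4 classes.

#' Number of animals in an object
#' @param x a \code{PedigreeTable}, \code{RelationshipMatrix} or
#'   \code{GenotypePanel}.
#' @return Integer count.
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))

#' @rdname nAnimals
#' @export
setMethod("nAnimals", "PedigreeTable", function(x) nrow(x@ped))
#' @rdname nAnimals
#' @export
setMethod("nAnimals", "RelationshipMatrix", function(x) length(x@index))
#' @rdname nAnimals
#' @export
setMethod("nAnimals", "GenotypePanel", function(x) length(x@individualIds))

#' Pedigree table accessor
#' @param x a \code{PedigreeTable}.
#' @return The underlying data.frame (code, animal, sire, dam, sire_code,
#'   dam_code, birth_date), ordered by internal code.
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))
#' @rdname pedigree
#' @export
setMethod("pedigree", "PedigreeTable", function(x) x@ped[order(x@ped$code), , drop = FALSE])

#' Relationship-matrix accessors
#' @param x a \code{RelationshipMatrix}.
#' @return \code{relValues}: the matrix; \code{relIndex}: the animal labels in
#'   matrix order; \code{relRole}: the role tag.
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))
#' @rdname relValues
#' @export
setMethod("relValues", "RelationshipMatrix", function(x) x@values)
#' @rdname relValues
#' @export
setGeneric("relIndex", function(x) standardGeneric("relIndex"))
#' @rdname relValues
#' @export
setMethod("relIndex", "RelationshipMatrix", function(x) x@index)
#' @rdname relValues
#' @export
setGeneric("relRole", function(x) standardGeneric("relRole"))
#' @rdname relValues
#' @export
setMethod("relRole", "RelationshipMatrix", function(x) x@role)

#' Genotype-panel accessors
#' @param x a \code{GenotypePanel}.
#' @return \code{dosages}: the numeric dosage matrix (with NA for missing);
#'   \code{individualIds}/\code{locusIds}: labels; \code{alleleFreqs}:
#'   per-locus counted-allele frequency over non-missing calls.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname dosages
#' @export
setMethod("dosages", "GenotypePanel", function(x) x@dosages)
#' @rdname dosages
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))
#' @rdname dosages
#' @export
setMethod("individualIds", "GenotypePanel", function(x) x@individualIds)
#' @rdname dosages
#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))
#' @rdname dosages
#' @export
setMethod("locusIds", "GenotypePanel", function(x) x@locusIds)
#' @rdname dosages
#' @export
setGeneric("alleleFreqs", function(x) standardGeneric("alleleFreqs"))
#' @rdname dosages
#' @export
setMethod("alleleFreqs", "GenotypePanel", function(x) {
  colMeans(x@dosages, na.rm = TRUE) / 2
})

#' Model-fit accessors
#' @param x a \code{ModelFit}.
#' @return \code{ebv}: named vector of additive solutions over the full
#'   pedigree; \code{pev}: prediction-error variances (NA unless computed);
#'   \code{accuracies}: per-animal accuracies; \code{fixedSolutions}: the
#'   fixed-effect solution table.
#' @export
setGeneric("ebv", function(x) standardGeneric("ebv"))
#' @rdname ebv
#' @export
setMethod("ebv", "ModelFit", function(x) x@ebv)
#' @rdname ebv
#' @export
setGeneric("pev", function(x) standardGeneric("pev"))
#' @rdname ebv
#' @export
setMethod("pev", "ModelFit", function(x) x@pev)
#' @rdname ebv
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))
#' @rdname ebv
#' @export
setMethod("accuracies", "ModelFit", function(x) x@accuracy)
#' @rdname ebv
#' @export
setGeneric("fixedSolutions", function(x) standardGeneric("fixedSolutions"))
#' @rdname ebv
#' @export
setMethod("fixedSolutions", "ModelFit", function(x) x@fixed)

## show methods -------------------------------------------------------------

setMethod("show", "PedigreeTable", function(object) {
  p <- object@ped
  nf <- sum(p$sire_code == 0 & p$dam_code == 0)
  cat("PedigreeTable with", nrow(p), "animals (", nf, "founders )\n")
})

setMethod("show", "GenotypePanel", function(object) {
  d <- object@dosages
  miss <- if (length(d)) mean(is.na(d)) else 0
  cat(sprintf("GenotypePanel: %d individuals x %d loci (%.2f%% missing)\n",
              nrow(d), ncol(d), 100 * miss))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat(sprintf("RelationshipMatrix [%s] over %d animals\n",
              object@role, length(object@index)))
})

setMethod("show", "HybridParams", function(object) {
  cat(sprintf("HybridParams: beta=%.2f tuning=%s tau=%.2f omega=%.2f (%s blending)\n",
              object@beta, object@tuning, object@tau, object@omega,
              object@blendMode))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit (%s): %d animals, %d fixed effects; solver: %s\n",
              object@spec@trait, length(object@ebv), nrow(object@fixed),
              object@log$method))
})

setMethod("show", "ValidationPlan", function(object) {
  cat(sprintf("ValidationPlan: %d validation cows; %d full / %d reduced records\n",
              length(object@validationIds), nrow(object@full),
              nrow(object@reduced)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d founders + %d x %d offspring; %d SNPs ",
                     "(%d QTL); h2=%.2f; seed=%d\n"),
              object@nFounders, object@nGenerations, object@nOffspringPerGen,
              object@nSnps, object@nQtl,
              object@sigma2a / (object@sigma2a + object@sigma2pe + object@sigma2e),
              as.integer(object@seed)))
})
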