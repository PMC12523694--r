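## Forward validation, realized accuracy, and parameter-sweep grids.

#' Select forward-validation cows
#'
#' Validation candidates are genotyped cows with at least one lactation
#' record; the \code{n} most recently born (birth date descending, ties broken
#' lexicographically by label) have all their records masked from the reduced
#' data set.
#'
#' @param genotypedIds genotyped animal labels.
#' @param phenotypes lactation table (edited, with \code{cow} column).
#' @param ped a [PedigreeTable-class] providing birth dates.
#' @param n number of validation cows (error if it exceeds the eligible
#'   count); the study default is a fraction of about 0.32 of the eligible
#'   genotyped cows.
#' @return A [ValidationPlan-class].
#' @export
selectValidationCows <- function(genotypedIds, phenotypes, ped, n) {
  p <- pedigree(ped)
  eligible <- intersect(genotypedIds, unique(as.character(phenotypes$cow)))
  if (n > length(eligible))
    stop("n = ", n, " exceeds the ", length(eligible),
         " genotyped cows with records")
  bd <- p$birth_date[match(eligible, p$animal)]
  ord <- order(bd, eligible, decreasing = c(TRUE, FALSE), method = "radix")
  chosen <- eligible[ord][seq_len(n)]
  reduced <- phenotypes[!(as.character(phenotypes$cow) %in% chosen), ,
                        drop = FALSE]
  rownames(reduced) <- NULL
  new("ValidationPlan", validationIds = chosen, full = phenotypes,
      reduced = reduced)
}

#' Realized accuracy of forward validation
#'
#' Pearson correlation, over the validation cows only, between the full-data
#' pedigree-BLUP EBVs and the reduced-data (G)EBVs of the model under test:
#' \deqn{\mathrm{Realized\ Accuracy} = cor(EBV_{BLUP, full},\;
#' G/EBV_{reduced}).}
#' The full-data side is always the ABLUP fit, whichever model produced the
#' reduced solutions.
#'
#' @param ebvFull named EBVs from the full-data ABLUP fit.
#' @param ebvReduced named (G)EBVs from the reduced-data fit under test.
#' @param ids validation cow labels (must be covered by both).
#' @return The correlation.
#' @examples
#' realizedAccuracy(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 4),
#'                  c("a", "b", "c"))   # 9/sqrt(84) = 0.982
#' @export
realizedAccuracy <- function(ebvFull, ebvReduced, ids) {
  if (!all(ids %in% names(ebvFull)) || !all(ids %in% names(ebvReduced)))
    stop("validation ids must be covered by both solution sets")
  if (length(ids) < 3) stop("need at least 3 validation animals")
  a <- ebvFull[ids]; b <- ebvReduced[ids]
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance among validation animals")
  cor(a, b)
}

#' Default sweep grids
#'
#' The experiment grids: blending \eqn{\beta \in \{0.05, 0.10, 0.20, 0.30,
#' 0.40\}}, tuning TG0--TG4, and scaling \eqn{\tau} and \eqn{\omega} each in
#' \{0.60, 0.70, 0.80, 0.90, 1.0\} (varied one at a time, the other held at
#' the default 1.0).
#'
#' @return A list with elements \code{beta}, \code{tuning}, \code{tau},
#'   \code{omega}.
#' @export
sweepGrids <- function() {
  list(beta = c(0.05, 0.10, 0.20, 0.30, 0.40),
       tuning = paste0("TG", 0:4),
       tau = c(0.60, 0.70, 0.80, 0.90, 1.0),
       omega = c(0.60, 0.70, 0.80, 0.90, 1.0))
}

.fmtLevel <- function(x) if (x == 1) "1" else sprintf("%.2f", x)

.gridPoints <- function(grids, mode) {
  base <- hybridParams()     # beta 0.05, TG2, tau = omega = 1
  pts <- switch(mode,
    blending = lapply(grids$beta, function(b) {
      list(label = sprintf("ssGBLUP_G%.2f", 1 - b),
           params = hybridParams(beta = b))
    }),
    tuning = lapply(grids$tuning, function(tg) {
      list(label = paste0("ssGBLUP_", tg),
           params = hybridParams(tuning = tg))
    }),
    scaling = c(
      lapply(grids$tau, function(tv) {
        list(label = paste0("ssGBLUP_tau", .fmtLevel(tv)),
             params = hybridParams(tau = tv))
      }),
      lapply(grids$omega, function(ov) {
        list(label = paste0("ssGBLUP_omega", .fmtLevel(ov)),
             params = hybridParams(omega = ov))
      })))
  pts
}

#' Run a blending / tuning / scaling sweep
#'
#' Implements the one-factor experiment design: one lever is varied over its
#' grid while the others stay at the standard configuration (\eqn{\beta} =
#' 0.05, TG2, \eqn{\tau} = \eqn{\omega} = 1). Per trait, the full-data ABLUP
#' reference is fitted once, an ABLUP reduced baseline row is emitted, and one
#' reduced ssGBLUP model is fitted per grid point; accuracies are realized
#' accuracies over the validation cows.
#'
#' Model labels follow the conventional naming: \code{ssGBLUP_G0.95} ...
#' \code{ssGBLUP_G0.60} for blending (\code{G} = \eqn{1-\beta}),
#' \code{ssGBLUP_TG0..TG4} for tuning, and \code{ssGBLUP_tau0.60} /
#' \code{ssGBLUP_omega0.60} (ASCII for the Greek \eqn{\tau}/\eqn{\omega}) for
#' scaling.
#'
#' @param bundle a list with \code{ped} ([PedigreeTable-class]), \code{panel}
#'   (QC-filtered [GenotypePanel-class]), \code{plan}
#'   ([ValidationPlan-class]); e.g. from [studyBundle()].
#' @param mode \code{"blending"}, \code{"tuning"} or \code{"scaling"}.
#' @param grids grid lists as from [sweepGrids()].
#' @param traits traits to evaluate.
#' @param varcomp variance components \code{c(sigma2a, sigma2pe, sigma2e)}
#'   applied to every trait (only their ratios enter the solutions).
#' @param fullReference \code{"ablup"} (the definition above) or
#'   \code{"same"} for a sensitivity analysis scoring each variant against its
#'   own full-data fit.
#' @return A data.frame with one row per model x trait: \code{model},
#'   \code{trait}, \code{accuracy}, \code{beta}, \code{tuning}, \code{tau},
#'   \code{omega}. Row count is |grid| x |traits| plus one ABLUP baseline row
#'   per trait.
#' @export
runSweep <- function(bundle, mode = c("blending", "tuning", "scaling"),
                     grids = sweepGrids(),
                     traits = c("milk", "protein", "fat"),
                     varcomp = c(0.28, 0.17, 0.55),
                     fullReference = c("ablup", "same")) {
  mode <- match.arg(mode)
  fullReference <- match.arg(fullReference)
  ped <- bundle$ped; panel <- bundle$panel; plan <- bundle$plan
  gid <- individualIds(panel)
  Ainv <- buildAInverse(ped)
  A <- buildA(ped)
  A22p <- extractA22(A, gid)
  G <- buildG(panel)
  pts <- .gridPoints(grids, mode)
  rows <- list()
  for (tr in traits) {
    spec <- modelSpec(varcomp[1], varcomp[2], varcomp[3], trait = tr)
    dFull <- buildDesign(plan@full, ped, spec)
    dRed <- buildDesign(plan@reduced, ped, spec)
    ablupFull <- solveMME(dFull, Ainv, spec)
    ablupRed <- solveMME(dRed, Ainv, spec)
    accA <- realizedAccuracy(ebv(ablupFull), ebv(ablupRed),
                             plan@validationIds)
    rows[[length(rows) + 1L]] <-
      data.frame(model = "ABLUP", trait = tr, accuracy = accA,
                 beta = NA, tuning = NA, tau = NA, omega = NA,
                 stringsAsFactors = FALSE)
    for (pt in pts) {
      hp <- pt$params
      Hinv <- tryCatch(
        hybridInverse(Ainv, A22p$A22, A22p$A22inv, G, hp),
        error = function(e) stop("grid point ", pt$label, " (", tr, "): ",
                                 conditionMessage(e)))
      fitRed <- solveMME(dRed, Hinv, spec)
      ref <- if (fullReference == "ablup") ablupFull else
        solveMME(dFull, Hinv, spec)
      acc <- realizedAccuracy(ebv(ref), ebv(fitRed), plan@validationIds)
      rows[[length(rows) + 1L]] <-
        data.frame(model = pt$label, trait = tr, accuracy = acc,
                   beta = hp@beta, tuning = hp@tuning, tau = hp@tau,
                   omega = hp@omega, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate and prepare one study data set
#'
#' Runs the full data pipeline on a synthetic population: simulate pedigree /
#' genotypes / lactations, apply the standard edits and contemporary-group
#' rules, and set up the forward-validation split.
#'
#' @param cfg a [SimConfig-class].
#' @param nValidation validation cows to mask; default 0.32 of the eligible
#'   genotyped cows.
#' @return A list: \code{ped}, \code{panel}, \code{plan}, \code{trueBv},
#'   \code{pheno} (edited, grouped full table), \code{editReport}.
#' @export
studyBundle <- function(cfg = simConfig(), nValidation = NULL) {
  pop <- simulatePopulation(cfg)
  raw <- simulatePhenotypes(pop, cfg)
  ed <- editLactations(raw)
  pheno <- formContemporaryGroups(ed$data, pop$ped)
  gid <- individualIds(pop$panel)
  if (is.null(nValidation))
    nValidation <- round(0.32 * length(intersect(gid, unique(pheno$cow))))
  plan <- selectValidationCows(gid, pheno, pop$ped, nValidation)
  list(ped = pop$ped, panel = pop$panel, plan = plan, trueBv = pop$trueBv,
       pheno = pheno, editReport = ed$report)
}

#' One ABLUP-vs-ssGBLUP forward-validation comparison
#'
#' Fits the full-data ABLUP reference, the reduced-data ABLUP baseline, and
#' the reduced-data ssGBLUP model under \code{params}, then reports realized
#' accuracy (against the full ABLUP EBVs) and, since the data are simulated,
#' true accuracy (against the simulated breeding values) for the validation
#' cows.
#'
#' @param cfg a [SimConfig-class].
#' @param params a [HybridParams-class] (default: standard configuration).
#' @param nValidation validation cows to mask (see [studyBundle()]).
#' @param trait trait to evaluate.
#' @return A list: \code{realized} and \code{true}, each
#'   \code{c(ablup, ssgblup)}; and \code{n} (validation cow count).
#' @export
runValidationStudy <- function(cfg = simConfig(), params = hybridParams(),
                               nValidation = NULL, trait = "milk") {
  b <- studyBundle(cfg, nValidation)
  spec <- modelSpec(cfg@sigma2a, cfg@sigma2pe, cfg@sigma2e, trait = trait)
  gid <- individualIds(b$panel)
  Ainv <- buildAInverse(b$ped)
  A <- buildA(b$ped)
  A22p <- extractA22(A, gid)
  G <- buildG(b$panel)
  Hinv <- hybridInverse(Ainv, A22p$A22, A22p$A22inv, G, params)
  dFull <- buildDesign(b$plan@full, b$ped, spec)
  dRed <- buildDesign(b$plan@reduced, b$ped, spec)
  ablupFull <- solveMME(dFull, Ainv, spec)
  ablupRed <- solveMME(dRed, Ainv, spec)
  ssRed <- solveMME(dRed, Hinv, spec)
  ids <- b$plan@validationIds
  list(realized = c(ablup = realizedAccuracy(ebv(ablupFull), ebv(ablupRed), ids),
                    ssgblup = realizedAccuracy(ebv(ablupFull), ebv(ssRed), ids)),
       true = c(ablup = trueAccuracy(ebv(ablupRed), b$trueBv, ids),
                ssgblup = trueAccuracy(ebv(ssRed), b$trueBv, ids)),
       n = length(ids))
}
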