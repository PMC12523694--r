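## Synthetic dairy population: pedigree, gene-dropped genotypes, lactations.

.addMonths <- function(date, months) {
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m")) - 1L + as.integer(months)
  d <- pmin(as.integer(format(date, "%d")), 28L)
  as.Date(sprintf("%04d-%02d-%02d", y + m %/% 12L, m %% 12L + 1L, d))
}

#' Simulate an unrelated genotype panel under Hardy--Weinberg equilibrium
#'
#' Draws per-locus counted-allele frequencies Uniform(\code{mafRange}) and
#' independent Binomial(2, p) dosages: an idealized base population with
#' unlinked loci, useful for exercising the G-matrix algebra.
#'
#' @param nInd,nSnps panel dimensions.
#' @param mafRange frequency range (pair inside (0, 1)).
#' @param seed integer seed.
#' @return A [GenotypePanel-class].
#' @export
simulatePanel <- function(nInd, nSnps, mafRange = c(0.05, 0.95), seed = 1) {
  set.seed(seed)
  p <- runif(nSnps, mafRange[1], mafRange[2])
  dos <- matrix(rbinom(nInd * nSnps, 2L, rep(p, each = nInd)), nInd, nSnps)
  genotypePanel(dos, paste0("ind", seq_len(nInd)), paste0("snp", seq_len(nSnps)))
}

#' Simulate a multi-generation dairy population
#'
#' Gene-drops unlinked SNP haplotypes through a random-mating pedigree with a
#' restricted sire pool (half-sib families). True breeding values are the sum
#' of a marker part (effects at \code{nQtl} of the SNPs, scaled so the marker
#' part explains \code{markerFraction} of \eqn{\sigma^2_a} among founders) and
#' a residual polygenic part transmitted as parent average plus Mendelian
#' sampling. A \code{genotypedFraction} of the cows, biased towards recent
#' generations, forms the genotyped subset.
#'
#' All randomness derives from \code{cfg@seed}; equal configurations give
#' bit-identical output.
#'
#' @param cfg a [SimConfig-class].
#' @return A list: \code{ped} ([PedigreeTable-class]), \code{panel}
#'   ([GenotypePanel-class] for the genotyped subset), \code{trueBv} (named
#'   vector, all animals), \code{meta} (data.frame: animal, sex, generation,
#'   birth_date).
#' @export
simulatePopulation <- function(cfg = simConfig()) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(as.integer(cfg@seed))
  nF <- cfg@nFounders; nG <- cfg@nGenerations; nO <- cfg@nOffspringPerGen
  nImpS <- if (cfg@importedSireFraction > 0) as.integer(cfg@nImportedSires) else 0L
  nImpD <- if (cfg@importedSireFraction > 0 && cfg@importedDamFraction > 0)
    as.integer(cfg@nImportedDams) else 0L
  n <- nF + nG * nO + nImpS + nImpD
  id <- sprintf("A%06d", seq_len(n))
  gen <- c(rep(0L, nF), rep(seq_len(nG), each = nO),
           rep(nG - 1L, nImpS + nImpD))            # imported animals enter late
  imported <- c(rep(FALSE, nF + nG * nO), rep(TRUE, nImpS + nImpD))
  sex <- ifelse(runif(n) < cfg@femaleFraction, "F", "M")
  sex[imported] <- rep(c("M", "F"), c(nImpS, nImpD))
  sire <- rep(NA_character_, n); dam <- rep(NA_character_, n)
  for (g in seq_len(nG)) {
    prevM <- which(gen == g - 1L & sex == "M" & !imported)
    prevF <- which(gen == g - 1L & sex == "F" & !imported)
    if (!length(prevM) || !length(prevF))
      stop("generation ", g - 1L, " has no available sires or dams")
    pool <- if (length(prevM) > cfg@nSiresPerGen)
      sample(prevM, cfg@nSiresPerGen) else prevM
    kids <- which(gen == g & !imported)
    sire[kids] <- id[sample(pool, length(kids), replace = TRUE)]
    dam[kids] <- id[sample(prevF, length(kids), replace = TRUE)]
    if (g == nG && nImpS > 0) {
      ## final generation: part of the matings use imported founder sires,
      ## and some of those are full embryo imports (imported dam as well)
      impS <- which(imported & sex == "M")
      impD <- which(imported & sex == "F")
      useImp <- kids[runif(length(kids)) < cfg@importedSireFraction]
      sire[useImp] <- id[sample(impS, length(useImp), replace = TRUE)]
      if (length(impD)) {
        useImpD <- useImp[runif(length(useImp)) < cfg@importedDamFraction]
        dam[useImpD] <- id[sample(impD, length(useImpD), replace = TRUE)]
      }
    }
  }
  byear <- cfg@baseYear + gen * cfg@yearsPerGen +
    sample.int(cfg@yearsPerGen, n, replace = TRUE) - 1L
  bdate <- as.Date(sprintf("%d-%02d-%02d", byear,
                           sample.int(12L, n, replace = TRUE),
                           sample.int(28L, n, replace = TRUE)))

  ## gene dropping: two haplotype matrices over all animals
  m <- cfg@nSnps
  p <- runif(m, cfg@mafRange[1], cfg@mafRange[2])
  hap1 <- matrix(0L, n, m); hap2 <- matrix(0L, n, m)
  rownames(hap1) <- rownames(hap2) <- id
  fo <- which(is.na(sire))                # pedigree founders, incl. imported
  hap1[fo, ] <- matrix(rbinom(length(fo) * m, 1L, rep(p, each = length(fo))),
                       length(fo), m)
  hap2[fo, ] <- matrix(rbinom(length(fo) * m, 1L, rep(p, each = length(fo))),
                       length(fo), m)
  sIdx <- match(sire, id); dIdx <- match(dam, id)
  for (i in which(!is.na(sire))) {
    pick <- runif(m) < 0.5
    hap1[i, ] <- ifelse(pick, hap1[sIdx[i], ], hap2[sIdx[i], ])
    pick <- runif(m) < 0.5
    hap2[i, ] <- ifelse(pick, hap1[dIdx[i], ], hap2[dIdx[i], ])
  }
  dos <- hap1 + hap2

  ## marker part of the breeding value
  sigma2m <- cfg@markerFraction * cfg@sigma2a
  u <- numeric(n)
  if (cfg@nQtl > 0 && sigma2m > 0) {
    qtl <- sample.int(m, min(cfg@nQtl, m))
    alpha <- rnorm(length(qtl))
    u <- as.numeric(dos[, qtl, drop = FALSE] %*% alpha)
    vf <- var(u[fo])
    if (vf > 0) u <- (u - mean(u[fo])) * sqrt(sigma2m / vf)
  } else {
    sigma2m <- 0
  }
  ## residual polygenic part, transmitted down the pedigree
  sigma2p <- cfg@sigma2a - sigma2m
  poly <- numeric(n)
  if (sigma2p > 0) {
    pf <- rnorm(length(fo))
    poly[fo] <- (pf - mean(pf)) * sqrt(sigma2p / var(pf))
    ms <- sqrt(0.5 * sigma2p)
    for (i in which(!is.na(sire)))
      poly[i] <- 0.5 * (poly[sIdx[i]] + poly[dIdx[i]]) + rnorm(1, 0, ms)
  }
  bv <- setNames(u + poly, id)

  ## genotyped subset: recent cows plus the service sires (national genomic
  ## programmes genotype the proven bulls alongside the sampled cows);
  ## imported females live abroad and are neither genotyped nor recorded
  cows <- which(sex == "F" & !imported)
  nGeno <- max(1L, round(cfg@genotypedFraction * length(cows)))
  wts <- (gen[cows] + 1)^cfg@recencyBias
  genoIdx <- cows[sample.int(length(cows), nGeno, prob = wts)]
  if (cfg@genotypeSires)
    genoIdx <- union(genoIdx, match(unique(stats::na.omit(sire)), id))
  genoIdx <- sort(genoIdx)
  panel <- genotypePanel(dos[genoIdx, , drop = FALSE], id[genoIdx],
                         paste0("snp", seq_len(m)))

  ## recorded pedigree: parents of non-genotyped animals may go unrecorded
  recSire <- sire; recDam <- dam
  if (cfg@parentMissingRate > 0) {
    open <- setdiff(which(gen > 0L), genoIdx)
    recSire[open][runif(length(open)) < cfg@parentMissingRate] <- NA
    recDam[open][runif(length(open)) < cfg@parentMissingRate] <- NA
  }
  ped <- readPedigree(data.frame(animal = id, sire = recSire, dam = recDam,
                                 birth_date = as.character(bdate),
                                 stringsAsFactors = FALSE))
  meta <- data.frame(animal = id, sex = sex, generation = gen,
                     birth_date = bdate, imported = imported,
                     stringsAsFactors = FALSE)
  list(ped = ped, panel = panel, trueBv = bv, meta = meta)
}

#' Simulate repeated lactation records
#'
#' Generates 1--\code{recordsPerCow} lactations per cow following the
#' repeatability model: herd-year-season effect + parity effect + linear age
#' covariate + true breeding value + permanent environment (constant within
#' cow) + residual, on a standardized scale, then mapped to kg of milk
#' (\code{traitMean}/\code{traitSd}) and clamped into the legal editing
#' window. Fat and protein yields derive from milk via truncated-normal
#' percentage draws, so all simulated records pass the standard edits
#' unchanged. Ages at calving are drawn inside the legal per-parity windows.
#'
#' @param pop result of [simulatePopulation()].
#' @param cfg the same [SimConfig-class].
#' @param fixedEffects logical; when \code{FALSE}, herd-year-season, parity
#'   and age effects are all zero (useful for clean heritability checks).
#' @return A lactation data.frame with columns \code{cow, herd, parity,
#'   calving_date, birth_date, age_months, milk_kg, fat_kg, protein_kg,
#'   fat_pct, protein_pct}.
#' @export
simulatePhenotypes <- function(pop, cfg = simConfig(), fixedEffects = TRUE) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(as.integer(cfg@seed) + 1L)
  meta <- pop$meta
  keep <- meta$sex == "F" & !(meta$imported %||% FALSE)
  cows <- meta[keep, , drop = FALSE]
  nc <- nrow(cows)
  nRec <- sample.int(cfg@recordsPerCow, nc, replace = TRUE)
  herd <- sample.int(cfg@nHerds, nc, replace = TRUE)
  pe <- rnorm(nc, 0, sqrt(cfg@sigma2pe))
  age1 <- sample(20:30, nc, replace = TRUE)
  rows <- vector("list", nc)
  for (k in seq_len(nc)) {
    par <- seq_len(nRec[k])
    ages <- cumsum(c(age1[k], 13L + sample(0:2, 2, replace = TRUE)))[par]
    rows[[k]] <- data.frame(cow = cows$animal[k], herd = herd[k],
                            parity = par,
                            birth_date = cows$birth_date[k],
                            age_months = ages, pe = pe[k],
                            stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  d$calving_date <- .addMonths(d$birth_date, d$age_months)
  cgLab <- paste(d$herd, format(d$calving_date, "%Y"),
                 assignSeason(d$calving_date), sep = "_")
  if (fixedEffects) {
    cgLevels <- sort(unique(cgLab))
    cgEff <- setNames(rnorm(length(cgLevels), 0, cfg@sigmaCg), cgLevels)
    parEff <- c(0, 0.15, 0.25)[d$parity]
    mid <- c(31, 44, 57)[d$parity]                 # window midpoints, months
    fx <- cgEff[cgLab] + parEff + 0.01 * (d$age_months - mid)
  } else {
    fx <- 0
  }
  e <- rnorm(nrow(d), 0, sqrt(cfg@sigma2e))
  ystd <- fx + pop$trueBv[d$cow] + d$pe + e
  d$milk_kg <- pmin(30000, pmax(1000, cfg@traitMean + cfg@traitSd * ystd))
  d$fat_pct <- pmin(8.8, pmax(2.2, rnorm(nrow(d), 3.2, 0.3)))
  d$protein_pct <- pmin(8.8, pmax(2.2, rnorm(nrow(d), 3.65, 0.25)))
  d$fat_kg <- d$milk_kg * d$fat_pct / 100
  d$protein_kg <- d$milk_kg * d$protein_pct / 100
  d$pe <- NULL
  rownames(d) <- NULL
  d[, c("cow", "herd", "parity", "calving_date", "birth_date", "age_months",
        "milk_kg", "fat_kg", "protein_kg", "fat_pct", "protein_pct")]
}

#' Correlation with simulated truth
#'
#' Pearson correlation between estimated and true breeding values over a set
#' of animals: the parameter-recovery analogue of realized accuracy, available
#' only in simulation where the truth is known.
#'
#' @param est named vector of (G)EBVs.
#' @param trueBv named vector of simulated breeding values.
#' @param ids animals to correlate over (default: names of \code{est}).
#' @return The correlation.
#' @export
trueAccuracy <- function(est, trueBv, ids = names(est)) {
  if (!all(ids %in% names(est)) || !all(ids %in% names(trueBv)))
    stop("ids must be covered by both estimate and truth")
  a <- est[ids]; b <- trueBv[ids]
  if (length(ids) < 3 || sd(a) == 0 || sd(b) == 0)
    stop("need >= 3 animals with non-zero variance")
  cor(a, b)
}
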