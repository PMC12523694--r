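## Lactation-record editing and contemporary-group formation.

#' Calving season
#'
#' Southern-hemisphere convention: calvings from October through March are
#' "summer", April through September "winter".
#'
#' @param calvingDate a \code{Date} (or string coercible to one).
#' @return \code{"summer"} or \code{"winter"} (vectorized).
#' @examples
#' assignSeason(as.Date("2005-10-15"))  # summer
#' assignSeason(as.Date("2005-09-30"))  # winter
#' @export
assignSeason <- function(calvingDate) {
  m <- as.integer(format(as.Date(calvingDate), "%m"))
  ifelse(m >= 10 | m <= 3, "summer", "winter")
}

#' Default lactation editing rules
#'
#' Age-at-calving windows (months, inclusive) per parity 1--3, milk-yield
#' bounds (kg) and fat/protein percentage bounds. All windows are read
#' inclusively.
#'
#' @return A list with elements \code{ageWindows} (3 x 2 matrix),
#'   \code{milkRange}, \code{pctRange}, \code{requireFirstLactation}.
#' @export
editConfig <- function(ageWindows = rbind(c(20, 42), c(30, 54), c(40, 67)),
                       milkRange = c(1000, 30000), pctRange = c(2, 9),
                       requireFirstLactation = TRUE) {
  list(ageWindows = ageWindows, milkRange = milkRange, pctRange = pctRange,
       requireFirstLactation = requireFirstLactation)
}

.needPhenoCols <- c("cow", "herd", "parity", "calving_date", "birth_date",
                    "milk_kg", "fat_kg", "protein_kg")

#' Edit lactation records
#'
#' Applies the phenotype edits in a fixed attribution order, so that a record
#' failing several rules is counted once, at the first failing rule:
#' missing birth/calving dates; age-at-calving outside the parity window
#' (inclusive); milk yield outside \code{milkRange}; fat or protein percentage
#' outside \code{pctRange}; and finally all records of cows lacking a
#' parity-1 record are dropped. Fat/protein percentages are recomputed from kg
#' yields when absent. The result is sorted by cow then parity, so the output
#' is independent of input row order.
#'
#' @param raw data.frame with columns \code{cow, herd, parity, calving_date,
#'   birth_date, milk_kg, fat_kg, protein_kg} (and optionally \code{fat_pct},
#'   \code{protein_pct}, \code{age_months}).
#' @param rules an [editConfig()] list.
#' @return A list: \code{data} (edited table, with \code{age_months},
#'   \code{fat_pct}, \code{protein_pct} filled in) and \code{report}
#'   (data.frame \code{rule}, \code{removed}; counts sum to the rows dropped).
#' @export
editLactations <- function(raw, rules = editConfig()) {
  stopifnot(all(.needPhenoCols %in% names(raw)))
  d <- raw
  d$cow <- as.character(d$cow)
  d$parity <- as.integer(d$parity)
  if (any(!d$parity %in% 1:3)) stop("parities must be 1, 2 or 3")
  d$calving_date <- as.Date(d$calving_date)
  d$birth_date <- as.Date(d$birth_date)
  if (!"age_months" %in% names(d)) {
    d$age_months <- round(as.numeric(d$calving_date - d$birth_date) / 30.4375)
  }
  if (!"fat_pct" %in% names(d)) d$fat_pct <- 100 * d$fat_kg / d$milk_kg
  if (!"protein_pct" %in% names(d)) d$protein_pct <- 100 * d$protein_kg / d$milk_kg

  fail <- rep(NA_character_, nrow(d))
  mark <- function(bad, rule) ifelse(is.na(fail) & bad, rule, fail)
  fail <- mark(is.na(d$birth_date) | is.na(d$calving_date), "missing_dates")
  w <- rules$ageWindows[d$parity, , drop = FALSE]
  fail <- mark(d$age_months < w[, 1] | d$age_months > w[, 2], "age_window")
  fail <- mark(d$milk_kg < rules$milkRange[1] | d$milk_kg > rules$milkRange[2],
               "milk_bounds")
  fail <- mark(d$fat_pct < rules$pctRange[1] | d$fat_pct > rules$pctRange[2] |
                 d$protein_pct < rules$pctRange[1] |
                 d$protein_pct > rules$pctRange[2], "pct_bounds")
  kept <- d[is.na(fail), , drop = FALSE]
  nFirst <- 0L
  if (rules$requireFirstLactation) {
    hasP1 <- unique(kept$cow[kept$parity == 1L])
    drop5 <- !(kept$cow %in% hasP1)
    nFirst <- sum(drop5)
    kept <- kept[!drop5, , drop = FALSE]
  }
  kept <- kept[order(kept$cow, kept$parity), , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0) warning("all records removed by editing")
  rulesOrder <- c("missing_dates", "age_window", "milk_bounds", "pct_bounds",
                  "no_first_lactation")
  counts <- c(table(factor(fail, levels = rulesOrder[1:4])), nFirst)
  report <- data.frame(rule = rulesOrder, removed = as.integer(counts),
                       stringsAsFactors = FALSE)
  list(data = kept, report = report)
}

#' Form herd-year-season contemporary groups
#'
#' Assigns \code{cg_id = herd x calving year x season} (season per
#' [assignSeason()]; the year is the calendar year of calving as-is, so the
#' October--December and January--March halves of one summer carry different
#' year labels). Groups with fewer than \code{minAnimals} distinct cows or
#' fewer than \code{minSires} distinct known sires are removed. Cows absent
#' from the pedigree are counted with unknown sire (with a warning); only
#' known sires count towards the sire threshold.
#'
#' Re-running on its own output is a fixed point.
#'
#' @param edited edited lactation table (from [editLactations()]).
#' @param ped a [PedigreeTable-class] used to look up sires.
#' @param minAnimals minimum distinct cows per group (default 5).
#' @param minSires minimum distinct known sires per group (default 2).
#' @return The table restricted to surviving groups, with a \code{cg_id}
#'   column added.
#' @export
formContemporaryGroups <- function(edited, ped, minAnimals = 5, minSires = 2) {
  d <- edited
  year <- format(as.Date(d$calving_date), "%Y")
  d$cg_id <- paste(d$herd, year, assignSeason(d$calving_date), sep = "_")
  p <- pedigree(ped)
  sire <- p$sire[match(d$cow, p$animal)]
  if (any(is.na(match(d$cow, p$animal)))) {
    warning(sum(is.na(match(d$cow, p$animal))),
            " cows missing from pedigree; counted with unknown sire")
  }
  keepCg <- vapply(split(seq_len(nrow(d)), d$cg_id), function(rows) {
    nCows <- length(unique(d$cow[rows]))
    nSires <- length(unique(stats::na.omit(sire[rows])))
    nCows >= minAnimals && nSires >= minSires
  }, logical(1))
  out <- d[d$cg_id %in% names(keepCg)[keepCg], , drop = FALSE]
  out <- out[order(out$cow, out$parity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
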