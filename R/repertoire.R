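# Survey summaries: per-species BSH content tables, the four-way
# BSH/PVA/both/neither category breakdown, BSH copy-number multiplicity,
# and lifestyle cross-tabulations. Percentages use half-up rounding to two
# decimal places (whole percents for the multiplicity shares).

#' Build per-strain call records from classification results
#'
#' @param results [predict.bsh_classifier()] output joined to provenance:
#'   needs `species`, `strain`, `label` columns (one row per candidate)
#' @param metadata optional strain metadata; strains present there but
#'   absent from `results` contribute zero-count rows
#' @return data frame with `species`, `strain`, `n_bsh`, `n_pva`
#' @export
strain_call_records <- function(results, metadata = NULL) {
  need <- c("species", "strain", "label")
  stopifnot(all(need %in% names(results)))
  key <- paste(results$species, results$strain, sep = "\r")
  base <- unique(data.frame(species = results$species,
                            strain = results$strain,
                            stringsAsFactors = FALSE))
  if (!is.null(metadata)) {
    base <- unique(rbind(base, metadata[, c("species", "strain")]))
  }
  bkey <- paste(base$species, base$strain, sep = "\r")
  base$n_bsh <- vapply(bkey, function(k)
    sum(key == k & results$label == "BSH"), integer(1), USE.NAMES = FALSE)
  base$n_pva <- vapply(bkey, function(k)
    sum(key == k & results$label == "PVA"), integer(1), USE.NAMES = FALSE)
  base <- base[order(base$species, base$strain), ]
  rownames(base) <- NULL
  base
}

#' Per-species summary of BSH content
#'
#' One row per species with at least one BSH-positive strain: total strains,
#' BSH-positive strains, their percentage (half-up, 2 dp), and counts of
#' strains carrying exactly 1, 2 and 3 BSH copies.
#'
#' @param records strain call records (`species`, `strain`, `n_bsh`, ...)
#' @return data frame with `species`, `total_strains`, `n_with_bsh`,
#'   `pct_with_bsh`, `n_with_1`, `n_with_2`, `n_with_3`
#' @export
summarize_species <- function(records) {
  if (nrow(records) == 0) stop("no strain call records", call. = FALSE)
  sp <- sort(unique(records$species))
  rows <- lapply(sp, function(s) {
    r <- records[records$species == s, ]
    n_with <- sum(r$n_bsh >= 1)
    if (n_with == 0) return(NULL)
    data.frame(species = s, total_strains = nrow(r), n_with_bsh = n_with,
               pct_with_bsh = round_half_up(100 * n_with / nrow(r), 2),
               n_with_1 = sum(r$n_bsh == 1), n_with_2 = sum(r$n_bsh == 2),
               n_with_3 = sum(r$n_bsh >= 3), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(), total_strains = integer(),
                      n_with_bsh = integer(), pct_with_bsh = numeric(),
                      n_with_1 = integer(), n_with_2 = integer(),
                      n_with_3 = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Four-way species category breakdown
#'
#' A species encodes BSH when at least one of its strains has `n_bsh >= 1`
#' (inclusive of species that also encode PVA), analogously for PVA, so
#' `n_pva + n_bsh - n_both + n_neither == total_species`.
#'
#' @param records strain call records
#' @param total_species total surveyed species (>= distinct species in
#'   `records`)
#' @return one-row data frame of counts and percentages (half-up, 2 dp)
#' @export
category_breakdown <- function(records, total_species) {
  sp <- unique(records$species)
  if (total_species < length(sp)) {
    stop("total_species smaller than the number of distinct species",
         call. = FALSE)
  }
  has_bsh <- vapply(sp, function(s)
    any(records$n_bsh[records$species == s] >= 1), logical(1))
  has_pva <- vapply(sp, function(s)
    any(records$n_pva[records$species == s] >= 1), logical(1))
  n_bsh <- sum(has_bsh)
  n_pva <- sum(has_pva)
  n_both <- sum(has_bsh & has_pva)
  n_neither <- total_species - sum(has_bsh | has_pva)
  pct <- function(k) round_half_up(100 * k / total_species, 2)
  data.frame(total_species = total_species,
             n_species_bsh = n_bsh, pct_species_bsh = pct(n_bsh),
             n_species_pva = n_pva, pct_species_pva = pct(n_pva),
             n_species_both = n_both, pct_species_both = pct(n_both),
             n_species_neither = n_neither,
             pct_species_neither = pct(n_neither))
}

#' BSH copy-number multiplicity across BSH-encoding species
#'
#' A species is "single" when no strain carries 2 or 3 copies; "triple" when
#' some strain carries 3; "double" otherwise. Percentages of BSH-encoding
#' species, half-up to whole percent.
#'
#' @param summaries output of [summarize_species()]
#' @return one-row data frame with counts and `pct_single`, `pct_double`,
#'   `pct_triple`
#' @export
bsh_multiplicity <- function(summaries) {
  n <- nrow(summaries)
  if (n == 0) stop("no BSH-encoding species", call. = FALSE)
  single <- summaries$n_with_2 == 0 & summaries$n_with_3 == 0
  triple <- summaries$n_with_3 > 0
  double <- !single & !triple
  data.frame(n_species = n, n_single = sum(single), n_double = sum(double),
             n_triple = sum(triple),
             pct_single = round_half_up(100 * sum(single) / n, 0),
             pct_double = round_half_up(100 * sum(double) / n, 0),
             pct_triple = round_half_up(100 * sum(triple) / n, 0))
}

#' Range of per-species BSH-positive strain percentages
#'
#' @param summaries output of [summarize_species()]
#' @return numeric vector `c(min, max)` of `pct_with_bsh`
#' @export
per_species_range <- function(summaries) {
  if (nrow(summaries) == 0) stop("no species summaries", call. = FALSE)
  c(min = min(summaries$pct_with_bsh), max = max(summaries$pct_with_bsh))
}

species_lifestyle_map <- function(metadata) {
  m <- unique(metadata[, c("species", "lifestyle")])
  dup <- unique(m$species[duplicated(m$species)])
  if (length(dup) > 0) {
    stop("species with more than one lifestyle: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  setNames(m$lifestyle, m$species)
}

#' Lifestyle cross-tabulation of enzyme-encoding species
#'
#' For each enzyme class (BSH, PVA): the count and percentage of encoding
#' species per lifestyle category, percentages over the class's encoding
#' species (half-up, 2 dp).
#'
#' @param records strain call records
#' @param metadata strain metadata (`species`, `strain`, `lifestyle`);
#'   every species in `records` must appear, with a single lifestyle
#' @return data frame with `enzyme`, `lifestyle`, `n_species`, `pct_species`
#' @export
lifestyle_crosstab <- function(records, metadata) {
  lmap <- species_lifestyle_map(metadata)
  sp <- unique(records$species)
  missing <- setdiff(sp, names(lmap))
  if (length(missing) > 0) {
    stop("species missing from metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(c(BSH = "n_bsh", PVA = "n_pva"), function(col) {
    enc <- sp[vapply(sp, function(s)
      any(records[[col]][records$species == s] >= 1), logical(1))]
    if (length(enc) == 0) return(NULL)
    tab <- table(factor(lmap[enc], levels = LIFESTYLES))
    data.frame(lifestyle = names(tab), n_species = as.integer(tab),
               pct_species = round_half_up(100 * as.integer(tab) /
                                             length(enc), 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, lapply(names(rows), function(e) {
    if (is.null(rows[[e]])) return(NULL)
    cbind(enzyme = e, rows[[e]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Published per-species BSH content table
#'
#' The printed overview of BSH content across the 39 BSH-encoding
#' lactobacillus species (total strains, BSH-positive strains and their
#' percentage, and exact per-copy-number strain counts), shipped as a
#' plain-text input for worked examples and cross-checks.
#'
#' @return data frame with `species`, `total_strains`, `n_with_bsh`,
#'   `pct_with_bsh`, `n_with_1`, `n_with_2`, `n_with_3`
#' @export
table2_bsh_content <- function() {
  path <- system.file("extdata", "table2_bsh_content.tsv",
                      package = "bshscreen", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Expand the published BSH content table into per-strain call records
#'
#' Creates one synthetic strain row per counted strain (copy numbers 0-3),
#' so the summarisers can recompute the printed percentages from raw-shaped
#' input.
#'
#' @param tab a table shaped like [table2_bsh_content()]
#' @return strain call records (`n_pva` set to 0)
#' @export
table2_strain_calls <- function(tab = table2_bsh_content()) {
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    copies <- c(rep(0L, r$total_strains - r$n_with_bsh),
                rep(1L, r$n_with_1), rep(2L, r$n_with_2),
                rep(3L, r$n_with_3))
    data.frame(species = r$species,
               strain = sprintf("s%03d", seq_along(copies)),
               n_bsh = copies, n_pva = 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Synthetic 170-species survey table
#'
#' A synthetic stand-in for the survey's species-level metadata: one row per
#' species with its lifestyle label and BSH/PVA presence flags. The
#' marginal counts (39 BSH-encoding species split 33 vertebrate-adapted /
#' 5 unknown / 1 nomadic; 82 PVA-encoding species split 11 / 33 free-living /
#' 33 unknown / 5 nomadic; 8 species encoding both; 57 encoding neither; 170
#' total) match the published survey, but the species-to-lifestyle and
#' species-to-presence assignments beyond the 39 named BSH species are
#' synthetic.
#'
#' @return data frame with `species`, `lifestyle`, `bsh`, `pva`
#' @export
synthetic_survey_table <- function() {
  path <- system.file("extdata", "survey170_lifestyle_synthetic.tsv",
                      package = "bshscreen", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Strain call records and metadata from a survey presence table
#'
#' @param survey a table shaped like [synthetic_survey_table()]
#' @return list with `records` (one strain per species) and `metadata`
#' @export
survey_strain_calls <- function(survey = synthetic_survey_table()) {
  records <- data.frame(species = survey$species, strain = "s001",
                        n_bsh = as.integer(survey$bsh),
                        n_pva = as.integer(survey$pva),
                        stringsAsFactors = FALSE)
  metadata <- data.frame(species = survey$species, strain = "s001",
                         lifestyle = survey$lifestyle,
                         stringsAsFactors = FALSE)
  list(records = records, metadata = metadata)
}
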