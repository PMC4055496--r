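#' Default label-to-genetics congruence rules
#'
#' Maps each product label (optionally qualified by declared catch area) to
#' the set of acceptable genetic species groups. A generic "Cod" label with
#' no declared area accepts either cod species; an Atlantic-declared cod must
#' be *Gadus morhua*, so a Pacific-cod identification counts as mislabelled.
#' `area = NA` rows apply to any (or undeclared) catch area.
#'
#' @return data.frame with columns `label`, `area`, `groups` (comma-joined).
#' @export
congruence_rules <- function() {
  data.frame(
    label = c("Cod", "Cod", "Cod", "Haddock", "Alaskan Pollack",
              "Hake (M. capensis)", "Whiting"),
    area = c("Atlantic", "Pacific", NA, NA, NA, NA, NA),
    groups = c("morhua", "macrocephalus", "morhua,macrocephalus",
               "aeglefinus", "chalcogramma", "capensis", "merlangus"),
    stringsAsFactors = FALSE
  )
}

#' Acceptable species groups for a label/area combination
#'
#' @param label product label.
#' @param area declared catch area or `NA`.
#' @param rules a rule table, see [congruence_rules()].
#' @return character vector of group ids.
#' @export
allowed_groups <- function(label, area, rules = congruence_rules()) {
  cand <- rules[rules$label == label, , drop = FALSE]
  if (nrow(cand) == 0)
    stop(sprintf("no congruence rule for label '%s'", label))
  if (!is.na(area)) {
    hit <- cand[!is.na(cand$area) & cand$area == area, , drop = FALSE]
    if (nrow(hit) == 0) hit <- cand[is.na(cand$area), , drop = FALSE]
  } else {
    hit <- cand[is.na(cand$area), , drop = FALSE]
  }
  if (nrow(hit) == 0)
    stop(sprintf("no congruence rule for label '%s' (area %s)", label, area))
  strsplit(hit$groups[1], ",")[[1]]
}

#' Verdict for one sample: does the genetic ID match the label?
#'
#' `CORRECT` iff the reconciled group is among the label's acceptable
#' groups; a `MIXED` reconciliation is always `MISLABELLED` (reason
#' `mixed`); an `UNRESOLVED` genetic ID yields verdict `UNRESOLVED`. An
#' ambiguous (non-mixed) multi-group identification is `CORRECT` only when
#' every tied group is acceptable, `MISLABELLED` (reason `ambiguous`) when
#' none is, and `UNRESOLVED` otherwise.
#'
#' @param sample list/row with `sample_id`, `label_species`, `catch_area`.
#' @param genetic a [reconcile_replicates()] result.
#' @param rules rule table.
#' @return list with `sample_id`, `verdict`, `reason`, `genetic`.
#' @export
congruence_verdict <- function(sample, genetic, rules = congruence_rules()) {
  stopifnot(inherits(genetic, "reconciled_id"))
  gen_str <- paste(genetic$final, collapse = "+")
  mk <- function(verdict, reason = NA_character_) {
    list(sample_id = sample$sample_id, verdict = verdict, reason = reason,
         genetic = gen_str, mixed = isTRUE(genetic$mixed))
  }
  if (identical(genetic$final, "UNRESOLVED")) return(mk("UNRESOLVED"))
  allowed <- allowed_groups(sample$label_species, sample$catch_area, rules)
  if (genetic$mixed) return(mk("MISLABELLED", "mixed"))
  g <- genetic$final
  if (length(g) == 1) {
    if (g %in% allowed) mk("CORRECT") else mk("MISLABELLED", "substitution")
  } else {
    if (all(g %in% allowed)) mk("CORRECT")
    else if (!any(g %in% allowed)) mk("MISLABELLED", "ambiguous")
    else mk("UNRESOLVED", "ambiguous")
  }
}

#' Stratified mislabelling summary
#'
#' Counts and rates overall, by labelled species (with cod split by declared
#' catch area), by processing level, and for the recurring substitution
#' patterns (Atlantic-declared cod identified as Pacific cod, haddock
#' identified as Atlantic cod, mixed-composition cod/haddock). Rates are
#' percentages of the DNA-analysable denominator; `UNRESOLVED` samples are
#' excluded from denominators. Raw fractions are retained; the print method
#' rounds half-up to 2 decimals.
#'
#' @param verdicts data.frame with `sample_id`, `verdict`, `reason`,
#'   `genetic`, `mixed` (rows from [congruence_verdict()]).
#' @param samples data.frame with `sample_id`, `label_species`, `catch_area`,
#'   `processing_level`.
#' @param totals optional list of stratum denominators (as from a published
#'   summary table covering only the mislabelled samples): fields
#'   `n_analysable`, `labels` (named counts), `cod_by_area` (Atlantic/
#'   Pacific/Unspecified), `processing_levels` (named counts "1".."5").
#'   When supplied, only mislabelled/unresolved verdicts need be present.
#' @return object of class `mislabel_summary`.
#' @export
summarize_mislabelling <- function(verdicts, samples, totals = NULL) {
  stopifnot(is.data.frame(verdicts), is.data.frame(samples))
  if (!all(verdicts$sample_id %in% samples$sample_id))
    stop("every verdict needs a matching sample record")
  d <- merge(verdicts, samples, by = "sample_id")
  mis <- d[d$verdict == "MISLABELLED", , drop = FALSE]

  if (is.null(totals)) {
    analysable <- d[d$verdict != "UNRESOLVED", , drop = FALSE]
    n_overall <- nrow(analysable)
    lab_n <- table(analysable$label_species)
    lvl_n <- table(factor(analysable$processing_level, levels = 1:5))
    cod <- analysable[analysable$label_species == "Cod", , drop = FALSE]
    area_n <- c(Atlantic = sum(cod$catch_area %in% "Atlantic"),
                Pacific = sum(cod$catch_area %in% "Pacific"),
                Unspecified = sum(is.na(cod$catch_area)))
  } else {
    n_overall <- totals$n_analysable
    lab_n <- unlist(totals$labels)
    lvl_n <- setNames(unlist(totals$processing_levels), 1:5)
    area_n <- unlist(totals$cod_by_area)
  }

  k_overall <- nrow(mis)
  rate <- function(k, n) ifelse(n > 0, 100 * k / n, NA_real_)

  by_label <- data.frame(
    label = names(lab_n),
    n = as.integer(lab_n),
    k = vapply(names(lab_n),
               function(l) sum(mis$label_species == l), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  by_label$rate_pct <- rate(by_label$k, by_label$n)

  cod_mis <- mis[mis$label_species == "Cod", , drop = FALSE]
  cod_by_area <- data.frame(
    area = names(area_n),
    n = as.integer(area_n),
    k = c(sum(cod_mis$catch_area %in% "Atlantic"),
          sum(cod_mis$catch_area %in% "Pacific"),
          sum(is.na(cod_mis$catch_area)))[
            match(names(area_n), c("Atlantic", "Pacific", "Unspecified"))],
    stringsAsFactors = FALSE, row.names = NULL)
  cod_by_area$rate_pct <- rate(cod_by_area$k, cod_by_area$n)

  by_level <- data.frame(
    level = 1:5,
    n = as.integer(lvl_n),
    k = vapply(1:5, function(l) sum(mis$processing_level == l), 0L))
  by_level$rate_pct <- rate(by_level$k, by_level$n)

  n_cod <- sum(by_label$n[by_label$label == "Cod"])
  n_had <- sum(by_label$n[by_label$label == "Haddock"])
  n_atl <- area_n[["Atlantic"]]
  details <- data.frame(
    pattern = c("atlantic_cod_as_pacific", "haddock_as_cod",
                "cod_mixed", "haddock_mixed"),
    n = c(n_atl, n_had, n_cod, n_had),
    k = c(sum(cod_mis$catch_area %in% "Atlantic" & !cod_mis$mixed &
                grepl("macrocephalus", cod_mis$genetic)),
          sum(mis$label_species == "Haddock" & !mis$mixed &
                mis$genetic == "morhua"),
          sum(cod_mis$mixed),
          sum(mis$label_species == "Haddock" & mis$mixed)),
    stringsAsFactors = FALSE)
  details$rate_pct <- rate(details$k, details$n)

  structure(list(
    overall = list(n = n_overall, k = k_overall,
                   rate_pct = rate(k_overall, n_overall),
                   correct_pct = rate(n_overall - k_overall, n_overall),
                   n_unresolved = sum(d$verdict == "UNRESOLVED")),
    by_label = by_label, cod_by_area = cod_by_area, by_level = by_level,
    details = details), class = "mislabel_summary")
}

#' @export
print.mislabel_summary <- function(x, ...) {
  r2 <- function(v) formatC(round_half_up(v, 2), format = "f", digits = 2)
  cat(sprintf("Mislabelling: %d/%d samples (%s%%); correctly labelled %s%%\n",
              x$overall$k, x$overall$n, r2(x$overall$rate_pct),
              r2(x$overall$correct_pct)))
  if (x$overall$n_unresolved > 0)
    cat(sprintf("  (%d unresolved samples excluded)\n",
                x$overall$n_unresolved))
  cat("\nBy labelled species:\n")
  for (i in seq_len(nrow(x$by_label)))
    cat(sprintf("  %-20s %3d/%3d  %s%%\n", x$by_label$label[i],
                x$by_label$k[i], x$by_label$n[i], r2(x$by_label$rate_pct[i])))
  cat("Cod by declared area:\n")
  for (i in seq_len(nrow(x$cod_by_area)))
    cat(sprintf("  %-20s %3d/%3d  %s%%\n", x$cod_by_area$area[i],
                x$cod_by_area$k[i], x$cod_by_area$n[i],
                r2(x$cod_by_area$rate_pct[i])))
  cat("By processing level (1 fresh/frozen fillet ... 5 fishcake):\n")
  for (i in 1:5)
    cat(sprintf("  level %d              %3d/%3d  %s%%\n", i,
                x$by_level$k[i], x$by_level$n[i], r2(x$by_level$rate_pct[i])))
  invisible(x)
}

#' Extrapolate excess landings from a substitution rate
#'
#' If a fraction `rate` of the reference species' reported landings are in
#' fact another species landed under its name, the excess tonnage is
#' `rate * reference_landings`; optionally also expressed as a percentage of
#' the stock's total allowable catch quota.
#'
#' @param rate fraction in `[0, 1]`.
#' @param reference_landings tonnes (>= 0).
#' @param quota optional quota in tonnes for the percentage.
#' @return list with `excess_tonnes` and (if `quota` given) `pct_of_quota`.
#' @export
excess_landings <- function(rate, reference_landings, quota = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (reference_landings < 0) stop("landings must be non-negative")
  out <- list(excess_tonnes = rate * reference_landings)
  if (!is.null(quota)) {
    if (quota <= 0) stop("quota must be positive")
    out$pct_of_quota <- 100 * out$excess_tonnes / quota
  }
  out
}

# species binomial -> congener group id (panel naming convention)
species_group_map <- function() {
  sp <- default_species()
  setNames(sp$group, sp$species)
}

.FIXTURE_MD5 <- "c8892acd9757f0522b3f6cbadcbabf75"

#' Load the packaged retail-survey mislabelled-sample records
#'
#' A transcription of the mislabelled-sample summary of a 386-product UK
#' supermarket whitefish survey: the 21 products whose genetic identification
#' contradicted the label, with label, declared catch area, product type,
#' real-time PCR call and both replicate sequence identifications, plus the
#' stratum denominators (371 DNA-analysable samples; 179 cod of which 57
#' Atlantic-declared and 20 Pacific-declared; 155 haddock; 32 Alaskan
#' pollack; 4 hake; 1 whiting; processing levels 84/84/31/128/44). The
#' printed analysable share (97.4%) is inconsistent with 371/386 = 96.1%;
#' both numbers are kept and the discrepancy flagged in
#' `totals$printed_analysable_pct_inconsistent`.
#'
#' @return list with `records` (data.frame incl. parsed `processing_level`),
#'   `reconciled` (named list of [reconcile_replicates()] results built from
#'   the two replicate identifications), and `totals`.
#' @export
load_survey_fixture <- function() {
  tsv <- system.file("extdata", "survey_mislabelled.tsv",
                     package = "fishaudit", mustWork = TRUE)
  jsn <- system.file("extdata", "survey_totals.json",
                     package = "fishaudit", mustWork = TRUE)
  md5 <- unname(tools::md5sum(tsv))
  if (!identical(md5, .FIXTURE_MD5))
    stop("fixture checksum mismatch: survey_mislabelled.tsv is corrupted")
  rec <- read.delim(tsv, stringsAsFactors = FALSE,
                    colClasses = c(sample_id = "character"))
  lvl_map <- c("fresh fillet" = 1L, "breaded fillet" = 2L,
               "fish fingers" = 3L, "precooked meal" = 4L,
               "fish cakes" = 5L)
  rec$processing_level <- unname(lvl_map[rec$product_type])
  if (anyNA(rec$processing_level))
    stop("unrecognised product type in fixture")
  rec$catch_area[rec$catch_area == "NA"] <- NA_character_

  g <- species_group_map()
  bad <- setdiff(c(rec$seq_id_1, rec$seq_id_2), names(g))
  if (length(bad) > 0)
    stop("unknown species in fixture: ", paste(bad, collapse = ", "))
  reconciled <- lapply(seq_len(nrow(rec)), function(i)
    reconcile_replicates(g[[rec$seq_id_1[i]]], g[[rec$seq_id_2[i]]],
                         sample_id = rec$sample_id[i]))
  names(reconciled) <- rec$sample_id

  totals <- jsonlite::read_json(jsn, simplifyVector = TRUE)
  totals$printed_analysable_pct_inconsistent <-
    abs(totals$printed_analysable_pct -
          100 * totals$n_analysable / totals$n_collected) > 0.5
  list(records = rec, reconciled = reconciled, totals = totals)
}

#' Concordance analysis of the packaged survey records
#'
#' Convenience wrapper: verdicts for the packaged mislabelled-sample records
#' against the default congruence rules, summarised with the survey's
#' stratum denominators.
#'
#' @param rules rule table, see [congruence_rules()].
#' @return a [summarize_mislabelling()] result.
#' @export
audit_survey_fixture <- function(rules = congruence_rules()) {
  fx <- load_survey_fixture()
  verdicts <- do.call(rbind, lapply(seq_len(nrow(fx$records)), function(i) {
    v <- congruence_verdict(fx$records[i, ], fx$reconciled[[i]], rules)
    as.data.frame(v, stringsAsFactors = FALSE)
  }))
  summarize_mislabelling(verdicts, fx$records, totals = fx$totals)
}
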