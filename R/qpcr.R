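#' Endpoint dRn of a well/dye trajectory
#'
#' Returns the cycle-40 dRn value exactly (no smoothing); endpoint
#' fluorescence is the quantity the positivity threshold is applied to.
#'
#' @param plate long plate data.frame (plate_id, well, role, sample_id, dye,
#'   cycle, delta_rn).
#' @param well well id, e.g. "A1".
#' @param dye dye layer, e.g. "COD".
#' @param plate_id optional plate id (needed when `plate` spans plates).
#' @return numeric endpoint dRn.
#' @export
endpoint_delta_rn <- function(plate, well, dye, plate_id = NULL) {
  sel <- plate$well == well & plate$dye == dye
  if (!is.null(plate_id)) sel <- sel & plate$plate_id == plate_id
  tr <- plate[sel, ]
  v <- tr$delta_rn[tr$cycle == 40]
  if (length(v) != 1)
    stop(sprintf("missing cycle-40 dRn for well %s, dye %s", well, dye))
  v
}

#' No-template-control threshold statistics
#'
#' Computes the positivity threshold `zM = M + Z*SD + C` from the endpoint
#' dRn values of a plate's no-template controls (per dye layer). `M` and `SD`
#' are the NTC endpoint mean and standard deviation, `Z = 3.89` is the
#' one-tailed normal quantile for 99.999% confidence (stored as a constant so
#' the statistic matches the published formula digit for digit), and `C`
#' (default 0.3) is a constant offset absorbing the slight fluorescence
#' increase caused by spectral bleeding between dye layers.
#'
#' @param ntc_endpoints numeric vector of NTC endpoint dRn values (>= 2).
#' @param C constant fluorescence offset.
#' @param Z one-tailed normal quantile constant.
#' @return object of class `ntc_stats` with fields M, SD, n_ntc, C, Z, zM.
#' @export
ntc_threshold <- function(ntc_endpoints, C = 0.3, Z = 3.89) {
  if (length(ntc_endpoints) < 2)
    stop("at least 2 NTC endpoints are required (SD undefined otherwise)")
  M <- mean(ntc_endpoints)
  SD <- sd(ntc_endpoints)
  structure(list(M = M, SD = SD, n_ntc = length(ntc_endpoints),
                 C = C, Z = Z, zM = M + Z * SD + C),
            class = "ntc_stats")
}

#' @export
print.ntc_stats <- function(x, ...) {
  cat(sprintf("NTC stats (n=%d): M=%.4g SD=%.4g C=%.4g -> zM=%.4g\n",
              x$n_ntc, x$M, x$SD, x$C, x$zM))
  invisible(x)
}

#' Call a single probe reaction against the NTC threshold
#'
#' Positive iff the endpoint dRn is strictly larger than `zM`; a value equal
#' to the threshold is negative.
#'
#' @param sample_endpoint numeric endpoint dRn (vectorised).
#' @param stats an [ntc_threshold()] result.
#' @return logical.
#' @export
call_probe <- function(sample_endpoint, stats) {
  stopifnot(inherits(stats, "ntc_stats"))
  sample_endpoint > stats$zM
}

#' Combine the cod and haddock probe results into a species call
#'
#' Exactly one of four categories: `COD` (cod probe only), `HADDOCK` (haddock
#' probe only), `INCONCLUSIVE` (both), `NEGATIVE` (neither; this means
#' "neither cod nor haddock", not assay failure).
#'
#' @param cod,had logical probe positivity (vectorised).
#' @return character vector of calls.
#' @export
call_sample <- function(cod, had) {
  ifelse(cod & had, "INCONCLUSIVE",
         ifelse(cod, "COD", ifelse(had, "HADDOCK", "NEGATIVE")))
}

#' Plate quality control
#'
#' A plate passes iff it carries at least 8 NTC wells, every positive-control
#' well calls positive against its own dye's threshold, and no NTC well calls
#' positive. Failures enumerate the offending wells; QC failure is a report
#' state, not an error.
#'
#' @param plate long plate data.frame for a single plate.
#' @param C,Z threshold constants, see [ntc_threshold()].
#' @return object of class `plate_qc`: list(plate_id, pass, failures,
#'   thresholds).
#' @export
validate_plate <- function(plate, C = 0.3, Z = 3.89) {
  pid <- unique(plate$plate_id)
  if (length(pid) != 1) stop("validate_plate expects a single plate")
  failures <- character(0)
  dyes <- sort(unique(plate$dye))
  ntc_wells <- unique(plate$well[plate$role == "NTC"])
  if (length(ntc_wells) < 8)
    failures <- c(failures,
                  sprintf("only %d NTC wells (8 required)", length(ntc_wells)))
  thresholds <- list()
  pos_role <- c(COD = "POS_COD", HAD = "POS_HAD")
  for (dye in dyes) {
    ntc_end <- vapply(ntc_wells, function(w)
      endpoint_delta_rn(plate, w, dye), 0)
    if (length(ntc_end) < 2) next
    st <- ntc_threshold(ntc_end, C = C, Z = Z)
    thresholds[[dye]] <- st
    bad_ntc <- ntc_wells[call_probe(ntc_end, st)]
    if (length(bad_ntc) > 0)
      failures <- c(failures, sprintf("NTC well %s positive on dye %s",
                                      bad_ntc, dye))
    role <- pos_role[[dye]] %||% NA_character_
    if (!is.na(role)) {
      pw <- unique(plate$well[plate$role == role])
      for (w in pw) {
        if (!call_probe(endpoint_delta_rn(plate, w, dye), st))
          failures <- c(failures,
                        sprintf("positive control %s below threshold on dye %s",
                                w, dye))
      }
    }
  }
  structure(list(plate_id = pid, pass = length(failures) == 0,
                 failures = failures, thresholds = thresholds),
            class = "plate_qc")
}

#' @export
print.plate_qc <- function(x, ...) {
  cat(sprintf("Plate %s QC: %s\n", x$plate_id,
              if (x$pass) "pass" else "FAIL"))
  for (f in x$failures) cat(" -", f, "\n")
  invisible(x)
}

#' Per-sample species calls from plate fluorescence
#'
#' For each plate and dye layer, computes the NTC threshold and calls every
#' sample well; the two dye layers are combined with [call_sample()]. NTC
#' statistics are computed within each plate and dye layer, never pooled
#' across plates. Samples on plates failing QC are marked `UNRESOLVED`
#' rather than dropped.
#'
#' @param plates long plate data.frame (may span several plates).
#' @param C,Z threshold constants.
#' @return list with `calls` (data.frame: sample_id, plate_id, cod_positive,
#'   had_positive, call) and `qc` (list of [validate_plate()] reports).
#' @export
qpcr_calls <- function(plates, C = 0.3, Z = 3.89) {
  calls <- NULL
  qc <- list()
  for (pid in unique(plates$plate_id)) {
    pl <- plates[plates$plate_id == pid, ]
    pq <- validate_plate(pl, C = C, Z = Z)
    qc[[pid]] <- pq
    swells <- unique(pl[pl$role == "SAMPLE", c("well", "sample_id")])
    if (nrow(swells) == 0) next
    if (!pq$pass) {
      calls <- rbind(calls, data.frame(
        sample_id = swells$sample_id, plate_id = pid,
        cod_positive = NA, had_positive = NA, call = "UNRESOLVED",
        stringsAsFactors = FALSE))
      next
    }
    ends <- function(dye) vapply(swells$well, function(w)
      endpoint_delta_rn(pl, w, dye), 0)
    cod <- call_probe(ends("COD"), pq$thresholds[["COD"]])
    had <- call_probe(ends("HAD"), pq$thresholds[["HAD"]])
    calls <- rbind(calls, data.frame(
      sample_id = swells$sample_id, plate_id = pid,
      cod_positive = unname(cod), had_positive = unname(had),
      call = call_sample(unname(cod), unname(had)),
      stringsAsFactors = FALSE))
  }
  if (is.null(calls))
    calls <- data.frame(sample_id = character(0), plate_id = character(0),
                        cod_positive = logical(0), had_positive = logical(0),
                        call = character(0))
  rownames(calls) <- NULL
  list(calls = calls, qc = qc)
}
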