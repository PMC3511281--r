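#' Write a session to a directory of TSV files
#'
#' Serializes a session to three tab-separated files with mandatory headers:
#' `spikes.tsv` (`unit_id`, `t_s`), `units.tsv` (`unit_id`, `region`,
#' `sort_quality`, `distance_mm`, `rec_start_s`, `rec_end_s`) and `stim.tsv`
#' (`train_id`, `pulse_index`, `onset_s`, `width_ms`, `rate_hz`,
#' `intensity_mw_mm2`). All times are seconds from recording start, written as
#' fixed-point decimals with 5 places (10 us resolution, the precision of the
#' stimulus timing); pulse widths are ms. Sessions whose times lie on the
#' 10 us grid round-trip losslessly through [read_session()]. Simulated
#' sessions additionally get a `ground_truth.tsv` sidecar with the generating
#' labels.
#'
#' @param session an [opto_session()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "opto_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop_invalid("cannot create directory ", path)
  fmt_t <- function(x) sprintf("%.5f", x)
  spikes <- do.call(rbind, lapply(session$units, function(u) {
    if (!length(u$timestamps)) return(NULL)
    data.frame(unit_id = u$unit_id, t_s = fmt_t(u$timestamps))
  }))
  if (is.null(spikes)) spikes <- data.frame(unit_id = character(), t_s = character())
  units <- do.call(rbind, lapply(session$units, function(u) {
    data.frame(unit_id = u$unit_id, region = u$region,
               sort_quality = u$sort_quality,
               distance_mm = ifelse(is.na(u$distance_to_injection), "NA",
                                    sprintf("%.3f", u$distance_to_injection)),
               rec_start_s = fmt_t(u$recording_start),
               rec_end_s = fmt_t(u$recording_end))
  }))
  stim <- pulse_onsets(session$protocol)
  stim$onset_s <- fmt_t(stim$onset_s)
  wr <- function(df, file) {
    utils::write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  wr(spikes, "spikes.tsv")
  wr(units, "units.tsv")
  wr(stim, "stim.tsv")
  if (!is.null(session$ground_truth)) wr(session$ground_truth, "ground_truth.tsv")
  invisible(path)
}

#' Read and validate a session directory
#'
#' Reads the three TSV files written by [write_session()], checking every
#' structural invariant on load: parseable numeric fields (malformed rows are
#' reported with their line number), strictly increasing per-unit timestamps
#' within the recording bounds, spikes belonging to declared units, complete
#' and regular pulse sequences, and non-overlapping, time-ordered trains.
#' Loading never silently drops rows.
#'
#' @param path directory containing `spikes.tsv`, `units.tsv`, `stim.tsv`.
#' @return an [opto_session()].
#' @export
read_session <- function(path) {
  need <- c("spikes.tsv", "units.tsv", "stim.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop_invalid("session directory is missing ", paste(missing, collapse = ", "))
  }
  rd <- function(file) {
    utils::read.delim(file.path(path, file), colClasses = "character",
                      check.names = FALSE)
  }
  spikes <- rd("spikes.tsv")
  units <- rd("units.tsv")
  stim <- rd("stim.tsv")
  num <- function(df, col, file) {
    if (!col %in% names(df)) stop_invalid(file, ": missing column ", col)
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]) & df[[col]] != "NA" & df[[col]] != "")
    if (length(bad)) {
      stop_invalid(file, " line ", bad[1] + 1, ": cannot parse ", col,
                   " value '", df[[col]][bad[1]], "'")
    }
    x
  }
  spikes$t_s <- num(spikes, "t_s", "spikes.tsv")
  units$rec_start_s <- num(units, "rec_start_s", "units.tsv")
  units$rec_end_s <- num(units, "rec_end_s", "units.tsv")
  units$distance_mm <- num(units, "distance_mm", "units.tsv")
  for (col in c("train_id", "pulse_index", "onset_s", "width_ms", "rate_hz",
                "intensity_mw_mm2")) {
    stim[[col]] <- num(stim, col, "stim.tsv")
  }
  unknown <- setdiff(spikes$unit_id, units$unit_id)
  if (length(unknown)) {
    stop_invalid("spikes.tsv refers to unit(s) absent from units.tsv: ",
                 paste(unknown, collapse = ", "))
  }
  sts <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    ts <- spikes$t_s[spikes$unit_id == u$unit_id]
    spike_train(ts, unit_id = u$unit_id, region = u$region,
                sort_quality = u$sort_quality,
                recording_start = u$rec_start_s, recording_end = u$rec_end_s,
                distance_to_injection = u$distance_mm)
  })
  n_assigned <- sum(vapply(sts, function(u) length(u$timestamps), numeric(1)))
  if (n_assigned != nrow(spikes)) {
    stop_invalid("spike count mismatch after load (", n_assigned, " vs ",
                 nrow(spikes), " rows)")
  }
  proto <- rebuild_protocol(stim)
  gt <- NULL
  if (file.exists(file.path(path, "ground_truth.tsv"))) {
    gt <- utils::read.delim(file.path(path, "ground_truth.tsv"),
                            check.names = FALSE)
  }
  opto_session(sts, proto, gt)
}

# Reassemble a stim_protocol from per-pulse rows, validating pulse regularity.
rebuild_protocol <- function(stim) {
  if (!nrow(stim)) {
    return(stim_protocol(data.frame(onset = numeric(), n_pulses = integer(),
                                    pulse_width = numeric(), pulse_rate = numeric(),
                                    intensity = numeric())))
  }
  trains <- lapply(split(stim, stim$train_id), function(d) {
    d <- d[order(d$pulse_index), , drop = FALSE]
    if (!identical(as.integer(d$pulse_index), seq_len(nrow(d)))) {
      stop_invalid("stim.tsv: train ", d$train_id[1],
                   " has an incomplete pulse sequence")
    }
    if (length(unique(d$width_ms)) > 1 || length(unique(d$rate_hz)) > 1) {
      stop_invalid("stim.tsv: train ", d$train_id[1],
                   " mixes pulse widths or rates")
    }
    expected <- d$onset_s[1] + (d$pulse_index - 1) / d$rate_hz[1]
    if (any(abs(d$onset_s - expected) > 2e-5)) {
      stop_invalid("stim.tsv: train ", d$train_id[1],
                   " pulse onsets are inconsistent with its pulse rate")
    }
    data.frame(onset = d$onset_s[1], n_pulses = nrow(d),
               pulse_width = d$width_ms[1], pulse_rate = d$rate_hz[1],
               intensity = d$intensity_mw_mm2[1])
  })
  stim_protocol(do.call(rbind, trains))
}
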