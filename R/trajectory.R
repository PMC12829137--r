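#' Construct a pitch trajectory
#'
#' A pitch trajectory is the per-rendition record of an operant pitch
#' conditioning experiment: one row per rendition of the target
#' syllable/utterance, ordered in time. Baseline renditions carry no
#' threshold and no hit flag; feedback renditions carry both.
#'
#' @param day integer day index (non-decreasing across renditions).
#' @param h time-of-day as a fraction of the day since local midnight,
#'   in `[0, 1)`.
#' @param pitch pitch of the target segment in Hz (finite, positive).
#' @param hit logical; whether the rendition triggered the aversive
#'   white-noise stimulus. `NA` during baseline.
#' @param threshold pitch threshold in Hz in force at that rendition;
#'   `NA` during baseline.
#' @param contingency `"low"` if white noise is delivered on pitches below
#'   the threshold, `"high"` if above; `NA` during baseline.
#' @param subject optional subject identifier stored in the metadata.
#' @param validate check invariants (ordering, positivity, hit consistency).
#'
#' @return An object of class `pitch_trajectory`: a `data.frame` with
#'   columns `day`, `h`, `pitch`, `hit`, `threshold`, `contingency` and a
#'   `meta` attribute.
#' @export
pitch_trajectory <- function(day, h, pitch, hit = NA, threshold = NA_real_,
                             contingency = NA_character_, subject = NA_character_,
                             validate = TRUE) {
  n <- length(pitch)
  df <- data.frame(
    day = as.integer(day),
    h = as.numeric(h),
    pitch = as.numeric(pitch),
    hit = as.logical(rep_len(hit, n)),
    threshold = as.numeric(rep_len(threshold, n)),
    contingency = as.character(rep_len(contingency, n)),
    stringsAsFactors = FALSE
  )
  attr(df, "meta") <- list(subject = subject, units = "Hz")
  class(df) <- c("pitch_trajectory", "data.frame")
  if (validate) validate_trajectory(df)
  df
}

#' Validate a pitch trajectory
#'
#' Checks the structural invariants: at least two renditions, finite
#' positive pitches, renditions strictly ordered by `(day, h)`, threshold
#' and hit flags jointly present or jointly absent per rendition, and hit
#' flags consistent with the contingency direction where all three are
#' present (ties at the threshold count as escapes).
#'
#' @param traj a `pitch_trajectory`.
#' @return `traj`, invisibly, if valid; otherwise an error naming the
#'   offending row.
#' @export
validate_trajectory <- function(traj) {
  stopifnot(is.data.frame(traj))
  req <- c("day", "h", "pitch", "hit", "threshold", "contingency")
  miss <- setdiff(req, names(traj))
  if (length(miss) > 0)
    stop("trajectory is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(traj) < 2) stop("a trajectory needs at least 2 renditions")
  bad <- which(!is.finite(traj$pitch) | traj$pitch <= 0)
  if (length(bad) > 0)
    stop("non-positive or non-finite pitch at row ", bad[1])
  if (any(traj$h < 0 | traj$h >= 1, na.rm = TRUE))
    stop("time-of-day fraction h must lie in [0, 1)")
  key <- traj$day + traj$h
  if (any(diff(key) <= 0))
    stop("renditions must be strictly ordered by (day, h); violation at row ",
         which(diff(key) <= 0)[1] + 1L)
  thr <- !is.na(traj$threshold)
  hitp <- !is.na(traj$hit)
  if (any(thr != hitp))
    stop("hit and threshold must be jointly present (feedback) or jointly ",
         "absent (baseline); mismatch at row ", which(thr != hitp)[1])
  fb <- which(thr & !is.na(traj$contingency))
  if (length(fb) > 0) {
    expect_hit <- ifelse(traj$contingency[fb] == "low",
                         traj$pitch[fb] < traj$threshold[fb],
                         traj$pitch[fb] > traj$threshold[fb])
    bad <- fb[traj$hit[fb] != expect_hit]
    if (length(bad) > 0)
      stop("hit flag inconsistent with contingency/threshold at row ", bad[1])
  }
  invisible(traj)
}

trajectory_meta <- function(traj) attr(traj, "meta")

#' Read a rendition table from delimited text
#'
#' Reads a CSV/TSV file (delimiter autodetected from the header line) with
#' one row per rendition. Time may be given either as `day` + `h` columns
#' or as a single ISO-8601 `timestamp` column, which is converted to a day
#' index and time-of-day fraction relative to local midnight.
#'
#' @param path path to the delimited file (header required).
#' @param dialect named character vector mapping canonical column names
#'   (`day`, `h`, `timestamp`, `pitch`, `hit`, `threshold`, `contingency`,
#'   `subject`) to the names used in the file. Unmapped names are taken
#'   as-is; the default matches [write_trajectory()] output
#'   (`pitch_hz`, `threshold_hz`).
#' @return a validated [pitch_trajectory()].
#' @export
read_trajectory <- function(path,
                            dialect = c(pitch = "pitch_hz",
                                        threshold = "threshold_hz")) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  pick <- function(canon) {
    nm <- if (canon %in% names(dialect)) dialect[[canon]] else canon
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  pitch <- pick("pitch")
  if (is.null(pitch)) stop("required pitch column not found in ", path)
  day <- pick("day"); h <- pick("h")
  if (is.null(day) || is.null(h)) {
    ts <- pick("timestamp")
    if (is.null(ts))
      stop("need either day+h columns or a timestamp column in ", path)
    tt <- as.POSIXct(ts, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(tt)) stop("unparseable timestamp at row ", which(is.na(tt))[1])
    d0 <- as.Date(tt)
    day <- as.integer(d0 - min(d0))
    h <- as.numeric(difftime(tt, as.POSIXct(paste(d0, "00:00:00"), tz = "UTC"),
                             units = "secs")) / 86400
  }
  hitcol <- pick("hit")
  pitch_trajectory(
    day = day, h = h, pitch = pitch,
    hit = if (is.null(hitcol)) NA else as.logical(hitcol),
    threshold = ifelse0(pick("threshold"), NA_real_),
    contingency = ifelse0(pick("contingency"), NA_character_),
    subject = if (!is.null(pick("subject"))) pick("subject")[1] else NA_character_
  )
}

ifelse0 <- function(x, default) if (is.null(x)) default else x

#' Write a rendition table to delimited text
#'
#' Canonical column order `subject, day, h, pitch_hz, hit, threshold_hz,
#' contingency`, re-readable by [read_trajectory()] with the default
#' dialect. Hit flags are written as 0/1.
#'
#' @param traj a `pitch_trajectory`.
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sep = ",") {
  validate_trajectory(traj)
  meta <- trajectory_meta(traj)
  out <- data.frame(
    subject = if (is.null(meta$subject)) NA_character_ else meta$subject,
    day = traj$day,
    h = traj$h,
    pitch_hz = traj$pitch,
    hit = as.integer(traj$hit),
    threshold_hz = traj$threshold,
    contingency = traj$contingency,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Split a trajectory into baseline and feedback periods
#'
#' The feedback (white-noise conditioning) period is assumed to be a
#' contiguous suffix of the experiment, demarcated by the presence of a
#' threshold. Interleaving baseline renditions after feedback onset is a
#' structural error, not silently reordered.
#'
#' @param traj a `pitch_trajectory`.
#' @return a list with elements `baseline` and `feedback`
#'   (either may have zero rows); their concatenation equals `traj`.
#' @export
split_baseline_feedback <- function(traj) {
  fb <- !is.na(traj$threshold)
  if (any(fb)) {
    onset <- which(fb)[1]
    if (!all(fb[onset:nrow(traj)]))
      stop("baseline rendition after feedback onset (row ",
           onset - 1L + which(!fb[onset:nrow(traj)])[1],
           "); feedback must be a contiguous suffix")
  } else {
    onset <- nrow(traj) + 1L
  }
  subset_traj <- function(idx) {
    out <- traj[idx, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "meta") <- trajectory_meta(traj)
    class(out) <- class(traj)
    out
  }
  list(baseline = subset_traj(seq_len(onset - 1L)),
       feedback = subset_traj(seq(onset, length.out = nrow(traj) - onset + 1L)))
}

#' Singing-history counts
#'
#' For each rendition, the number of target-syllable renditions produced
#' strictly within the preceding `x` seconds (half-open window
#' `(time_t - x, time_t)`), clipped at `N_h - 1` so that the history-offset
#' index `1 + n_h(t)` lies in `{1, ..., N_h}`. Windows never cross the
#' day boundary (birds do not sing overnight).
#'
#' @param traj a `pitch_trajectory`.
#' @param x history horizon in seconds (default 2).
#' @param N_h quantization ceiling (counts clipped to `N_h - 1`).
#' @return integer vector of length `nrow(traj)` with values in
#'   `0:(N_h-1)`.
#' @export
history_counts <- function(traj, x = 2, N_h = 5L) {
  stopifnot(x > 0, N_h >= 1)
  tsec <- traj$h * 86400
  n <- nrow(traj)
  out <- integer(n)
  for (d in unique(traj$day)) {
    idx <- which(traj$day == d)
    tt <- tsec[idx]
    # renditions strictly inside (tt - x, tt); tt is sorted within a day
    lo <- findInterval(tt - x, tt)  # count of tt[j] <= tt[i] - x
    cnt <- (seq_along(tt) - 1L) - lo
    out[idx] <- pmin(cnt, N_h - 1L)
  }
  out
}

#' @export
print.pitch_trajectory <- function(x, ...) {
  meta <- trajectory_meta(x)
  nfb <- sum(!is.na(x$threshold))
  cat(sprintf("<pitch_trajectory> %d renditions over %d day(s)%s\n",
              nrow(x), length(unique(x$day)),
              if (!is.null(meta$subject) && !is.na(meta$subject))
                paste0(", subject ", meta$subject) else ""))
  cat(sprintf("  baseline: %d, feedback: %d renditions\n", nrow(x) - nfb, nfb))
  invisible(x)
}
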