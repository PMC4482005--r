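#' Tri-axial accelerometer recording
#'
#' Container for a body-worn accelerometer recording: three axis series in
#' units of g, a sampling frequency, an optional sensor range and an optional
#' class label. All downstream analysis works on the acceleration sum vector
#' (see [compute_sv()]); the axis decomposition only matters for I/O.
#'
#' @param ax,ay,az numeric vectors of equal length, accelerations in g.
#' @param fs sampling frequency in Hz (positive integer, default 100).
#' @param id optional recording identifier.
#' @param label one of `"fall"`, `"adl"`, `"unknown"`.
#' @param range_g optional sensor saturation magnitude in g (e.g. 2 or 6);
#'   if given, every axis sample must satisfy `|value| <= range_g`.
#' @return An object of class `"recording"`.
#' @examples
#' rec <- recording(ax = c(0.6, 0), ay = c(0.8, 0), az = c(0, 1), fs = 100)
#' compute_sv(rec)$values
#' @export
recording <- function(ax, ay, az, fs = 100L, id = NULL,
                      label = c("unknown", "fall", "adl"), range_g = NULL) {
  label <- match.arg(label)
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(ax)
  if (n < 1L) stop("recording must contain at least one sample", call. = FALSE)
  if (length(ay) != n || length(az) != n)
    stop("axis series must have identical lengths", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0 || fs != round(fs))
    stop("`fs` must be a positive integer sampling frequency in Hz", call. = FALSE)
  if (anyNA(ax) || anyNA(ay) || anyNA(az))
    stop("axis series must not contain missing values", call. = FALSE)
  if (!is.null(range_g)) {
    if (max(abs(ax), abs(ay), abs(az)) > range_g + 1e-9)
      stop("axis values exceed the stated sensor range `range_g`", call. = FALSE)
  }
  structure(
    list(id = if (is.null(id)) NA_character_ else as.character(id),
         fs = as.integer(fs), ax = ax, ay = ay, az = az,
         range_g = range_g, label = label),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d samples @ %d Hz (%.1f s), label = %s\n",
              x$id, length(x$ax), x$fs, length(x$ax) / x$fs, x$label))
  invisible(x)
}

#' @export
length.recording <- function(x) length(x$ax)

#' Acceleration sum vector series
#'
#' @param values non-negative numeric vector, SV samples in g.
#' @param fs sampling frequency in Hz.
#' @return An object of class `"sv_series"`.
#' @export
sv_series <- function(values, fs) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty sum-vector series", call. = FALSE)
  if (any(values < 0)) stop("sum-vector values must be non-negative", call. = FALSE)
  structure(list(fs = as.integer(fs), values = values), class = "sv_series")
}

#' @export
print.sv_series <- function(x, ...) {
  cat(sprintf("<sv_series> %d samples @ %d Hz, range [%.3f, %.3f] g\n",
              length(x$values), x$fs, min(x$values), max(x$values)))
  invisible(x)
}

#' Compute the acceleration sum vector of a recording
#'
#' The sum vector (SV) is the per-sample Euclidean magnitude of the three
#' accelerometer axes, `sqrt(ax^2 + ay^2 + az^2)`, in g. At rest it sits near
#' 1 g (gravity); falls show a dip below and a sharp peak above it.
#'
#' @param rec a [recording()].
#' @return An [sv_series()] with the same length and sampling frequency.
#' @export
compute_sv <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  sv_series(sqrt(rec$ax^2 + rec$ay^2 + rec$az^2), rec$fs)
}

as_sv <- function(x) {
  if (inherits(x, "sv_series")) return(x)
  if (inherits(x, "recording")) return(compute_sv(x))
  stop("expected a recording or sv_series", call. = FALSE)
}

#' Active-period criterion
#'
#' A recording counts as an active period when the range of its sum vector
#' (max minus min) strictly exceeds `threshold_g`. This is the inclusion
#' criterion used to select candidate activity segments from continuous
#' monitoring; a recording at rest (SV constant near 1 g) is not active.
#'
#' @param sv an [sv_series()] (or a [recording()], converted automatically).
#' @param threshold_g range threshold in g (default 1.01).
#' @return `TRUE` iff `max(SV) - min(SV) > threshold_g` (strict).
#' @export
is_active_period <- function(sv, threshold_g = 1.01) {
  sv <- as_sv(sv)
  diff(range(sv$values)) > threshold_g
}

#' Extract a peak-candidate window from a sum-vector series
#'
#' Returns the `duration_s`-second window centered on `center_index`
#' (1-based). The window is the half-open slice
#' `[center_index - h, center_index + h)` with `h = round(duration_s * fs / 2)`
#' so the center sample sits at offset `h + 1` within the window and the
#' length is exactly `round(duration_s * fs)`.
#'
#' If the window would overrun the series, the default policy (`"skip"`)
#' returns `NULL` — the candidate is rejected rather than padded with
#' fabricated samples. `edge_policy = "reflect"` instead pads by reflecting
#' the series at its boundaries.
#'
#' @param sv an [sv_series()].
#' @param center_index 1-based sample index of the window center.
#' @param duration_s window duration in seconds (default 2).
#' @param edge_policy `"skip"` (reject edge-overrunning windows) or
#'   `"reflect"` (reflection padding).
#' @return An object of class `"sv_window"` (fields `fs`, `values`,
#'   `center_index`, `duration_s`), or `NULL` under the skip policy.
#' @export
extract_window <- function(sv, center_index, duration_s = 2,
                           edge_policy = c("skip", "reflect")) {
  sv <- as_sv(sv)
  edge_policy <- match.arg(edge_policy)
  n <- length(sv$values)
  if (center_index < 1L || center_index > n)
    stop("`center_index` out of bounds", call. = FALSE)
  len <- round(duration_s * sv$fs)
  h <- round(len / 2)
  lo <- center_index - h
  hi <- center_index + (len - h) - 1L
  if (lo < 1L || hi > n) {
    if (edge_policy == "skip") return(NULL)
    idx <- seq.int(lo, hi)
    # reflect about the boundaries (sample 1 and sample n act as mirrors)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
    vals <- sv$values[idx]
  } else {
    vals <- sv$values[lo:hi]
  }
  structure(list(fs = sv$fs, values = vals, center_index = center_index,
                 duration_s = duration_s),
            class = "sv_window")
}

#' Read a tri-axial recording from CSV
#'
#' Expects the header `time_s,ax_g,ay_g,az_g` with one row per sample,
#' '.' decimal separator. The sampling frequency is inferred from the median
#' inter-sample interval of the time column; the file is rejected if the time
#' column is non-monotone or if any interval deviates from the median by more
#' than 1% (jitter), since all downstream windows assume uniform sampling.
#'
#' @param path file path.
#' @param id optional identifier (defaults to the file name without extension).
#' @param label optional label, `"fall"`, `"adl"` or `"unknown"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, id = NULL, label = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  if (!identical(names(df)[seq_along(need)], need))
    stop(sprintf("malformed header in %s: expected columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  t <- df$time_s
  if (length(t) >= 2L) {
    dt <- diff(t)
    if (any(dt <= 0)) stop(sprintf("non-monotone time column in %s", path),
                           call. = FALSE)
    med <- stats::median(dt)
    if (any(abs(dt - med) / med > 0.01))
      stop(sprintf("inconsistent sampling interval in %s (> 1%% jitter)", path),
           call. = FALSE)
    fs <- round(1 / med)
  } else {
    fs <- 100L
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  recording(df$ax_g, df$ay_g, df$az_g, fs = fs, id = id, label = label)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]: writes `time_s,ax_g,ay_g,az_g` with the
#' time column reconstructed as `(0:(n-1))/fs`.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  n <- length(rec$ax)
  df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs,
                   ax_g = rec$ax, ay_g = rec$ay, az_g = rec$az)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Labeled dataset of recordings
#'
#' A thin container pairing a list of [recording()] objects with their labels,
#' as produced by [simulate_dataset()] or [read_dataset()].
#'
#' @param recordings list of [recording()] objects.
#' @return An object of class `"fall_dataset"`.
#' @export
fall_dataset <- function(recordings) {
  stopifnot(is.list(recordings), length(recordings) >= 1L,
            all(vapply(recordings, inherits, logical(1), "recording")))
  ids <- vapply(recordings, `[[`, character(1), "id")
  labels <- vapply(recordings, `[[`, character(1), "label")
  structure(list(recordings = recordings, id = ids, label = labels),
            class = "fall_dataset")
}

#' @export
print.fall_dataset <- function(x, ...) {
  cat(sprintf("<fall_dataset> %d recordings (%d falls, %d ADLs, %d unlabeled)\n",
              length(x$recordings), sum(x$label == "fall"),
              sum(x$label == "adl"), sum(x$label == "unknown")))
  invisible(x)
}

#' @export
length.fall_dataset <- function(x) length(x$recordings)

#' Read a dataset from a manifest CSV
#'
#' The manifest has columns `id,path,label` with `label` in
#' `{fall, adl}`; paths are resolved relative to the manifest's directory
#' unless absolute.
#'
#' @param manifest_path path to the manifest CSV.
#' @return A [fall_dataset()].
#' @export
read_dataset <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("id", "path", "label") %in% names(man)))
    stop("manifest must have columns id,path,label", call. = FALSE)
  base <- dirname(manifest_path)
  recs <- vector("list", nrow(man))
  keep <- logical(nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    r <- tryCatch(read_recording(p, id = man$id[i], label = man$label[i]),
                  error = function(e) {
                    warning(sprintf("skipping unreadable recording %s: %s",
                                    man$id[i], conditionMessage(e)),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(r)) { recs[[i]] <- r; keep[i] <- TRUE }
  }
  if (!any(keep)) stop("no readable recordings in manifest", call. = FALSE)
  fall_dataset(recs[keep])
}

#' Write a dataset to a directory
#'
#' Writes one CSV per recording plus a `manifest.csv` (`id,path,label`).
#'
#' @param ds a [fall_dataset()].
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "fall_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- paste0(ds$id, ".csv")
  for (i in seq_along(ds$recordings))
    write_recording(ds$recordings[[i]], file.path(dir, paths[i]))
  man <- data.frame(id = ds$id, path = paths, label = ds$label)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  invisible(mp)
}
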