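#' Feature-extraction configuration
#'
#' Bundles the knobs of the wavelet-feature scan and the LPV search.
#'
#' @param trigger_threshold_g SV value in g above which a sample becomes a
#'   candidate peak and wavelet analysis is run on its centered window
#'   (default 1.5 — low enough that no fall is missed, high enough to skip
#'   quiet stretches).
#' @param window_duration_s candidate window duration in seconds (default 2).
#' @param scan_stride scan stride in samples (default 1: every sample is
#'   inspected; larger values trade fidelity for speed).
#' @param lpv_search_s seconds before the global peak over which the
#'   pre-impact minimum (LPV) is sought (default 1).
#' @param edge_policy candidate windows overrunning the recording are
#'   `"skip"`ped (default) or `"reflect"`-padded.
#' @param scale_step,translation_step CWT grid steps in samples, see
#'   [cwt_grid()].
#' @param cwt_norm CWT normalization, see [cwt_coefficients()].
#' @return An object of class `"feature_config"`.
#' @export
feature_config <- function(trigger_threshold_g = 1.5, window_duration_s = 2,
                           scan_stride = 1L, lpv_search_s = 1,
                           edge_policy = c("skip", "reflect"),
                           scale_step = 1L, translation_step = 1L,
                           cwt_norm = c("inverse_sqrt_scale", "inverse_scale")) {
  stopifnot(trigger_threshold_g > 0, scan_stride >= 1L, window_duration_s > 0,
            lpv_search_s >= 0)
  structure(list(trigger_threshold_g = trigger_threshold_g,
                 window_duration_s = window_duration_s,
                 scan_stride = as.integer(scan_stride),
                 lpv_search_s = lpv_search_s,
                 edge_policy = match.arg(edge_policy),
                 scale_step = as.integer(scale_step),
                 translation_step = as.integer(translation_step),
                 cwt_norm = match.arg(cwt_norm)),
            class = "feature_config")
}

#' Wavelet similarity feature of a recording
#'
#' Scans the sum vector in sample order (stride `cfg$scan_stride`); every
#' sample whose SV exceeds the trigger threshold (1.5 g by default) marks a
#' candidate peak. For each candidate, the 2-second window centered on it is
#' compared to the mother wavelet by computing the CWT coefficients over the
#' restricted scale/translation grid and keeping their maximum. The feature
#' is the overall maximum across all candidates, clipped below at zero; it
#' is zero when no sample ever exceeds the trigger. Higher values mean the
#' recording contains a segment more similar to the prototype fall.
#'
#' @param sv an [sv_series()] or [recording()].
#' @param wavelet a `"fall_wavelet"` or `"mother_wavelet"`.
#' @param cfg a [feature_config()].
#' @return A single non-negative number.
#' @export
wavelet_feature <- function(sv, wavelet, cfg = feature_config()) {
  sv <- as_sv(sv)
  if (inherits(wavelet, "fall_wavelet")) wavelet <- wavelet$wavelet
  grid <- cwt_grid(sv$fs, cfg$scale_step, cfg$translation_step)
  L <- round(cfg$window_duration_s * sv$fs)
  fb <- cwt_filterbank(wavelet, grid, L, cfg$cwt_norm)
  .wavelet_feature_fb(sv, fb, cfg)
}

# Scan using a prebuilt filterbank (shared across the recordings of a
# dataset: building the bank costs more than scoring one window).
.wavelet_feature_fb <- function(sv, fb, cfg) {
  vals <- sv$values
  n <- length(vals)
  L <- fb$L
  h <- round(L / 2)
  scan <- seq.int(1L, n, by = cfg$scan_stride)
  cand <- scan[vals[scan] > cfg$trigger_threshold_g]
  if (length(cand) == 0L) return(0)
  if (cfg$edge_policy == "skip") {
    cand <- cand[cand - h >= 1L & cand + (L - h) - 1L <= n]
    if (length(cand) == 0L) return(0)
    idx <- outer(seq_len(L) - h - 1L, cand, `+`)  # L x k window slices
    wins <- matrix(vals[idx], nrow = L)
  } else {
    wins <- vapply(cand, function(ci)
      extract_window(sv, ci, L / sv$fs, edge_policy = "reflect")$values,
      numeric(L))
    wins <- matrix(wins, nrow = L)
  }
  max(0, max(fb$W %*% wins))
}

#' Upper peak value (UPV)
#'
#' The global maximum of the sum vector, in g — the classic impact-magnitude
#' feature: the sharp deceleration at ground contact drives SV well above
#' the 1 g resting level.
#'
#' @param sv an [sv_series()] or [recording()].
#' @return The maximum SV in g.
#' @export
upv_feature <- function(sv) {
  sv <- as_sv(sv)
  max(sv$values)
}

#' Lower peak value (LPV)
#'
#' The minimum of the sum vector in the `lpv_search_s` seconds immediately
#' preceding (and including) the global maximum — the free-fall dip: during
#' the falling phase the body approaches free fall and SV drops below 1 g
#' before the impact peak. Lower values are more fall-like, so recordings
#' are ranked by `-LPV` when this feature is used as a classifier score.
#'
#' @param sv an [sv_series()] or [recording()].
#' @param cfg a [feature_config()] (only `lpv_search_s` is used).
#' @return The pre-impact minimum SV in g.
#' @export
lpv_feature <- function(sv, cfg = feature_config()) {
  sv <- as_sv(sv)
  peak <- which.max(sv$values)
  from <- max(1L, peak - round(cfg$lpv_search_s * sv$fs))
  min(sv$values[from:peak])
}

#' Per-recording feature table
#'
#' Computes all three features — the wavelet similarity score, UPV and
#' LPV — for every recording of a labeled dataset.
#'
#' @param dataset a [fall_dataset()].
#' @param wavelet a `"fall_wavelet"` or `"mother_wavelet"`.
#' @param cfg a [feature_config()].
#' @return A data.frame with columns `id`, `label`, `wavelet`, `upv_g`,
#'   `lpv_g`, one row per recording (input order preserved).
#' @export
build_feature_table <- function(dataset, wavelet, cfg = feature_config()) {
  stopifnot(inherits(dataset, "fall_dataset"))
  if (inherits(wavelet, "fall_wavelet")) wavelet <- wavelet$wavelet
  n <- length(dataset$recordings)
  out <- data.frame(id = dataset$id, label = dataset$label,
                    wavelet = numeric(n), upv_g = numeric(n),
                    lpv_g = numeric(n))
  banks <- new.env(parent = emptyenv())  # one filterbank per sampling rate
  for (i in seq_len(n)) {
    res <- tryCatch({
      sv <- compute_sv(dataset$recordings[[i]])
      key <- as.character(sv$fs)
      if (is.null(banks[[key]])) {
        grid <- cwt_grid(sv$fs, cfg$scale_step, cfg$translation_step)
        banks[[key]] <- cwt_filterbank(wavelet, grid,
                                       round(cfg$window_duration_s * sv$fs),
                                       cfg$cwt_norm)
      }
      c(.wavelet_feature_fb(sv, banks[[key]], cfg), upv_feature(sv),
        lpv_feature(sv, cfg))
    }, error = function(e) {
      warning(sprintf("skipping recording %s: %s", dataset$id[i],
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) { out$wavelet[i] <- NA } else {
      out$wavelet[i] <- res[1]; out$upv_g[i] <- res[2]; out$lpv_g[i] <- res[3]
    }
  }
  out[!is.na(out$wavelet), , drop = FALSE]
}

#' Score new recordings with a fitted fall wavelet
#'
#' @param object a `"fall_wavelet"` from [fall_wavelet()].
#' @param newdata a [recording()], [sv_series()], or [fall_dataset()].
#' @param cfg a [feature_config()].
#' @param type `"feature"` returns the wavelet similarity score(s);
#'   `"table"` returns the full feature table (datasets only).
#' @param ... unused.
#' @return A numeric vector of scores, or a feature-table data.frame.
#' @export
predict.fall_wavelet <- function(object, newdata, cfg = feature_config(),
                                 type = c("feature", "table"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "fall_dataset")) {
    tab <- build_feature_table(newdata, object, cfg)
    if (type == "table") return(tab)
    return(stats::setNames(tab$wavelet, tab$id))
  }
  if (type == "table")
    stop("`type = \"table\"` requires a fall_dataset", call. = FALSE)
  wavelet_feature(newdata, object, cfg)
}

#' Write a feature table to CSV
#'
#' @param tab a feature-table data.frame from [build_feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(tab, path) {
  utils::write.csv(tab[c("id", "label", "wavelet", "upv_g", "lpv_g")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
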