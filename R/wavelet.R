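#' Average peak-centered fall pattern
#'
#' For each fall, takes the window of `duration_s` seconds centered on the
#' global maximum of its sum vector (first occurrence on ties) and averages
#' these windows sample-wise. The result is the prototype impact morphology:
#' a pre-impact dip, a sharp impact peak at the window center, and damped
#' post-impact oscillation.
#'
#' Falls whose peak sits too close to a recording edge for a full window are
#' excluded with a warning; if all falls are excluded, an error is raised.
#'
#' @param falls list of [sv_series()] or [recording()] objects (falls).
#' @param duration_s window duration in seconds (default 2).
#' @return An object of class `"fall_pattern"`: fields `fs`, `values` (the
#'   per-sample mean, length `round(duration_s * fs)`), `sd` (per-sample
#'   standard deviation, `NA` for a single fall), `n` (number of falls used),
#'   `duration_s`.
#' @export
average_fall_pattern <- function(falls, duration_s = 2) {
  if (!is.list(falls) || length(falls) < 1L)
    stop("need at least one fall recording", call. = FALSE)
  svs <- lapply(falls, as_sv)
  fs <- svs[[1L]]$fs
  if (!all(vapply(svs, `[[`, integer(1), "fs") == fs))
    stop("all falls must share one sampling frequency", call. = FALSE)
  wins <- list()
  for (i in seq_along(svs)) {
    peak <- which.max(svs[[i]]$values)  # first occurrence on ties
    w <- extract_window(svs[[i]], peak, duration_s, edge_policy = "skip")
    if (is.null(w)) {
      warning(sprintf("fall %d excluded: peak window overruns the recording", i),
              call. = FALSE)
      next
    }
    wins[[length(wins) + 1L]] <- w$values
  }
  if (length(wins) == 0L)
    stop("no usable falls: every peak window overruns its recording",
         call. = FALSE)
  m <- do.call(cbind, wins)
  structure(list(fs = fs,
                 values = rowMeans(m),
                 sd = if (ncol(m) > 1L) apply(m, 1L, stats::sd) else
                   rep(NA_real_, nrow(m)),
                 n = ncol(m), duration_s = duration_s),
            class = "fall_pattern")
}

#' @export
print.fall_pattern <- function(x, ...) {
  cat(sprintf("<fall_pattern> mean of %d peak-centered %g-s windows @ %d Hz; peak %.2f g\n",
              x$n, x$duration_s, x$fs, max(x$values)))
  invisible(x)
}

# Cosine ramp that is 0 at both ends of the grid and 1 in the interior,
# rising over `m` points on each side.
taper_window <- function(n, frac = 0.02) {
  m <- max(1L, ceiling(frac * n))
  w <- rep(1, n)
  ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / m))
  w[seq_len(m)] <- ramp
  w[n + 1L - seq_len(m)] <- ramp
  w
}

#' Convert an averaged fall pattern into an admissible mother wavelet
#'
#' The prototype waveform must satisfy the wavelet admissibility condition
#' (zero integral) before it can drive a continuous wavelet transform. The
#' pattern is mean-subtracted and rescaled to the unit interval; the
#' endpoints are tapered to zero over `taper_frac` of the grid on each side
#' (so the wavelet is continuous when extended by zero outside \eqn{[0,1]}),
#' the residual integral introduced by the taper is removed by subtracting a
#' multiple of the taper profile (which preserves the zero endpoints), and
#' the result is scaled to unit discrete L2 norm.
#'
#' The default `method = "direct"` uses the mean-subtracted pattern itself:
#' averaging across training falls already smooths noise, and the conversion
#' must retain the narrow impact spike — the feature of the prototype that
#' distinguishes falls from the wider, smoother transients of daily
#' activities. `method = "polynomial"` instead projects the pattern onto
#' polynomials of degree `poly_degree` by least squares under the linear
#' constraint that the discrete integral of the fit is exactly zero; a
#' low-degree projection yields a smooth analytic wavelet but broadens the
#' impact spike (resolving a feature of relative width \eqn{w} needs degree
#' of order \eqn{1/w}), which blunts discrimination when impacts are sharp.
#'
#' @param pattern a `"fall_pattern"` from [average_fall_pattern()], or any
#'   non-constant numeric vector (interpreted as samples on \eqn{[0,1]}).
#' @param poly_degree polynomial degree of the smoothing projection
#'   (default 6; must be at least 2; only used by `method = "polynomial"`).
#' @param method `"direct"` (default) or `"polynomial"`.
#' @param taper_frac fraction of the grid tapered to zero at each end
#'   (default 0.02).
#' @return An object of class `"mother_wavelet"`: fields `x` (grid on
#'   \eqn{[0,1]}, same length as the pattern), `psi` (ordinates,
#'   dimensionless, zero discrete integral, unit discrete L2 norm),
#'   `fs_source`, `source_duration_s`, `poly_degree`, `method`, `n_falls`,
#'   and `fit_rss` (residual sum of squares of the constrained polynomial
#'   fit to the mean-subtracted pattern; 0 for `method = "direct"`).
#' @export
pattern_to_wavelet <- function(pattern, poly_degree = 6L,
                               method = c("direct", "polynomial"),
                               taper_frac = 0.02) {
  method <- match.arg(method)
  if (inherits(pattern, "fall_pattern")) {
    vals <- pattern$values
    fs_source <- pattern$fs
    dur <- pattern$duration_s
    n_falls <- pattern$n
  } else {
    vals <- as.numeric(pattern)
    fs_source <- NA_integer_; dur <- NA_real_; n_falls <- NA_integer_
  }
  n <- length(vals)
  if (n < 8L) stop("pattern too short to convert", call. = FALSE)
  if (diff(range(vals)) < 1e-12)
    stop("degenerate pattern: constant input has no admissible wavelet",
         call. = FALSE)
  if (method == "polynomial" && poly_degree < 2L)
    stop("`poly_degree` must be at least 2", call. = FALSE)

  x <- seq(0, 1, length.out = n)
  dx <- 1 / (n - 1)
  y <- vals - mean(vals)

  if (method == "polynomial") {
    # Orthogonal-polynomial basis (plus intercept) for numerical stability;
    # constrained LS via the KKT system with constraint sum(B beta) = 0.
    B <- cbind(1, stats::poly(x, degree = poly_degree))
    p <- ncol(B)
    cvec <- colSums(B)
    K <- rbind(cbind(crossprod(B), cvec), c(cvec, 0))
    rhs <- c(crossprod(B, y), 0)
    beta <- solve(K, rhs)[seq_len(p)]
    psi0 <- as.numeric(B %*% beta)
    fit_rss <- sum((y - psi0)^2)
  } else {
    psi0 <- y - mean(y)
    fit_rss <- 0
  }

  w <- taper_window(n, taper_frac)
  psi1 <- psi0 * w
  psi1 <- psi1 - (sum(psi1) / sum(w)) * w  # restore zero integral, endpoints stay 0
  nrm <- sqrt(sum(psi1^2) * dx)
  if (nrm < 1e-10)
    stop("degenerate pattern: projection is numerically zero", call. = FALSE)
  psi <- psi1 / nrm

  structure(list(x = x, psi = psi, fs_source = fs_source,
                 source_duration_s = dur,
                 poly_degree = if (method == "polynomial") as.integer(poly_degree) else NA_integer_,
                 method = method, n_falls = n_falls, fit_rss = fit_rss),
            class = "mother_wavelet")
}

#' @export
print.mother_wavelet <- function(x, ...) {
  dx <- 1 / (length(x$x) - 1)
  cat(sprintf("<mother_wavelet> %d points on [0,1] (%s), integral %.2e, L2 norm %.6f\n",
              length(x$x), x$method, sum(x$psi) * dx, sqrt(sum(x$psi^2) * dx)))
  invisible(x)
}

#' Fit an adapted fall wavelet to a set of fall recordings
#'
#' The central fitting function: averages the peak-centered sum-vector
#' windows of the training falls into a prototype fall pattern and converts
#' it into an admissible mother wavelet (see [average_fall_pattern()] and
#' [pattern_to_wavelet()]). The fitted object scores new recordings by their
#' maximum continuous-wavelet-transform similarity to the prototype via
#' [predict.fall_wavelet()].
#'
#' @param falls the training falls: a [fall_dataset()] (recordings labeled
#'   `"fall"` are used), or a list of [recording()] / [sv_series()] objects.
#' @param duration_s pattern window duration in seconds (default 2).
#' @param poly_degree polynomial degree for the wavelet conversion.
#' @param method wavelet conversion method, see [pattern_to_wavelet()].
#' @param taper_frac endpoint taper fraction, see [pattern_to_wavelet()].
#' @return An object of class `"fall_wavelet"` containing the
#'   `"mother_wavelet"` (`$wavelet`), the averaged `"fall_pattern"`
#'   (`$pattern`) and the call.
#' @seealso [predict.fall_wavelet()], [evaluate_features()]
#' @examples
#' ds <- simulate_dataset(sim_config(n_falls = 3, n_adls = 2, seed = 1))
#' fw <- fall_wavelet(ds)
#' fw
#' predict(fw, ds$recordings[[1]])
#' @export
fall_wavelet <- function(falls, duration_s = 2, poly_degree = 6L,
                         method = c("direct", "polynomial"),
                         taper_frac = 0.02) {
  method <- match.arg(method)
  if (inherits(falls, "fall_dataset")) {
    keep <- falls$label == "fall"
    if (!any(keep)) stop("dataset contains no falls to train on", call. = FALSE)
    falls <- falls$recordings[keep]
  }
  if (inherits(falls, "recording") || inherits(falls, "sv_series"))
    falls <- list(falls)
  pat <- average_fall_pattern(falls, duration_s = duration_s)
  wav <- pattern_to_wavelet(pat, poly_degree = poly_degree, method = method,
                            taper_frac = taper_frac)
  structure(list(wavelet = wav, pattern = pat, call = match.call()),
            class = "fall_wavelet")
}

#' @export
print.fall_wavelet <- function(x, ...) {
  cat("Adapted fall wavelet\n")
  cat(sprintf("  trained on %d fall(s), %g-s peak-centered windows @ %d Hz\n",
              x$pattern$n, x$pattern$duration_s, x$pattern$fs))
  cat(sprintf("  conversion: %s%s, %d grid points on [0,1]\n",
              x$wavelet$method,
              if (x$wavelet$method == "polynomial")
                sprintf(" (degree %d)", x$wavelet$poly_degree) else "",
              length(x$wavelet$psi)))
  invisible(x)
}

#' @export
summary.fall_wavelet <- function(object, ...) {
  print(object)
  p <- object$pattern
  cat(sprintf("  pattern: peak %.2f g, pre-impact min %.2f g\n",
              max(p$values), min(p$values[seq_len(which.max(p$values))])))
  dx <- 1 / (length(object$wavelet$x) - 1)
  cat(sprintf("  wavelet: integral %.2e, L2 norm %.6f\n",
              sum(object$wavelet$psi) * dx,
              sqrt(sum(object$wavelet$psi^2) * dx)))
  invisible(object)
}

#' @export
coef.fall_wavelet <- function(object, ...) object$wavelet$psi

#' Plot a fitted fall wavelet
#'
#' Two panels: the averaged fall pattern (with a ±1 SD band when available)
#' and the adapted mother wavelet on \eqn{[0,1]}.
#'
#' @param x a `"fall_wavelet"`.
#' @param ... passed to [plot()].
#' @export
plot.fall_wavelet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  p <- x$pattern
  t <- (seq_along(p$values) - 1) / p$fs - p$duration_s / 2
  graphics::plot(t, p$values, type = "l", xlab = "time from peak (s)",
                 ylab = "SV (g)", main = "Average fall pattern", ...)
  if (!anyNA(p$sd)) {
    graphics::lines(t, p$values + p$sd, lty = 3)
    graphics::lines(t, p$values - p$sd, lty = 3)
  }
  graphics::plot(x$wavelet$x, x$wavelet$psi, type = "l", xlab = "x",
                 ylab = expression(psi(x)), main = "Adapted mother wavelet", ...)
  invisible(x)
}

#' Write / read a mother wavelet
#'
#' Serializes the wavelet as a CSV with columns `x,psi` plus a JSON sidecar
#' (same path with extension `.json`) holding `fs_source`,
#' `source_duration_s`, `poly_degree`, `method` and `n_falls`.
#'
#' @param wavelet a `"mother_wavelet"` or `"fall_wavelet"`.
#' @param path CSV output path.
#' @return `path`, invisibly (for the writer); a `"mother_wavelet"` (reader).
#' @export
write_wavelet <- function(wavelet, path) {
  if (inherits(wavelet, "fall_wavelet")) wavelet <- wavelet$wavelet
  stopifnot(inherits(wavelet, "mother_wavelet"))
  utils::write.csv(data.frame(x = wavelet$x, psi = wavelet$psi), path,
                   row.names = FALSE, quote = FALSE)
  side <- wavelet[c("fs_source", "source_duration_s", "poly_degree",
                    "method", "n_falls")]
  jsonlite::write_json(side, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, null = "null", na = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_wavelet
#' @export
read_wavelet <- function(path) {
  df <- utils::read.csv(path)
  side_path <- sub("\\.[^.]*$", ".json", path)
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  g <- function(k, default) if (!is.null(side[[k]])) side[[k]] else default
  structure(list(x = df$x, psi = df$psi,
                 fs_source = as.integer(g("fs_source", NA)),
                 source_duration_s = as.numeric(g("source_duration_s", NA)),
                 poly_degree = as.integer(g("poly_degree", NA)),
                 method = as.character(g("method", "polynomial")),
                 n_falls = as.integer(g("n_falls", NA))),
            class = "mother_wavelet")
}
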