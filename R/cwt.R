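#' Scale/translation grid for the restricted CWT
#'
#' The mother wavelet lives on \eqn{[0,1]} and was generated from a pattern
#' of `duration_s` seconds, so a signal with the prototype's shape matches
#' best at the sample scale `a = duration_s * fs` (2 Fs by default). The
#' search is therefore restricted to scales in `[1.5 fs, 2.5 fs]` (an
#' interval of half-width 0.5 Fs centered on 2 Fs) and, because both the
#' candidate window and the prototype are peak-centered, to translations in
#' `[0.5 fs, 1.5 fs]` — coefficients nearer the window borders are discarded
#' to avoid border effects.
#'
#' @param fs sampling frequency in Hz.
#' @param scale_step,translation_step grid steps in samples (default 1).
#' @return An object of class `"cwt_grid"` with integer fields `scales`
#'   and `translations`.
#' @export
cwt_grid <- function(fs, scale_step = 1L, translation_step = 1L) {
  stopifnot(fs > 0, scale_step >= 1L, translation_step >= 1L)
  scales <- seq.int(round(1.5 * fs), round(2.5 * fs), by = scale_step)
  translations <- seq.int(round(0.5 * fs), round(1.5 * fs), by = translation_step)
  if (length(scales) == 0L || length(translations) == 0L)
    stop("empty CWT grid", call. = FALSE)
  structure(list(scales = as.integer(scales),
                 translations = as.integer(translations)),
            class = "cwt_grid")
}

#' @export
print.cwt_grid <- function(x, ...) {
  cat(sprintf("<cwt_grid> %d scales in [%d, %d], %d translations in [%d, %d] (samples)\n",
              length(x$scales), min(x$scales), max(x$scales),
              length(x$translations), min(x$translations), max(x$translations)))
  invisible(x)
}

# Evaluate the mother wavelet at arbitrary arguments by linear interpolation
# of its samples on [0,1]; zero outside [0,1].
psi_eval <- function(wavelet, u) {
  out <- numeric(length(u))
  ok <- u >= 0 & u <= 1
  if (any(ok))
    out[ok] <- stats::approx(wavelet$x, wavelet$psi, xout = u[ok],
                             method = "linear", rule = 2)$y
  out
}

# The dilated/translated wavelet sampled at integer window positions
# t = 0..L-1 (0-based): psi((t - b)/a + 1/2), support [b - a/2, b + a/2].
# The translation b is the *center* of the dilated wavelet within the
# window, so b = fs aligns the wavelet's center (the prototype peak at
# x = 1/2) with the center of a 2-second window — which is where the
# candidate peak sits and why the translation box brackets fs.
dilated_row <- function(wavelet, a, b, L) {
  t <- seq_len(L) - 1
  psi_eval(wavelet, (t - b) / a + 0.5)
}

# Full bank of dilated wavelets for a grid: matrix with one row per
# (scale, translation) pair (scale-major order) and L columns. Each row is
# the sampled, window-truncated wavelet, re-centered to zero mean over the
# window (discrete admissibility must hold exactly even where the dilated
# support is cut by the window edge, otherwise the resting 1 g baseline
# leaks into the coefficients), then weighted by the scale normalization:
# the energy convention divides by the row's exact discrete L2 norm (the
# discrete realization of 1/sqrt(a), since ||psi((.-b)/a)||_2 = sqrt(a) for
# the unit-norm continuous wavelet), the as-printed convention by the scale
# itself. Scoring a window is then a single matrix-vector product.
cwt_filterbank <- function(wavelet, grid, L,
                           norm = c("inverse_sqrt_scale", "inverse_scale")) {
  norm <- match.arg(norm)
  nA <- length(grid$scales); nB <- length(grid$translations)
  t <- seq_len(L) - 1
  W <- matrix(0, nrow = nA * nB, ncol = L)
  for (i in seq_len(nA)) {
    a <- grid$scales[i]
    # args: nB x L matrix of (t - b)/a + 1/2
    args <- outer(-grid$translations, t, `+`) / a + 0.5
    M <- matrix(psi_eval(wavelet, args), nrow = nB)
    M <- M - rowMeans(M)
    fac <- if (norm == "inverse_sqrt_scale") 1 / sqrt(rowSums(M^2)) else
      rep(1 / a, nB)
    W[(i - 1L) * nB + seq_len(nB), ] <- fac * M
  }
  structure(list(W = W, scales = grid$scales, translations = grid$translations,
                 L = L, norm = norm), class = "cwt_filterbank")
}

#' CWT coefficients of a candidate window against the fall wavelet
#'
#' Computes, for every scale `a` and translation `b` of the grid, the
#' discrete analogue of
#' \deqn{C(a,b) = \frac{1}{a} \int SV(t)\, \psi\!\left(\frac{t-b}{a}\right) dt,}
#' as a Riemann sum with \eqn{\Delta t} of one sample: the wavelet samples
#' are linearly interpolated at \eqn{(t-b)/a + 1/2} (so `b` is the center of
#' the dilated wavelet's support \eqn{[b-a/2,\, b+a/2]} inside the window)
#' and zero outside \eqn{[0,1]}; signal samples beyond the window are treated
#' as zero. Each sampled, truncated wavelet is re-centered to zero mean over
#' the window before the sum, so the admissibility condition holds exactly
#' in the discretization and a constant baseline (the resting 1 g) cannot
#' leak into the coefficients even at scales whose support is cut by the
#' window edge. The coefficient measures the similarity of the window to the
#' scaled, shifted prototype — the larger, the more fall-like.
#'
#' The default normalization `"inverse_sqrt_scale"` divides each coefficient
#' by the exact discrete L2 norm of the sampled wavelet — the discrete
#' realization of the energy-preserving \eqn{1/\sqrt{a}} convention, since
#' \eqn{\|\psi((\cdot-b)/a)\|_2 = \sqrt{a}} for the unit-norm prototype.
#' With unit energy at every scale the coefficient of a self-similar input
#' peaks exactly at the generating scale and translation (Cauchy–Schwarz),
#' which is what makes the restricted search box meaningful.
#' `norm = "inverse_scale"` weights by \eqn{1/a} instead; it tilts the scale
#' profile toward small scales and is kept as a convention option. The
#' choice rescales coefficients per scale and so only shifts score
#' thresholds.
#'
#' @param window an `"sv_window"` from [extract_window()], or a numeric
#'   vector of SV samples.
#' @param wavelet a `"mother_wavelet"` or `"fall_wavelet"`.
#' @param grid a [cwt_grid()].
#' @param norm `"inverse_sqrt_scale"` (default) or `"inverse_scale"`.
#' @return An object of class `"cwt_coefficients"`: a numeric matrix
#'   (rows = scales, columns = translations) with the grid stored in
#'   attributes.
#' @export
cwt_coefficients <- function(window, wavelet, grid,
                             norm = c("inverse_sqrt_scale", "inverse_scale")) {
  norm <- match.arg(norm)
  if (inherits(wavelet, "fall_wavelet")) wavelet <- wavelet$wavelet
  v <- if (inherits(window, "sv_window")) window$values else as.numeric(window)
  stopifnot(inherits(grid, "cwt_grid"), length(v) >= 1L)
  fb <- cwt_filterbank(wavelet, grid, length(v), norm)
  cf <- fb$W %*% v
  m <- matrix(cf, nrow = length(grid$scales), ncol = length(grid$translations),
              byrow = TRUE)
  dimnames(m) <- list(scale = grid$scales, translation = grid$translations)
  structure(m, class = c("cwt_coefficients", class(m)),
            scales = grid$scales, translations = grid$translations, norm = norm)
}

#' Maximum CWT coefficient and its grid location
#'
#' Returns the signed maximum (not the absolute maximum: anti-correlated
#' windows should score low) over the restricted scale/translation grid,
#' taking the first occurrence — scanning scales in increasing order and
#' translations within each scale — on exact ties.
#'
#' @param coeffs a `"cwt_coefficients"` matrix.
#' @return A list with `value`, `scale` and `translation`.
#' @export
max_coefficient <- function(coeffs) {
  stopifnot(inherits(coeffs, "cwt_coefficients"), length(coeffs) >= 1L)
  m <- t(unclass(coeffs))  # column-major scan of t(m): translations fastest
  k <- which.max(m)
  j <- (k - 1L) %/% nrow(m) + 1L  # scale index
  i <- (k - 1L) %% nrow(m) + 1L   # translation index
  list(value = m[k], scale = attr(coeffs, "scales")[j],
       translation = attr(coeffs, "translations")[i])
}
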