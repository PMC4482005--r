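#' Simulation configuration
#'
#' Parameters of the synthetic fall / ADL generator. Recordings are one
#' minute at 100 Hz by default, mirroring body-worn monitoring practice:
#' fall recordings are centered on the impact; ADL recordings are active
#' periods (sum-vector range above 1.01 g) without a fall's dip-then-sharp-peak
#' signature.
#'
#' Falls: the designed SV rests at 1 g, dips to a lower peak value (LPV,
#' drawn from `lpv_range`) over `dip_duration_s` as the body approaches free
#' fall, spikes to an upper peak value (UPV, from `upv_range`) over the
#' short `impact_duration_s`, rings down as a damped oscillation and returns
#' to rest. ADLs: a gait-band sinusoid (frequency `gait_freq_hz`, amplitude
#' `gait_amp_g`) around 1 g plus occasional smooth transients (sitting down,
#' bumps) of height `spike_height_g` above baseline and width
#' `spike_width_s` — markedly wider and smoother than an impact spike, with
#' no preceding free-fall dip.
#'
#' @param fs sampling frequency in Hz (default 100).
#' @param duration_s recording duration in seconds (default 60).
#' @param n_falls,n_adls number of recordings per class (defaults 29 and 200).
#' @param seed integer seed (default 1).
#' @param lpv_range free-fall dip minimum, g (default \[0.2, 0.8\]).
#' @param upv_range impact peak, g (default \[2, 6\]).
#' @param dip_duration_s pre-impact dip duration, s (default \[0.2, 0.4\]).
#' @param impact_duration_s impact spike duration, s (default \[0.05, 0.15\]).
#' @param ring_freq_hz post-impact oscillation frequency, Hz (default \[3, 8\]).
#' @param ring_tau_s oscillation damping time constant, s (default \[0.2, 0.5\]).
#' @param impact_jitter_s impact time uniform jitter around the recording
#'   midpoint, s (default 5).
#' @param gait_freq_hz ADL gait frequency, Hz (default \[1.5, 2.5\]).
#' @param gait_amp_g ADL gait amplitude, g (default \[0.2, 0.6\]).
#' @param spike_rate_per_min expected number of ADL transients per minute
#'   (Poisson, default 2).
#' @param spike_height_g ADL transient height above baseline, g (default
#'   \[0.3, 2\]: peaks up to 3 g, overlapping the fall UPV range).
#' @param spike_width_s ADL transient Gaussian width (SD), s (default
#'   \[0.15, 0.5\]).
#' @param noise_sd additive Gaussian noise SD on the designed SV, g
#'   (default 0.02).
#' @param clip_g optional sensor range in g (e.g. 2): axis outputs are
#'   saturated at +/- `clip_g` after decomposition.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(fs = 100L, duration_s = 60, n_falls = 29L,
                       n_adls = 200L, seed = 1L,
                       lpv_range = c(0.2, 0.8), upv_range = c(2, 6),
                       dip_duration_s = c(0.2, 0.4),
                       impact_duration_s = c(0.05, 0.15),
                       ring_freq_hz = c(3, 8), ring_tau_s = c(0.2, 0.5),
                       impact_jitter_s = 5,
                       gait_freq_hz = c(1.5, 2.5), gait_amp_g = c(0.2, 0.6),
                       spike_rate_per_min = 2,
                       spike_height_g = c(0.3, 2), spike_width_s = c(0.15, 0.5),
                       noise_sd = 0.02, clip_g = NULL) {
  if (max(lpv_range) >= 1)
    stop("infeasible `lpv_range`: the free-fall dip must stay below 1 g",
         call. = FALSE)
  if (min(upv_range) <= 1.5)
    stop("infeasible `upv_range`: the impact peak must exceed the 1.5 g trigger",
         call. = FALSE)
  stopifnot(fs > 0, duration_s > 0, noise_sd >= 0, spike_rate_per_min >= 0)
  structure(as.list(environment()), class = "sim_config")
}

runif_range <- function(r) if (length(r) == 1L) r else stats::runif(1, r[1], r[2])

# Decompose a designed SV into three axes: a slowly drifting unit direction
# (smoothed random walk on the sphere) scaled by SV, so the root sum of
# squares reproduces the design exactly.
decompose_axes <- function(sv_values, fs, clip_g = NULL) {
  n <- length(sv_values)
  drift <- function() {
    w <- stats::rnorm(ceiling(n / fs) + 2L)      # one step per second
    stats::spline(seq_along(w), w, n = n)$y      # smooth to sample rate
  }
  d <- cbind(stats::rnorm(1) + drift(), stats::rnorm(1) + drift(),
             stats::rnorm(1) + drift())
  d <- d / sqrt(rowSums(d^2))
  ax <- d * sv_values
  if (!is.null(clip_g)) ax <- pmin(pmax(ax, -clip_g), clip_g)
  list(ax = ax[, 1], ay = ax[, 2], az = ax[, 3])
}

# Designed (noise-free) fall SV: rest at 1 g, cosine-eased dip to LPV,
# sharp impact spike to UPV, damped ringing, rest.
design_fall_sv <- function(cfg) {
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  lpv <- runif_range(cfg$lpv_range)
  upv <- runif_range(cfg$upv_range)
  dip_n <- round(runif_range(cfg$dip_duration_s) * fs)
  imp_n <- max(3L, round(runif_range(cfg$impact_duration_s) * fs))
  f_ring <- runif_range(cfg$ring_freq_hz)
  tau <- runif_range(cfg$ring_tau_s)
  tc <- round(n / 2 + stats::runif(1, -1, 1) * cfg$impact_jitter_s * fs)

  sv <- rep(1, n)
  # falling-phase dip ending just before the impact spike
  half_imp <- round(imp_n / 2)
  dip_end <- tc - half_imp
  if (dip_end - dip_n < 1L || tc + imp_n + 1L > n)
    stop("recording too short for the drawn fall morphology", call. = FALSE)
  dip_idx <- seq.int(dip_end - dip_n + 1L, dip_end)
  sv[dip_idx] <- lpv + (1 - lpv) * (1 + cos(pi * seq_along(dip_idx) / dip_n)) / 2
  # impact spike: raised-cosine from LPV up to UPV and back down to 1
  up_idx <- seq.int(dip_end + 1L, tc)
  sv[up_idx] <- lpv + (upv - lpv) *
    (1 - cos(pi * seq_along(up_idx) / length(up_idx))) / 2
  down_n <- imp_n - half_imp
  down_idx <- seq.int(tc + 1L, tc + down_n)
  sv[down_idx] <- 1 + (upv - 1) * (1 + cos(pi * seq_along(down_idx) / down_n)) / 2
  # damped post-impact ringing around 1 g, amplitude capped so the ring
  # never undercuts the free-fall dip or rivals the impact peak
  amp <- min(0.25 * (upv - 1), 0.6, 0.9 * (1 - lpv))
  ring_idx <- seq.int(tc + down_n + 1L, min(n, tc + down_n + round(5 * tau * fs)))
  tr <- (seq_along(ring_idx)) / fs
  sv[ring_idx] <- 1 + amp * exp(-tr / tau) * cos(2 * pi * f_ring * tr)
  list(sv = pmax(sv, 0.02), upv = upv, lpv = lpv)
}

#' Simulate a fall recording
#'
#' Draws fall parameters from `cfg`, designs the noise-free SV (see
#' [sim_config()]), adds Gaussian noise, and decomposes it into three axes
#' whose root sum of squares reproduces the designed SV. Uses the current
#' RNG state; seed at the dataset level via [simulate_dataset()].
#'
#' @param cfg a [sim_config()].
#' @param id optional recording id.
#' @return A [recording()] labeled `"fall"`, with attributes `"upv"` and
#'   `"lpv"` holding the drawn ground-truth parameters.
#' @export
simulate_fall <- function(cfg = sim_config(), id = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  des <- design_fall_sv(cfg)
  sv <- des$sv
  if (cfg$noise_sd > 0)
    sv <- pmax(sv + stats::rnorm(length(sv), 0, cfg$noise_sd), 0.01)
  axes <- decompose_axes(sv, cfg$fs, cfg$clip_g)
  rec <- recording(axes$ax, axes$ay, axes$az, fs = cfg$fs, id = id,
                   label = "fall", range_g = cfg$clip_g)
  attr(rec, "upv") <- des$upv
  attr(rec, "lpv") <- des$lpv
  rec
}

design_adl_sv <- function(cfg) {
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  amp <- runif_range(cfg$gait_amp_g)
  freq <- runif_range(cfg$gait_freq_hz)
  phase <- stats::runif(1, 0, 2 * pi)
  env <- 0.7 + 0.3 * abs(sin(2 * pi * t / cfg$duration_s * stats::runif(1, 1, 3)))
  sv <- 1 + amp * env * sin(2 * pi * freq * t + phase)
  k <- stats::rpois(1, cfg$spike_rate_per_min * cfg$duration_s / 60)
  for (i in seq_len(k)) {
    h <- runif_range(cfg$spike_height_g)
    w <- runif_range(cfg$spike_width_s)
    ctr <- stats::runif(1, 2, cfg$duration_s - 2)
    sv <- sv + h * exp(-(t - ctr)^2 / (2 * w^2))
  }
  pmax(sv, 0.02)
}

#' Simulate an ADL recording
#'
#' Generates an activity-of-daily-living recording (gait sinusoid plus
#' occasional smooth transients, see [sim_config()]) and regenerates until
#' the active-period criterion (SV range > 1.01 g) holds, as the real ADL
#' sets are selected that way.
#'
#' @param cfg a [sim_config()].
#' @param id optional recording id.
#' @param max_retries attempts before giving up (default 50).
#' @return A [recording()] labeled `"adl"` satisfying [is_active_period()].
#' @export
simulate_adl <- function(cfg = sim_config(), id = NULL, max_retries = 50L) {
  stopifnot(inherits(cfg, "sim_config"))
  for (i in seq_len(max_retries)) {
    sv <- design_adl_sv(cfg)
    if (cfg$noise_sd > 0)
      sv <- pmax(sv + stats::rnorm(length(sv), 0, cfg$noise_sd), 0.01)
    if (diff(range(sv)) > 1.01) {
      axes <- decompose_axes(sv, cfg$fs, cfg$clip_g)
      return(recording(axes$ax, axes$ay, axes$az, fs = cfg$fs, id = id,
                       label = "adl", range_g = cfg$clip_g))
    }
  }
  stop("could not generate an active ADL within `max_retries` attempts; ",
       "gait amplitude and transients too weak", call. = FALSE)
}

#' Simulate a labeled fall/ADL dataset
#'
#' Generates `n_falls` fall and `n_adls` ADL recordings, fully reproducible
#' from `cfg$seed` (the caller's RNG state is untouched).
#'
#' @param cfg a [sim_config()].
#' @return A [fall_dataset()]; write to disk with [write_dataset()].
#' @examples
#' ds <- simulate_dataset(sim_config(n_falls = 3, n_adls = 3, seed = 7))
#' table(ds$label)
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    falls <- lapply(seq_len(cfg$n_falls), function(i)
      simulate_fall(cfg, id = sprintf("fall_%03d", i)))
    adls <- lapply(seq_len(cfg$n_adls), function(i)
      simulate_adl(cfg, id = sprintf("adl_%03d", i)))
    fall_dataset(c(falls, adls))
  })
}
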