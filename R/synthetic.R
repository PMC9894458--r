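# Stated-world defaults for the generator: a 40-50 Hz vibration-driven
# quasi-periodic carrier whose dominant spectral peak moves up after the
# occlusion, with mild amplitude growth, slow amplitude modulation, slow
# frequency drift and broadband noise. Values are fixed a priori (see the
# methods vignette) and are not tuning knobs.
DEFAULT_STAGE_SHIFT <- stats::setNames(
  c(0, 8.0, 8.8, 9.6, 10.4, 11.2, 12.0, 12.8, 13.6), STAGES)
DEFAULT_STAGE_GAIN <- stats::setNames(
  c(1, 1.05, 1.08, 1.10, 1.12, 1.14, 1.15, 1.16, 1.17), STAGES)

#' Configuration for one synthetic leg
#'
#' Describes the generative model for one leg's nine stage recordings:
#' \deqn{y(t) = g_s \sum_h a_h \sin(h\,\phi_s(t) + \varphi_h)\,
#'       (1 + m \sin(2\pi f_m t + \varphi_m)) + \epsilon(t)}
#' where the instantaneous frequency \eqn{\dot\phi_s/2\pi} is
#' `f_vib + stage_peak_shift[s]` plus a slow Ornstein-Uhlenbeck drift, and
#' \eqn{\epsilon} is white Gaussian noise. Stage `T-1` has zero shift; the
#' post-occlusion stages shift the carrier upward, reproducing the
#' observed before/after peak displacement.
#'
#' @param pig_id,leg Identity of the generated leg.
#' @param fs Sampling rate, Hz.
#' @param duration_s Seconds of signal per stage (protocol default 120).
#' @param f_vib Carrier frequency in Hz; `NULL` draws it uniformly from
#'   `[40, 50]` (motors differ per leg with attachment pressure and skin).
#' @param harmonics Relative amplitudes of the carrier harmonics.
#' @param stage_peak_shift Named vector, additive carrier shift in Hz per
#'   stage (0 at `T-1`).
#' @param stage_gain Named vector, amplitude multiplier per stage.
#' @param noise_sd Standard deviation of the broadband noise (signal units;
#'   the carrier base amplitude is 0.5).
#' @param drift_sd,drift_tau Stationary SD (Hz) and correlation time (s) of
#'   the slow frequency drift; the drift is what makes neighbouring late
#'   stages overlap.
#' @param mod_depth,mod_freq Depth and frequency (Hz) of the slow amplitude
#'   modulation.
#' @param pc_std_trend Optional named per-stage multiplier on the
#'   modulation depth, shaping segment-to-segment feature variance.
#' @param seed Integer seed; the whole leg is a deterministic function of
#'   the config.
#' @return A `synthetic_leg_config`.
#' @export
synthetic_leg_config <- function(pig_id = "S1", leg = "L", fs = 1000,
                                 duration_s = 120, f_vib = NULL,
                                 harmonics = c(1, 0.3, 0.1),
                                 stage_peak_shift = DEFAULT_STAGE_SHIFT,
                                 stage_gain = DEFAULT_STAGE_GAIN,
                                 noise_sd = 0.2, drift_sd = 0.5,
                                 drift_tau = 5, mod_depth = 0.15,
                                 mod_freq = 0.7, pc_std_trend = NULL,
                                 seed = 1L) {
  if (duration_s * fs < 400) {
    stopf("duration_s * fs must be at least 400 samples")
  }
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (!is.null(f_vib) && (f_vib < 40 || f_vib > 50)) {
    warning("f_vib outside the measured 40-50 Hz motor range",
            call. = FALSE)
  }
  if (is.null(names(stage_peak_shift)) ||
      !all(STAGES %in% names(stage_peak_shift))) {
    stopf("stage_peak_shift must be named with all stage labels")
  }
  if (is.null(names(stage_gain)) || !all(STAGES %in% names(stage_gain))) {
    stopf("stage_gain must be named with all stage labels")
  }
  if (is.null(pc_std_trend)) {
    pc_std_trend <- stats::setNames(rep(1, 9), STAGES)
  }
  structure(
    list(pig_id = pig_id, leg = leg, fs = fs, duration_s = duration_s,
         f_vib = f_vib, harmonics = harmonics,
         stage_peak_shift = stage_peak_shift[STAGES],
         stage_gain = stage_gain[STAGES], noise_sd = noise_sd,
         drift_sd = drift_sd, drift_tau = drift_tau,
         mod_depth = mod_depth, mod_freq = mod_freq,
         pc_std_trend = pc_std_trend[STAGES], seed = as.integer(seed)),
    class = "synthetic_leg_config"
  )
}

# AR(1)-discretized Ornstein-Uhlenbeck process with stationary sd `sd`
# and correlation time `tau` seconds.
ou_drift <- function(n, sd, tau, fs) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-1 / (tau * fs))
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive",
                           init = stats::rnorm(1, sd = sd)))
}

#' Generate one synthetic leg
#'
#' Deterministic in the config seed: carrier phase offsets are drawn once
#' per leg, then each stage's trace is synthesized as a harmonic carrier
#' at `f_vib + shift(stage)` with slow frequency drift, slow amplitude
#' modulation, a stage gain and additive Gaussian noise.
#'
#' @param config A [synthetic_leg_config].
#' @return A [leg_dataset] with all nine stages.
#' @export
generate_leg <- function(config) {
  stopifnot(inherits(config, "synthetic_leg_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  base_amp <- 0.5  # arbitrary units, loosely anchored to the motor stroke
  with_seed(derive_seed(config$seed, 7L), {
    f_vib <- if (is.null(config$f_vib)) stats::runif(1, 40, 50)
             else config$f_vib
    phase0 <- stats::runif(length(config$harmonics), 0, 2 * pi)
    recs <- lapply(STAGES, function(s) {
      f_s <- f_vib + config$stage_peak_shift[[s]]
      drift <- ou_drift(n, config$drift_sd, config$drift_tau, fs)
      phi <- 2 * pi * cumsum(f_s + drift) / fs
      t <- (seq_len(n) - 1) / fs
      carrier <- numeric(n)
      for (h in seq_along(config$harmonics)) {
        carrier <- carrier +
          config$harmonics[h] * sin(h * phi + phase0[h])
      }
      depth <- config$mod_depth * config$pc_std_trend[[s]]
      am <- 1 + depth * sin(2 * pi * config$mod_freq * t +
                              stats::runif(1, 0, 2 * pi))
      y <- base_amp * config$stage_gain[[s]] * carrier * am +
        stats::rnorm(n, sd = config$noise_sd)
      emg_recording(y, s, pig_id = config$pig_id, leg = config$leg, fs = fs)
    })
    leg_dataset(recs)
  })
}

#' Generate a cohort of synthetic legs
#'
#' Emulates the 8-leg (4 pigs x left/right) design. Each leg gets its own
#' carrier frequency and gain jitter; with `shared_effect = TRUE` every
#' leg receives the same stage shift schedule, so a classifier trained on
#' some legs transfers to the rest. `heterogeneity` scales all
#' leg-specific perturbations: carrier spread around 45 Hz (up to +/- 5 Hz
#' at 1), gain jitter, and a leg-specific multiplier on the shift schedule
#' (`1 + heterogeneity * z`, `z ~ N(0, 0.3)`), so large values flip effect
#' signs for some legs. With `shared_effect = FALSE`, alternating legs
#' have the `T-1` and `T1` schedule entries (shift and gain) swapped:
#' the baseline then carries the high carrier in half the cohort, so the
#' class-conditional feature distributions pooled across legs are
#' symmetric and cross-leg (binary LOLO) transfer collapses toward
#' chance, while within-leg separability is untouched.
#'
#' @param n_legs Number of legs (default 8; ids P1-L, P1-R, P2-L, ...).
#' @param shared_effect Do all legs share the stage-shift schedule?
#' @param heterogeneity Non-negative scale of leg-specific perturbations
#'   (0 = statistically identical legs up to seeds).
#' @param seed Integer seed.
#' @param duration_s Seconds per stage, passed to each leg config.
#' @param ... Further arguments forwarded to [synthetic_leg_config].
#' @return List of [leg_dataset]s.
#' @export
generate_cohort <- function(n_legs = 8L, shared_effect = TRUE,
                            heterogeneity = 1, seed = 1L,
                            duration_s = 120, ...) {
  n_legs <- as.integer(n_legs)
  if (n_legs < 2) stopf("a cohort needs at least 2 legs")
  if (heterogeneity < 0) stopf("heterogeneity must be non-negative")
  draws <- with_seed(derive_seed(seed, 99L), list(
    f_dev = stats::runif(n_legs, -5, 5),
    gain_jit = stats::rnorm(n_legs, 0, 0.05),
    shift_z = stats::rnorm(n_legs, 0, 0.3)
  ))
  lapply(seq_len(n_legs), function(i) {
    pig <- paste0("P", (i + 1L) %/% 2L)
    side <- if (i %% 2L == 1L) "L" else "R"
    f_vib <- max(40, min(50, 45 + min(1, heterogeneity) * draws$f_dev[i]))
    mult <- 1 + heterogeneity * draws$shift_z[i]
    shift <- DEFAULT_STAGE_SHIFT * mult
    gain <- DEFAULT_STAGE_GAIN * (1 + heterogeneity * draws$gain_jit[i])
    if (!shared_effect && i %% 2L == 0L) {
      shift[c("T-1", "T1")] <- shift[c("T1", "T-1")]
      gain[c("T-1", "T1")] <- gain[c("T1", "T-1")]
    }
    cfg <- synthetic_leg_config(
      pig_id = pig, leg = side, duration_s = duration_s, f_vib = f_vib,
      stage_peak_shift = shift, stage_gain = gain,
      seed = derive_seed(seed, 200L + i), ...)
    generate_leg(cfg)
  })
}
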