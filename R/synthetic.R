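# Seeded generator of activity-like tri-axial accelerometer signals, the
# test bed for every other module: quasi-periodic dynamic classes (gait-like
# harmonics) and near-static classes (gravity offset plus low-amplitude
# postural sway), with per-subject amplitude/frequency jitter.

#' Default activity class specifications
#'
#' Six classes mirroring common activity-recognition benchmarks: four dynamic
#' (distinct fundamental frequencies with decaying harmonics and
#' movement-level noise) and two static (distinct gravity orientations with
#' low-frequency postural sway and small at-rest sensor noise). Amplitudes
#' and offsets are in g; frequencies in Hz.
#'
#' @return A list of class specs (`name`, `f0`, `harmonics`, `axis_gain`,
#'   `offset`, `noise_sd`).
#' @export
default_activity_classes <- function() {
  list(
    list(name = "walking", f0 = 1.5, harmonics = c(0.9, 0.45, 0.2),
         axis_gain = c(1.0, 0.6, 0.35), offset = c(0.1, 0.95, 0.2),
         noise_sd = 0.08),
    list(name = "jogging", f0 = 3.4, harmonics = c(1.4, 0.7, 0.25),
         axis_gain = c(1.0, 0.8, 0.5), offset = c(0.15, 0.9, 0.25),
         noise_sd = 0.12),
    list(name = "upstairs", f0 = 0.9, harmonics = c(0.8, 0.3, 0.35),
         axis_gain = c(0.7, 1.0, 0.45), offset = c(0.2, 0.9, 0.3),
         noise_sd = 0.10),
    list(name = "downstairs", f0 = 2.3, harmonics = c(1.0, 0.25, 0.1),
         axis_gain = c(0.9, 1.0, 0.3), offset = c(0.2, 0.85, 0.35),
         noise_sd = 0.10),
    list(name = "standing", f0 = 0.6, harmonics = c(0.05),
         axis_gain = c(1.0, 0.4, 0.7), offset = c(0.05, 1.0, 0.05),
         noise_sd = 0.010),
    list(name = "sitting", f0 = 0.25, harmonics = c(0.04),
         axis_gain = c(0.5, 0.6, 1.0), offset = c(0.45, 0.75, 0.45),
         noise_sd = 0.008)
  )
}

#' Synthetic dataset generator configuration
#'
#' Study conditions for the synthetic benchmark: the class specs, the number
#' of subjects and instances, the sampling rate and segment length (50 Hz and
#' 128 samples by default, the shape of common smartphone benchmarks), and
#' the per-subject jitter that injects subject-level heterogeneity
#' (multiplicative amplitude and frequency perturbations). The seed is
#' mandatory; one root seed drives stable per-subject streams, so adding
#' subjects never perturbs existing ones.
#'
#' @param classes List of class specs, see [default_activity_classes()].
#' @param subjects Number of subjects.
#' @param instances_per_class Instances per class per subject.
#' @param sampling_rate Sampling rate in Hz.
#' @param seg_len Segment length in samples.
#' @param amplitude_jitter_sd,frequency_jitter_sd Per-subject multiplicative
#'   jitter standard deviations.
#' @param noise_scale Multiplier applied to every class's noise sd (1 =
#'   nominal).
#' @param seed Integer seed (mandatory).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(classes = default_activity_classes(),
                             subjects = 10L, instances_per_class = 6L,
                             sampling_rate = 50, seg_len = 128L,
                             amplitude_jitter_sd = 0.15,
                             frequency_jitter_sd = 0.06,
                             noise_scale = 1, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  for (cl in classes) {
    f_max <- cl$f0 * length(cl$harmonics)
    if (f_max >= sampling_rate / 2) {
      abort(sprintf("class %s violates the Nyquist limit (%g Hz >= %g Hz).",
                    cl$name, f_max, sampling_rate / 2))
    }
    if (cl$noise_sd < 0) abort("noise sd must be >= 0.")
  }
  structure(
    list(classes = classes, subjects = as.integer(subjects),
         instances_per_class = as.integer(instances_per_class),
         sampling_rate = sampling_rate, seg_len = as.integer(seg_len),
         amplitude_jitter_sd = amplitude_jitter_sd,
         frequency_jitter_sd = frequency_jitter_sd,
         noise_scale = noise_scale, seed = as.integer(seed)),
    class = "generator_config"
  )
}

gen_instance <- function(cl, subj_jit, t, noise_scale) {
  v <- length(cl$offset)
  seg <- matrix(0, length(t), v)
  amp <- subj_jit$amp
  f0 <- cl$f0 * subj_jit$freq
  base_phase <- stats::runif(1, 0, 2 * pi)
  for (ax in seq_len(v)) {
    sig <- cl$offset[ax] * subj_jit$off[ax]
    for (k in seq_along(cl$harmonics)) {
      phase <- base_phase * k + stats::runif(1, -0.3, 0.3)
      sig <- sig + amp * cl$axis_gain[ax] * cl$harmonics[k] *
        sin(2 * pi * k * f0 * t + phase)
    }
    seg[, ax] <- sig +
      stats::rnorm(length(t), sd = cl$noise_sd * noise_scale)
  }
  colnames(seg) <- c("x", "y", "z")[seq_len(min(v, 3L))]
  seg
}

#' Generate a synthetic labeled dataset
#'
#' Draws `instances_per_class` segments per class and subject. Dynamic
#' classes are sums of harmonics of a class-specific fundamental with random
#' phases plus Gaussian noise; static classes reduce to a gravity-projection
#' offset, a faint sway harmonic and low noise. Each subject carries its own
#' deterministic multiplicative amplitude/frequency/orientation jitter.
#'
#' @param config A [generator_config()].
#' @return A dataset tibble (`subject`, `label`, `instance_id`, `segment`).
#' @examples
#' d <- generate_dataset(generator_config(subjects = 2,
#'                                        instances_per_class = 2, seed = 1))
#' nrow(d) # 2 subjects x 6 classes x 2 instances
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  t <- (seq_len(config$seg_len) - 1L) / config$sampling_rate
  rows <- list()
  iid <- 0L
  for (s in seq_len(config$subjects)) {
    subj <- sprintf("s%02d", s)
    subj_seed <- derive_seed(config$seed, s)
    withr::with_seed(subj_seed, {
      jit <- list(
        amp = max(0.2, 1 + stats::rnorm(1, sd = config$amplitude_jitter_sd)),
        freq = max(0.5, 1 + stats::rnorm(1, sd = config$frequency_jitter_sd)),
        off = 1 + stats::rnorm(3, sd = config$amplitude_jitter_sd / 2)
      )
      for (cl in config$classes) {
        for (r in seq_len(config$instances_per_class)) {
          iid <- iid + 1L
          rows[[iid]] <- new_dataset_row(
            gen_instance(cl, jit, t, config$noise_scale),
            cl$name, subj, iid)
        }
      }
    })
  }
  dplyr::bind_rows(rows)
}

#' Synthetic fall-like recording with magnitude spikes
#'
#' A quiescent tri-axial recording at about 1 g with `n_spikes` short
#' transient bursts whose magnitude exceeds the conventional 1.5 g fall
#' threshold, for exercising magnitude-peak segmentation. Spikes are evenly
#' spaced (hence separated by more than one window when `n_spikes` is small
#' relative to the duration).
#'
#' @param n_spikes Number of injected transients.
#' @param duration Recording duration in seconds.
#' @param sampling_rate Sampling rate in Hz.
#' @param spike_height Peak magnitude of each transient (in g).
#' @param seed Integer seed.
#' @param first_spike_at Optional sample index of the first spike (to place a
#'   spike near a boundary); remaining spikes stay evenly spaced.
#' @return A [raw_recording()] labeled `"fall"`.
#' @export
fall_like_recording <- function(n_spikes = 3L, duration = 30,
                                sampling_rate = 50, spike_height = 2.5,
                                seed = 1L, first_spike_at = NULL) {
  n <- as.integer(round(duration * sampling_rate))
  withr::with_seed(as.integer(seed), {
    samples <- cbind(
      x = stats::rnorm(n, 0, 0.01),
      y = stats::rnorm(n, 1, 0.01), # gravity on y
      z = stats::rnorm(n, 0, 0.01)
    )
    if (n_spikes > 0L) {
      centers <- round(seq(n / (n_spikes + 1), n * n_spikes / (n_spikes + 1),
                           length.out = n_spikes))
      if (!is.null(first_spike_at)) {
        centers[1L] <- as.integer(first_spike_at)
      }
      half <- 3L
      for (ctr in centers) {
        idx <- max(1L, ctr - half):min(n, ctr + half)
        bump <- (spike_height - 1) * exp(-((idx - ctr)^2) / 2)
        samples[idx, "y"] <- samples[idx, "y"] + bump
      }
    }
  })
  raw_recording(samples, sampling_rate, label = "fall", subject = "s01")
}
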