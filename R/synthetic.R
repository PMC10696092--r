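#' Epoch set container
#'
#' A labelled collection of fixed-length multichannel trials with sampling
#' metadata — the unit of data the pipeline operates on.
#'
#' @param trials numeric array, trials x channels x samples.
#' @param labels class label per trial (factor or coercible).
#' @param channel_ids channel labels; default `"ch1", ...`.
#' @param sample_rate sampling rate in Hz.
#' @param subject_ids optional per-trial subject identifier (enables
#'   leave-one-subject-out cross-validation).
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(trials, labels, channel_ids = NULL, sample_rate,
                      subject_ids = NULL) {
  stopifnot(is.array(trials), length(dim(trials)) == 3)
  n <- dim(trials)[1]
  d <- dim(trials)[2]
  labels <- as.factor(labels)
  if (length(labels) != n) stop_invalid("one label per trial required")
  if (!all(is.finite(trials))) stop_invalid("trial values must be finite")
  if (sample_rate <= 0) stop_invalid("sample_rate must be positive")
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(d))
  if (length(channel_ids) != d) stop_invalid("one id per channel required")
  if (!is.null(subject_ids)) {
    subject_ids <- as.character(subject_ids)
    if (length(subject_ids) != n) stop_invalid("one subject id per trial required")
  }
  structure(list(trials = trials, labels = labels,
                 channel_ids = as.character(channel_ids),
                 sample_rate = as.double(sample_rate),
                 subject_ids = subject_ids),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  dm <- dim(x$trials)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              dm[1], dm[2], dm[3], x$sample_rate))
  print(table(x$labels))
  if (!is.null(x$subject_ids)) {
    cat(sprintf("subjects: %d\n", length(unique(x$subject_ids))))
  }
  invisible(x)
}

#' Extract one trial as a multichannel path
#'
#' @param epochs an [epoch_set()].
#' @param i trial index.
#' @return a [multichannel_path()] with times in seconds.
#' @export
trial_path <- function(epochs, i) {
  stopifnot(inherits(epochs, "epoch_set"))
  s <- dim(epochs$trials)[3]
  multichannel_path(t(epochs$trials[i, , ]),
                    times = (seq_len(s) - 1) / epochs$sample_rate,
                    channel_ids = epochs$channel_ids)
}

#' Configuration for a phase-lagged sine system
#'
#' Describes the analytic example behind cyclicity analysis: channels
#' \eqn{X^i_t = A \sin(2\pi f t - \alpha_i) + \textrm{noise}}. When
#' `duration * frequency` is a positive integer the sampled path is closed
#' and the analytic lead matrix ([analytic_sine_lead_matrix()]) is exact.
#'
#' @param alphas phase offsets in radians, one per channel.
#' @param frequency oscillation frequency in Hz.
#' @param amplitude common amplitude.
#' @param duration trial duration in seconds.
#' @param sample_rate sampling rate in Hz; must exceed `2 * frequency`.
#' @param noise_sd Gaussian white noise standard deviation.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return a `sine_system_config` list.
#' @export
sine_system_config <- function(alphas, frequency = 1 / (2 * pi), amplitude = 1,
                               duration = 4 * pi, sample_rate = NULL,
                               noise_sd = 0, seed = 1L) {
  if (is.null(sample_rate)) sample_rate <- 500 * frequency
  if (sample_rate <= 2 * frequency) {
    stop_invalid("sample_rate (%g Hz) must exceed twice the frequency (%g Hz)",
                 sample_rate, frequency)
  }
  if (duration <= 0) stop_invalid("duration must be positive")
  structure(list(alphas = as.double(alphas), frequency = frequency,
                 amplitude = amplitude, duration = duration,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sine_system_config")
}

#' Generate a system of phase-lagged sines
#'
#' Channel i is \eqn{A \sin(2\pi f t - \alpha_i)} plus optional white noise,
#' sampled on a closed grid (endpoint included, so integer-period durations
#' yield closed paths and the rank-2 lead-matrix structure is exact). A pure
#' function of its configuration and seed.
#'
#' @param cfg a [sine_system_config()].
#' @param n_samples optional explicit sample count overriding
#'   `duration * sample_rate + 1`.
#' @return a [multichannel_path()].
#' @export
gen_lagged_sines <- function(cfg, n_samples = NULL) {
  stopifnot(inherits(cfg, "sine_system_config"))
  if (is.null(n_samples)) {
    n_samples <- round(cfg$duration * cfg$sample_rate) + 1L
  }
  times <- seq(0, cfg$duration, length.out = n_samples)
  vals <- vapply(cfg$alphas, function(a) {
    cfg$amplitude * sin(2 * pi * cfg$frequency * times - a)
  }, numeric(n_samples))
  if (cfg$noise_sd > 0) {
    vals <- vals + with_local_seed(cfg$seed,
      matrix(stats::rnorm(length(vals), sd = cfg$noise_sd), nrow(vals)))
  }
  multichannel_path(vals, times,
                    paste0("ch", seq_along(cfg$alphas)))
}

#' Generate several independent sine systems on disjoint channel blocks
#'
#' Concatenates the channels of several [gen_lagged_sines()] systems sharing
#' one duration and sampling grid. Each system contributes one dominant
#' conjugate eigenvalue pair to the lead matrix, supported on its own block,
#' so the per-block cyclic orders remain recoverable. Systems should differ
#' in frequency (integer cycle counts over the duration keep cross-block
#' signed areas at zero).
#'
#' @param cfgs list of [sine_system_config()] sharing `duration` and
#'   `sample_rate`.
#' @return a [multichannel_path()] with blockwise channel ids
#'   `set<k>_ch<i>`.
#' @export
gen_multiset_sines <- function(cfgs) {
  stopifnot(length(cfgs) >= 1)
  dur <- cfgs[[1]]$duration
  sr <- cfgs[[1]]$sample_rate
  for (cfg in cfgs) {
    stopifnot(inherits(cfg, "sine_system_config"))
    if (cfg$duration != dur || cfg$sample_rate != sr) {
      stop_invalid("all systems must share duration and sample_rate")
    }
  }
  paths <- lapply(cfgs, gen_lagged_sines)
  vals <- do.call(cbind, lapply(paths, function(p) p$values))
  ids <- unlist(lapply(seq_along(cfgs), function(k) {
    paste0("set", k, "_ch", seq_along(cfgs[[k]]$alphas))
  }))
  multichannel_path(vals, paths[[1]]$times, ids)
}

#' Configuration for two-class motor-imagery-like epochs
#'
#' Parametrizes a synthetic stand-in for two-class motor-imagery EEG: each
#' trial is a sum of band-limited oscillatory components (each with a
#' per-class per-channel phase-offset map — the lead-lag structure — and a
#' per-class amplitude — the event-related-desynchronization-like
#' modulation), plus Gaussian white and 1/f-like background noise. Classes
#' with identical component lists are exchangeable by construction.
#'
#' Each component is a list with fields `frequency` (Hz), `phase_maps` (list
#' of per-class numeric d-vectors of offsets in radians, or a single vector
#' shared by both classes, or `"random"` for fresh uniform offsets every
#' trial), `amplitudes` (per-class scalars or d-vectors), and optional
#' `phase_jitter_sd` (per-trial, per-channel jitter in radians, default
#' 0.2).
#'
#' @param n_trials_per_class trials per class.
#' @param n_channels channel count d.
#' @param sample_rate Hz.
#' @param duration trial length in seconds.
#' @param components list of component specs (see Details).
#' @param noise_sd white noise standard deviation.
#' @param pink_sd amplitude of the 1/f-like background (0 disables).
#' @param seed RNG seed.
#' @return a `mi_epoch_config` list.
#' @export
mi_epoch_config <- function(n_trials_per_class = 100L, n_channels = 22L,
                            sample_rate = 250, duration = 3,
                            components = list(), noise_sd = 1,
                            pink_sd = 0.5, seed = 1L) {
  for (cmp in components) {
    if (cmp$frequency >= sample_rate / 2) {
      stop_invalid("component frequency %g Hz violates Nyquist at %g Hz",
                   cmp$frequency, sample_rate)
    }
  }
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 n_channels = as.integer(n_channels),
                 sample_rate = sample_rate, duration = duration,
                 components = components, noise_sd = noise_sd,
                 pink_sd = pink_sd, seed = as.integer(seed)),
            class = "mi_epoch_config")
}

#' Preset epoch-generator configurations
#'
#' Three study conditions used throughout the package:
#' \describe{
#'   \item{`"lead-lag"`}{classes differ only in lead-lag structure: two
#'     oscillatory components (10 and 22 Hz, equal amplitude) whose
#'     per-channel phase maps are swapped between the frequencies across
#'     classes. The covariance expectation is identical across classes
#'     (cosine terms sum over both maps either way) while the lead matrix
#'     weights components by frequency, so lead-derived SPD features
#'     separate the classes and covariance features do not.}
#'   \item{`"amplitude"`}{classes differ only in band amplitude: phase maps
#'     are redrawn uniformly at random every trial (same distribution in
#'     both classes, so no stable lead-lag structure), and class 2
#'     attenuates the 10 Hz component to 60% (a static
#'     desynchronization-like factor). Covariance features carry the band
#'     power cleanly; lead matrices have no stable class structure.}
#'   \item{`"null"`}{identical class configurations; any classifier should
#'     stay within the binomial band of chance.}
#' }
#'
#' @param preset one of `"lead-lag"`, `"amplitude"`, `"null"`.
#' @param n_trials_per_class,n_channels,sample_rate,duration,seed overrides.
#' @return a [mi_epoch_config()].
#' @export
mi_preset <- function(preset = c("lead-lag", "amplitude", "null"),
                      n_trials_per_class = 100L, n_channels = 22L,
                      sample_rate = 250, duration = 3, seed = 1L) {
  preset <- match.arg(preset)
  d <- as.integer(n_channels)
  ## two fixed phase maps: a tight spread (weak pairwise signed areas — a
  ## weakly sequenced set) and a balanced wide spread (strong areas)
  map_a <- seq(0, 0.6, length.out = d)
  map_b <- 2 * pi * ((seq_len(d) * 7L) %% d) / d
  comps <- switch(
    preset,
    "lead-lag" = list(
      list(frequency = 9, phase_maps = list(map_a, map_b),
           amplitudes = c(1, 1), phase_jitter_sd = 0.05),
      list(frequency = 27, phase_maps = list(map_b, map_a),
           amplitudes = c(1, 1), phase_jitter_sd = 0.05)
    ),
    "amplitude" = list(
      list(frequency = 9, phase_maps = "random",
           amplitudes = c(1, 0.6), phase_jitter_sd = 0.05),
      list(frequency = 27, phase_maps = "random",
           amplitudes = c(0.7, 0.7), phase_jitter_sd = 0.05)
    ),
    "null" = list(
      list(frequency = 9, phase_maps = list(map_a, map_a),
           amplitudes = c(1, 1), phase_jitter_sd = 0.05),
      list(frequency = 27, phase_maps = list(map_b, map_b),
           amplitudes = c(1, 1), phase_jitter_sd = 0.05)
    )
  )
  mi_epoch_config(n_trials_per_class = n_trials_per_class, n_channels = d,
                  sample_rate = sample_rate, duration = duration,
                  components = comps, noise_sd = 2, pink_sd = 1,
                  seed = seed)
}

## 1/f-like noise: shape white noise in the frequency domain by 1/sqrt(f).
pink_noise <- function(n, d, sd) {
  w <- matrix(stats::rnorm(n * d), n, d)
  W <- stats::mvfft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index
  scale <- 1 / sqrt(f)
  X <- Re(stats::mvfft(W * scale, inverse = TRUE)) / n
  sd * X / stats::sd(as.vector(X))
}

#' Generate two-class motor-imagery-like epochs
#'
#' Produces an [epoch_set()] according to a [mi_epoch_config()]: trial t of
#' class c is
#' \deqn{\sum_k A_{k,c} \sin(2\pi f_k t - \phi_{k,c} - \eta) + \textrm{noise},}
#' with a fresh uniform global phase per trial and component, per-channel
#' phase jitter, white noise, and 1/f-like background. A pure function of
#' config and seed.
#'
#' @param cfg a [mi_epoch_config()] (e.g. from [mi_preset()]).
#' @return an [epoch_set()] with labels `"class1"`, `"class2"`.
#' @export
gen_mi_epochs <- function(cfg) {
  stopifnot(inherits(cfg, "mi_epoch_config"))
  n_per <- cfg$n_trials_per_class
  d <- cfg$n_channels
  s <- round(cfg$duration * cfg$sample_rate)
  times <- (seq_len(s) - 1) / cfg$sample_rate
  n <- 2L * n_per
  labels <- rep(c("class1", "class2"), each = n_per)
  trials <- array(0, c(n, d, s))
  with_local_seed(cfg$seed, {
    for (i in seq_len(n)) {
      cls <- if (i <= n_per) 1L else 2L
      x <- matrix(0, d, s)
      for (cmp in cfg$components) {
        amp <- cmp$amplitudes[[min(cls, length(cmp$amplitudes))]]
        amp <- rep_len(amp, d)
        phi <- if (identical(cmp$phase_maps, "random")) {
          stats::runif(d, 0, 2 * pi)
        } else if (is.list(cmp$phase_maps)) {
          rep_len(cmp$phase_maps[[min(cls, length(cmp$phase_maps))]], d)
        } else {
          rep_len(cmp$phase_maps, d)
        }
        jit_sd <- if (is.null(cmp$phase_jitter_sd)) 0.2 else cmp$phase_jitter_sd
        phi <- phi + stats::rnorm(d, sd = jit_sd)
        global <- stats::runif(1, 0, 2 * pi)
        ang <- outer(rep(2 * pi * cmp$frequency, d), times)
        x <- x + amp * sin(ang - phi - global)
      }
      if (cfg$noise_sd > 0) {
        x <- x + matrix(stats::rnorm(d * s, sd = cfg$noise_sd), d, s)
      }
      if (cfg$pink_sd > 0) {
        x <- x + t(pink_noise(s, d, cfg$pink_sd))
      }
      trials[i, , ] <- x
    }
  })
  epoch_set(trials, labels, sample_rate = cfg$sample_rate)
}

#' Generate multi-subject epochs with inter-subject variability
#'
#' Pools per-subject datasets drawn from a shared class structure, then
#' applies subject-specific distortions on top: a random global gain
#' (log-normal), a random channel-space rotation close to identity (mixing
#' strength `rotation`), and a subject-wide phase offset. The result enables
#' leave-one-subject-out cross-validation on synthetic data.
#'
#' @param cfg a [mi_epoch_config()]; `n_trials_per_class` is per subject.
#' @param n_subjects number of subjects (>= 3).
#' @param gain_sd standard deviation of the log-gain.
#' @param rotation channel-mixing strength in `[0, 1)` (0 = none).
#' @param phase_sd standard deviation of the subject-wide phase offset
#'   (radians), applied by shifting each subject's trials circularly.
#' @return an [epoch_set()] with `subject_ids`.
#' @export
gen_multi_subject <- function(cfg, n_subjects = 5L, gain_sd = 0.2,
                              rotation = 0.1, phase_sd = 0.3) {
  stopifnot(inherits(cfg, "mi_epoch_config"))
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 3L) stop_invalid("need at least 3 subjects")
  sets <- vector("list", n_subjects)
  with_local_seed(cfg$seed, {
    for (sj in seq_len(n_subjects)) {
      sub_cfg <- cfg
      sub_cfg$seed <- derive_seed(cfg$seed, sj)
      es <- gen_mi_epochs(sub_cfg)
      gain <- exp(stats::rnorm(1, sd = gain_sd))
      d <- dim(es$trials)[2]
      if (rotation > 0) {
        S <- matrix(stats::rnorm(d * d, sd = rotation / sqrt(d)), d, d)
        S <- (S - t(S)) / 2
        Q <- sym_rotation(S)
      } else {
        Q <- diag(d)
      }
      shift <- round(stats::rnorm(1, sd = phase_sd) / (2 * pi) *
                       cfg$sample_rate / 10)  # relative to a 10 Hz cycle
      for (i in seq_len(dim(es$trials)[1])) {
        x <- gain * Q %*% es$trials[i, , ]
        if (shift != 0) {
          idx <- ((seq_len(ncol(x)) - 1 + shift) %% ncol(x)) + 1
          x <- x[, idx, drop = FALSE]
        }
        es$trials[i, , ] <- x
      }
      es$subject_ids <- rep(sprintf("S%02d", sj), dim(es$trials)[1])
      sets[[sj]] <- es
    }
  })
  trials <- do.call(abind3, lapply(sets, function(e) e$trials))
  epoch_set(trials,
            labels = unlist(lapply(sets, function(e) as.character(e$labels))),
            channel_ids = sets[[1]]$channel_ids,
            sample_rate = cfg$sample_rate,
            subject_ids = unlist(lapply(sets, function(e) e$subject_ids)))
}

## orthogonal matrix from skew-symmetric S via the Cayley transform
sym_rotation <- function(S) {
  d <- nrow(S)
  solve(diag(d) - S / 2, diag(d) + S / 2)
}

## bind 3-D arrays along the first margin
abind3 <- function(...) {
  arrs <- list(...)
  dms <- vapply(arrs, function(a) dim(a)[1], integer(1))
  out <- array(0, c(sum(dms), dim(arrs[[1]])[2], dim(arrs[[1]])[3]))
  off <- 0L
  for (a in arrs) {
    out[off + seq_len(dim(a)[1]), , ] <- a
    off <- off + dim(a)[1]
  }
  out
}
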