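#' Simulation configuration for a synthetic EEG recording
#'
#' Describes a multichannel recording with 1/f background noise, optional
#' zero-lag mixing of shared sources into several channels (a volume-conduction
#' stand-in), and planted narrow-band phase-lagged coupling between channel
#' pairs. Coupling is realised as a shared noisy oscillator observed by both
#' channels with a fixed phase offset; the coupling `strength` in \[0, 1\]
#' controls per-channel phase jitter around that offset (1 = rigid phase
#' locking, 0 = independent phases). The strength to expected-dbWPLI mapping
#' is empirical and monotone; see the methods vignette.
#'
#' @param n_channels number of channels.
#' @param duration recording length in seconds.
#' @param fs sampling rate in Hz; 500 by default, matching common infant EEG
#'   acquisition.
#' @param coupling list of couplings built with [coupling()].
#' @param mixing `NULL` or a channels x sources numeric matrix; each source is
#'   an independent 1/f noise mixed instantaneously (zero lag) into the
#'   channels with the given weights.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background
#'   noise; 1 by default (EEG-like), 0 gives white noise.
#' @param snr oscillator-to-noise amplitude ratio (signal sd over noise sd per
#'   coupled channel). `Inf` suppresses background noise entirely.
#' @param phase_drift sd of the shared oscillator's random phase drift, in
#'   radians per sqrt(second); gives epochs independent absolute phases.
#' @param jitter_scale stationary sd (radians) of the per-channel
#'   mean-reverting phase jitter at strength 0; a coupling of strength `s`
#'   jitters with sd `jitter_scale * (1 - s)`. The default 2 rad makes
#'   strength-0 phases effectively uniform, so expected dbWPLI falls
#'   monotonically from 1 (s = 1) to about 0 (s = 0).
#' @param jitter_tau relaxation time (seconds) of the jitter process;
#'   successive 1-s epochs are approximately independent at the default 0.5.
#' @param seed integer seed; identical configs with identical seeds produce
#'   bit-identical recordings.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels, duration, fs = 500, coupling = list(),
                       mixing = NULL, noise_exponent = 1, snr = 1,
                       phase_drift = 1, jitter_scale = 2, jitter_tau = 0.5,
                       seed = NULL) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0) {
    stop("`duration` must be a single positive number")
  }
  if (!is.numeric(n_channels) || n_channels < 1) {
    stop("`n_channels` must be a positive count")
  }
  if (length(coupling) && !all(vapply(coupling, inherits, TRUE, "eeg_coupling"))) {
    stop("`coupling` must be a list of coupling() objects")
  }
  for (cp in coupling) {
    if (max(cp$i, cp$j) > n_channels) {
      stop("coupling references channel beyond n_channels")
    }
  }
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (nrow(mixing) != n_channels) {
      stop("`mixing` must have one row per channel")
    }
    if (any(dim(mixing) < 1L)) stop("`mixing` has a non-positive dimension")
  }
  structure(
    list(n_channels = as.integer(n_channels), fs = fs, duration = duration,
         coupling = coupling, mixing = mixing,
         noise_exponent = noise_exponent, snr = snr,
         phase_drift = phase_drift, jitter_scale = jitter_scale,
         jitter_tau = jitter_tau, seed = seed),
    class = "sim_config")
}

#' Planted narrow-band coupling between two channels
#'
#' @param i,j channel indices (1-based).
#' @param freq oscillator centre frequency in Hz.
#' @param lag phase lag of channel `j` relative to channel `i`, radians.
#'   Non-zero lags produce imaginary cross-spectra that dbWPLI detects; a
#'   zero lag emulates volume conduction and is invisible to it.
#' @param strength phase-locking strength in \[0, 1\].
#' @return An object of class `eeg_coupling`.
#' @export
coupling <- function(i, j, freq, lag = pi / 2, strength = 1) {
  stopifnot(i >= 1, j >= 1, i != j, freq > 0)
  if (strength < 0 || strength > 1) stop("`strength` must lie in [0, 1]")
  structure(list(i = as.integer(i), j = as.integer(j), freq = freq,
                 lag = lag, strength = strength),
            class = "eeg_coupling")
}

# 1/f^alpha noise of length n, unit sd, by spectral shaping of white noise.
onef_noise <- function(n, alpha, fs) {
  if (alpha == 0) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  f <- seq(0, fs / 2, length.out = floor(n / 2) + 1L)
  gain <- c(0, f[-1L]^(-alpha / 2))              # kill DC
  full <- c(gain, rev(gain[2:(n - length(gain) + 1L)]))
  x <- Re(stats::fft(stats::fft(w) * full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# Brownian phase path: cumulative Gaussian increments, sd `rate` per
# sqrt(second) so the drift statistics are sampling-rate independent.
phase_walk <- function(n, rate, fs) {
  if (rate <= 0) return(numeric(n))
  cumsum(stats::rnorm(n, sd = rate / sqrt(fs)))
}

# Stationary Ornstein-Uhlenbeck phase jitter: stationary sd `sigma`,
# relaxation time `tau` seconds. Unlike a random walk this does not
# accumulate, so the jitter sd (hence expected phase locking) is constant
# over the recording.
ou_phase <- function(n, sigma, tau, fs) {
  if (sigma <= 0) return(numeric(n))
  a <- exp(-1 / (tau * fs))
  innov_sd <- sigma * sqrt(1 - a^2)
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L, sd = sigma)
  eps <- stats::rnorm(n - 1L, sd = innov_sd)
  for (k in 2:n) x[k] <- a * x[k - 1L] + eps[k - 1L]
  x
}

#' Simulate a synthetic EEG recording
#'
#' Generates `n_channels` x `round(fs * duration)` samples: per-channel
#' 1/f^alpha noise, plus zero-lag mixed sources when a mixing matrix is given,
#' plus one shared noisy oscillator per planted coupling. For a coupling of
#' strength 1 at infinite SNR the two channels hold phase difference exactly
#' equal to the configured lag, so the downstream dbWPLI of that pair
#' approaches 1; at strength 0 the phases decouple and dbWPLI is near 0.
#'
#' @param cfg a [sim_config()].
#' @return An [eeg_recording()] (no annotations).
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- round(cfg$fs * cfg$duration)
    nch <- cfg$n_channels
    x <- matrix(0, nch, n)
    noise_amp <- if (is.infinite(cfg$snr)) 0 else 1
    sig_amp <- if (is.infinite(cfg$snr)) 1 else cfg$snr
    if (noise_amp > 0) {
      for (ch in seq_len(nch)) {
        x[ch, ] <- noise_amp * onef_noise(n, cfg$noise_exponent, cfg$fs)
      }
    }
    if (!is.null(cfg$mixing)) {
      nsrc <- ncol(cfg$mixing)
      src <- matrix(0, nsrc, n)
      for (s in seq_len(nsrc)) src[s, ] <- onef_noise(n, cfg$noise_exponent, cfg$fs)
      x <- x + cfg$mixing %*% src
    }
    tt <- (seq_len(n) - 1) / cfg$fs
    for (cp in cfg$coupling) {
      base <- 2 * pi * cp$freq * tt + phase_walk(n, cfg$phase_drift, cfg$fs)
      jit <- cfg$jitter_scale * (1 - cp$strength)
      amp <- sig_amp * sqrt(2)   # unit-sd sinusoid times snr
      x[cp$i, ] <- x[cp$i, ] +
        amp * sin(base + ou_phase(n, jit, cfg$jitter_tau, cfg$fs))
      x[cp$j, ] <- x[cp$j, ] +
        amp * sin(base + cp$lag + ou_phase(n, jit, cfg$jitter_tau, cfg$fs))
    }
    eeg_recording(x, fs = cfg$fs)
  })
}

#' Cohort simulation configuration
#'
#' Describes a cohort of subjects split into outcome groups. Each subject gets
#' a true coupling strength drawn from its group's Normal distribution
#' (truncated to \[0, 1\]), a recording simulated from a shared
#' [sim_config()] template with every planted coupling set to that strength,
#' and trait scores that are a noisy linear function of the true strength:
#' `trait = intercept + slope * strength + N(0, noise_sd)`.
#'
#' @param group_sizes named integer vector, subjects per group (e.g.
#'   `c("LR" = 20, "HR-TD" = 47, "HR-Atyp" = 21, "HR-ASD" = 13)`).
#' @param template a [sim_config()] whose couplings define the true coupled
#'   edge set; its `seed` is ignored (per-subject seeds derive from `seed`).
#' @param coupling_mean,coupling_sd named numeric vectors (per group) or
#'   single numbers recycled across groups.
#' @param traits named list; each element `list(intercept=, slope=, noise_sd=)`
#'   defines one trait scale. Defaults to a single ADI-R-RRB-like scale.
#' @param round_traits round trait scores to integers and clip at 0
#'   (ADI-R-like discreteness). Off by default so that noiseless traits are an
#'   exact monotone map of coupling strength.
#' @param male_fraction probability a simulated subject is male.
#' @param seed integer seed for the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes, template,
                          coupling_mean = 0.5, coupling_sd = 0.15,
                          traits = list(adi_r_rrb = list(intercept = 2,
                                                         slope = 6,
                                                         noise_sd = 1.5)),
                          round_traits = FALSE, male_fraction = 0.5,
                          seed = NULL) {
  if (length(group_sizes) == 0L || is.null(names(group_sizes)) ||
      any(!nzchar(names(group_sizes)))) {
    stop("`group_sizes` must be a non-empty named vector")
  }
  if (any(group_sizes < 0)) stop("group sizes must be >= 0")
  stopifnot(inherits(template, "sim_config"))
  groups <- names(group_sizes)
  expand <- function(v, what) {
    if (length(v) == 1L && is.null(names(v))) {
      stats::setNames(rep(v, length(groups)), groups)
    } else {
      if (!all(groups %in% names(v))) stop("`", what, "` missing group entries")
      v[groups]
    }
  }
  for (tr in traits) {
    if (!all(c("intercept", "slope", "noise_sd") %in% names(tr))) {
      stop("each trait model needs intercept, slope and noise_sd")
    }
    if (tr$noise_sd < 0) stop("trait noise_sd must be >= 0")
  }
  structure(
    list(group_sizes = group_sizes, template = template,
         coupling_mean = expand(coupling_mean, "coupling_mean"),
         coupling_sd = expand(coupling_sd, "coupling_sd"),
         traits = traits, round_traits = round_traits,
         male_fraction = male_fraction, seed = seed),
    class = "cohort_config")
}

#' Simulate a cohort of recordings with ground truth
#'
#' @param cfg a [cohort_config()].
#' @param keep_recordings set to `FALSE` to skip signal synthesis and return
#'   only the cohort table and ground truth (useful when only the trait model
#'   is under study).
#' @return A list with elements `recordings` (named list of
#'   [eeg_recording()]s, or `NULL`), `cohort` (data frame: `id`, `group`,
#'   `sex`, `age_days`, one column per trait, `true_coupling`) and
#'   `ground_truth` (per-subject true strengths, the coupled edge set as an
#'   `i`/`j` data frame, and the trait-generation parameters).
#' @export
simulate_cohort <- function(cfg, keep_recordings = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, {
    groups <- rep(names(cfg$group_sizes), times = cfg$group_sizes)
    n <- length(groups)
    if (n == 0L) stop("cohort is empty: all group sizes are zero")
    ids <- sprintf("S%03d", seq_len(n))
    strength <- pmin(1, pmax(0, stats::rnorm(
      n, mean = cfg$coupling_mean[groups], sd = cfg$coupling_sd[groups])))
    tab <- data.frame(id = ids, group = groups,
                      sex = ifelse(stats::runif(n) < cfg$male_fraction, "M", "F"),
                      age_days = round(stats::rnorm(n, 470, 45)),
                      stringsAsFactors = FALSE)
    for (nm in names(cfg$traits)) {
      tr <- cfg$traits[[nm]]
      val <- tr$intercept + tr$slope * strength +
        stats::rnorm(n, sd = tr$noise_sd)
      if (cfg$round_traits) val <- pmax(0, round(val))
      tab[[nm]] <- val
    }
    tab$true_coupling <- strength
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
    recordings <- NULL
    if (keep_recordings) {
      recordings <- vector("list", n)
      names(recordings) <- ids
      for (k in seq_len(n)) {
        cfg_k <- cfg$template
        cfg_k$seed <- subject_seeds[k]
        cfg_k$coupling <- lapply(cfg_k$coupling, function(cp) {
          cp$strength <- strength[k]
          cp
        })
        recordings[[k]] <- simulate_recording(cfg_k)
      }
    }
    edges <- if (length(cfg$template$coupling)) {
      data.frame(
        i = vapply(cfg$template$coupling, `[[`, integer(1L), "i"),
        j = vapply(cfg$template$coupling, `[[`, integer(1L), "j"))
    } else {
      data.frame(i = integer(0), j = integer(0))
    }
    list(recordings = recordings, cohort = tab,
         ground_truth = list(true_coupling = stats::setNames(strength, ids),
                             coupled_edges = edges,
                             traits = cfg$traits,
                             subject_seeds = subject_seeds))
  })
}
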