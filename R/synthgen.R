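#' Default stage-transition matrix for simulated hypnograms
#'
#' First-order Markov dynamics over (Wake, NREM, REM) with self-transitions
#' >= 0.88 for realistic bout lengths. The NREM-to-REM entry rate is set so
#' that the expected REM share of sleep equals `rem_target`; lowering
#' `rem_persistence` emulates the fragmented, short REM bouts of disordered
#' sleep.
#'
#' @param rem_target Target REM fraction of sleep time (0-1).
#' @param rem_persistence REM self-transition probability.
#' @return 3 x 3 row-stochastic matrix in stage order (Wake, NREM, REM).
#' @export
rbd_transition_matrix <- function(rem_target = 0.18, rem_persistence = 0.90) {
  exit_r <- 1 - rem_persistence
  q <- exit_r * rem_target / (1 - rem_target)   # NREM -> REM entry rate
  q <- min(q, 0.5)
  P <- rbind(c(0.88, 0.118, 0.002),
             c(0.03, 0.97 - q, q),
             c(0.4 * exit_r, 0.6 * exit_r, rem_persistence))
  dimnames(P) <- list(.stage_levels, .stage_levels)
  P
}

#' Simulation configuration for a synthetic PSG cohort
#'
#' The generator emulates the stage-dependent spectral signatures that
#' drive clinical staging: occipitally weighted alpha in wake, frontal
#' delta plus central 11-15 Hz spindle bursts in NREM, theta-dominant REM
#' with optional 20-35 Hz bursts emulating the high-frequency
#' contamination of REM without atonia, all over a 1/f background.
#'
#' @param n_subjects Number of subjects.
#' @param epochs_per_night 30-s epochs per recording.
#' @param rate Native sampling rate, Hz.
#' @param rem_target_mean,rem_target_sd Between-subject distribution of the
#'   REM share of sleep used to tilt each subject's transition matrix.
#' @param rem_contamination_prob Probability that a REM epoch carries
#'   20-35 Hz contamination bursts.
#' @param rem_contamination_rms Burst band amplitude, uV RMS.
#' @param artifact_rate Per-epoch probability of an injected high-amplitude
#'   artifact.
#' @param artifact_amplitude Artifact peak amplitude, uV.
#' @param background_rms 1/f background amplitude, uV RMS.
#' @param seed Master seed; every subject derives its own stream from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10, epochs_per_night = 240, rate = 100,
                       rem_target_mean = 0.18, rem_target_sd = 0.07,
                       rem_contamination_prob = 0.3,
                       rem_contamination_rms = 12,
                       artifact_rate = 0.01, artifact_amplitude = 800,
                       background_rms = 6, seed = 1) {
  structure(list(n_subjects = n_subjects, epochs_per_night = epochs_per_night,
                 rate = rate, rem_target_mean = rem_target_mean,
                 rem_target_sd = rem_target_sd,
                 rem_contamination_prob = rem_contamination_prob,
                 rem_contamination_rms = rem_contamination_rms,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 background_rms = background_rms, seed = seed),
            class = "sim_config")
}

#' Simulate a hypnogram from a stage-transition matrix
#'
#' First-order Markov chain over (Wake, NREM, REM), drawn from the current
#' RNG state (seed with `set.seed()` for reproducibility).
#'
#' @param n_epochs Number of 30-s epochs.
#' @param transition_matrix 3 x 3 row-stochastic matrix.
#' @param initial_stage Starting stage label (default Wake).
#' @param subject_id Identifier for the generated hypnogram.
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(n_epochs, transition_matrix = rbd_transition_matrix(),
                               initial_stage = 0, subject_id = "sim") {
  P <- as.matrix(transition_matrix)
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix must be row-stochastic")
  labels <- integer(n_epochs)
  s <- as.integer(initial_stage)
  for (e in seq_len(n_epochs)) {
    labels[e] <- s
    s <- sample.int(3L, 1L, prob = P[s + 1L, ]) - 1L
  }
  hypnogram(labels, subject_id)
}

# channel weighting templates over the canonical montage
.w_occipital <- c(0.7, 0.7, 1.0, 1.0, 1.8, 1.8, 0.9, 0.9)
.w_frontal  <- c(1.3, 1.3, 1.1, 1.1, 0.8, 0.8, 0.9, 0.9)
.w_central  <- c(0.8, 0.8, 1.5, 1.5, 0.7, 0.7, 0.8, 0.8)
.w_emg      <- c(1.3, 1.3, 1.0, 1.0, 0.8, 0.8, 1.2, 1.2)
.w_flat     <- rep(1, 8)

# band-limited Gaussian noise, one column per channel, exact per-channel RMS
.band_noise <- function(n, rate, lo, hi, rms8, envelope = NULL) {
  W <- stats::mvfft(matrix(stats::rnorm(n * 8L), n, 8L))
  f <- (seq_len(n) - 1L) * rate / n
  f_fold <- pmin(f, rate - f)
  mask <- as.numeric(f_fold >= lo & f_fold <= hi)
  x <- Re(stats::mvfft(W * mask, inverse = TRUE)) / n
  if (!is.null(envelope)) x <- x * envelope
  s <- apply(x, 2L, stats::sd)
  s[s < 1e-12] <- 1
  sweep(x, 2L, rms8 / s, "*")
}

.pink_noise <- function(n, rate, rms8) {
  W <- stats::mvfft(matrix(stats::rnorm(n * 8L), n, 8L))
  f <- (seq_len(n) - 1L) * rate / n
  f_fold <- pmax(pmin(f, rate - f), 0.5)
  shape <- 1 / sqrt(f_fold)
  shape[1L] <- 0
  x <- Re(stats::mvfft(W * shape, inverse = TRUE)) / n
  s <- apply(x, 2L, stats::sd)
  sweep(x, 2L, rms8 / s, "*")
}

.burst_envelope <- function(n, rate, n_bursts = 3, dur = c(0.5, 1.5)) {
  env <- rep(0, n)
  for (b in seq_len(n_bursts)) {
    d <- round(stats::runif(1, dur[1], dur[2]) * rate)
    start <- sample.int(max(1L, n - d), 1L)
    env[start:(start + d - 1L)] <- env[start:(start + d - 1L)] +
      0.5 * (1 - cos(2 * pi * seq_len(d) / d))
  }
  pmin(env, 1.2) + 0.05
}

#' Simulate one stage-conditioned 30-s EEG epoch
#'
#' Sum of a 1/f background and band-limited Gaussian components with
#' stage-specific amplitudes and scalp weighting: wake is alpha-dominant
#' and occipitally weighted, NREM delta-dominant with central spindle
#' bursts, REM theta-dominant with probabilistic 20-35 Hz contamination
#' bursts (lost-atonia analogue). Uses the current RNG state.
#'
#' @param stage Stage label 0/1/2.
#' @param cfg A [sim_config()].
#' @return Matrix `8 x (30 * rate)`, microvolts, canonical channel order.
#' @export
simulate_epoch <- function(stage, cfg = sim_config()) {
  if (!(stage %in% 0:2)) stop("unknown stage ", stage)
  fs <- cfg$rate
  n <- 30L * fs
  x <- .pink_noise(n, fs, cfg$background_rms * .w_flat)
  add <- function(lo, hi, rms, w, envelope = NULL)
    x <<- x + .band_noise(n, fs, lo, hi, rms * w, envelope)
  if (stage == 0L) {                       # Wake
    add(0.5, 4, 6, .w_flat)
    add(4, 8, 5, .w_flat)
    add(8, 13, 18, .w_occipital)
    add(13, 30, 6, .w_flat)
  } else if (stage == 1L) {                # NREM
    add(0.5, 4, 35, .w_frontal)
    add(4, 8, 9, .w_flat)
    add(8, 11, 4, .w_flat)
    add(11, 15, 12, .w_central, envelope = .burst_envelope(n, fs))
  } else {                                 # REM
    add(0.5, 4, 9, .w_flat)
    add(4, 8, 16, .w_flat)
    add(8, 13, 6, .w_flat)
    add(13, 20, 4, .w_flat)
    if (stats::runif(1) < cfg$rem_contamination_prob)
      add(20, 35, cfg$rem_contamination_rms, .w_emg,
          envelope = .burst_envelope(n, fs, n_bursts = 4))
  }
  t(x)
}

#' Simulate one whole-night recording with its ground-truth hypnogram
#'
#' @param cfg A [sim_config()].
#' @param subject_id Identifier.
#' @param transition_matrix Stage dynamics; defaults to
#'   [rbd_transition_matrix()] at the config's REM target.
#' @param rem_target Optional subject-specific REM share of sleep.
#' @return List with `recording` and `hypnogram`.
#' @export
simulate_recording <- function(cfg = sim_config(), subject_id = "sim",
                               transition_matrix = NULL, rem_target = NULL) {
  if (is.null(transition_matrix)) {
    if (is.null(rem_target)) rem_target <- cfg$rem_target_mean
    transition_matrix <- rbd_transition_matrix(rem_target)
  }
  hyp <- simulate_hypnogram(cfg$epochs_per_night, transition_matrix,
                            subject_id = subject_id)
  n <- 30L * cfg$rate
  sig <- matrix(0, 8L, n * cfg$epochs_per_night)
  for (e in seq_len(cfg$epochs_per_night)) {
    ep <- simulate_epoch(hyp$labels[e], cfg)
    if (stats::runif(1) < cfg$artifact_rate) {
      ch <- sample.int(8L, 1L)
      d <- round(0.2 * cfg$rate)
      start <- sample.int(n - d, 1L)
      ep[ch, start:(start + d - 1L)] <- ep[ch, start:(start + d - 1L)] +
        cfg$artifact_amplitude * sin(2 * pi * seq_len(d) / d)
    }
    sig[, ((e - 1L) * n + 1L):(e * n)] <- ep
  }
  list(recording = recording(sig, cfg$rate, canonical_montage(), subject_id),
       hypnogram = hyp)
}

#' Draw per-subject REM percentages for association studies
#'
#' Cohort-level REM% of TST values (normal, clipped to a plausible range),
#' matching the between-subject spread the recording generator produces,
#' for testing the association statistics without synthesizing EEG.
#'
#' @param n Number of subjects.
#' @param mean,sd Distribution of REM% (percentage points).
#' @param range Clipping range.
#' @return Numeric vector of REM percentages.
#' @export
simulate_rem_pcts <- function(n, mean = 18, sd = 7, range = c(2, 45)) {
  pmin(pmax(stats::rnorm(n, mean, sd), range[1]), range[2])
}

#' Default planted effects of REM% on the clinical scales
#'
#' Linear-plus-noise effects calibrated so that, at the generator's
#' between-subject REM% spread (SD ~7 percentage points), the population
#' Spearman correlation is about -0.5 for the PSQI analogue, about -0.45
#' for the RBDSQ analogue, and 0 for the ESS analogue.
#'
#' @return Named list of per-scale effect definitions
#'   (`intercept`, `slope`, `sd`, `lo`, `hi`).
#' @export
scale_effects <- function() {
  list(psqi = list(intercept = 11.0, slope = -0.22, sd = 2.5, lo = 0, hi = 21),
       ess = list(intercept = 7.0, slope = 0.0, sd = 2.5, lo = 0, hi = 24),
       rbdsq = list(intercept = 10.7, slope = -0.19, sd = 2.5, lo = 0, hi = 13))
}

#' Simulate clinical scale scores with a planted dependence on REM%
#'
#' Each scale is `intercept + slope * REM% + Gaussian noise`, rounded to
#' integers and clipped to its instrument range. Demographic covariates
#' (age, sex, BMI, medication use) are drawn independently of REM%.
#'
#' @param rem_pcts Per-subject REM% of TST.
#' @param effects Per-scale effect definitions, see [scale_effects()].
#' @param subject_ids Optional identifiers.
#' @return Data frame with `subject_id`, one column per scale, and the
#'   covariates `age`, `sex`, `bmi`, `medication`.
#' @export
simulate_scales <- function(rem_pcts, effects = scale_effects(),
                            subject_ids = NULL) {
  n <- length(rem_pcts)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  out <- data.frame(subject_id = subject_ids, stringsAsFactors = FALSE)
  for (nm in names(effects)) {
    e <- effects[[nm]]
    raw <- e$intercept + e$slope * rem_pcts + stats::rnorm(n, 0, e$sd)
    out[[nm]] <- pmin(pmax(round(raw), e$lo), e$hi)
  }
  out$age <- round(stats::rnorm(n, 65, 9))
  out$sex <- stats::rbinom(n, 1L, 0.6)
  out$bmi <- round(stats::rnorm(n, 23.4, 3), 1)
  out$medication <- stats::rbinom(n, 1L, 0.3)
  out
}

#' Simulate a full synthetic cohort
#'
#' Per-subject recordings at the native rate with ground-truth hypnograms,
#' plus a clinical scale table whose planted effects act on each subject's
#' true REM% of sleep. Fully reproducible from the master seed; each
#' subject consumes its own derived seed.
#'
#' @param cfg A [sim_config()].
#' @return List of class `synthetic_cohort`: `subjects` (list of
#'   `recording` + `hypnogram`), `scales`, `rem_pct` (true REM% of TST per
#'   subject), `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  subjects <- vector("list", cfg$n_subjects)
  rem_true <- numeric(cfg$n_subjects)
  ids <- sprintf("S%03d", seq_len(cfg$n_subjects))
  for (i in seq_len(cfg$n_subjects)) {
    set.seed(cfg$seed + 1000L * i)
    target <- pmin(pmax(stats::rnorm(1, cfg$rem_target_mean, cfg$rem_target_sd),
                        0.04), 0.40)
    subjects[[i]] <- simulate_recording(cfg, ids[i], rem_target = target)
    ns <- night_summary(subjects[[i]]$hypnogram)
    rem_true[i] <- if (ns$undefined_pct) 0 else ns$rem_pct
  }
  set.seed(cfg$seed + 77L)
  scales <- simulate_scales(rem_true, subject_ids = ids)
  structure(list(subjects = subjects,
                 scales = scales,
                 rem_pct = data.frame(subject_id = ids, rem_pct = rem_true,
                                      stringsAsFactors = FALSE),
                 config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x %d epochs @ %g Hz (seed %d)\n",
              x$config$n_subjects, x$config$epochs_per_night, x$config$rate,
              x$config$seed))
  invisible(x)
}
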