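#' Default audiovisual stimulus set
#'
#' Eight percussion videos in a 2x2 within-subject design: instrument
#' familiarity (A = familiar, B = unfamiliar) crossed with sound congruity
#' (X = congruent, Y = incongruent), two instruments per cell. Familiarity
#' manipulates prior uncertainty about the upcoming sound; congruity
#' manipulates the prediction error when the sound arrives.
#'
#' @return Data frame with columns \code{stimulus}, \code{instrument},
#'   \code{sound}, \code{familiarity} (factor A/B) and \code{congruity}
#'   (factor X/Y); 8 rows, 2 per condition cell.
#' @export
default_stimuli <- function() {
  data.frame(
    stimulus = c("AX1", "AX2", "AY1", "AY2", "BX1", "BX2", "BY1", "BY2"),
    instrument = c("clave", "hand drum", "clave", "hand drum",
                   "jawbone", "slit drum", "jawbone", "slit drum"),
    sound = c("clave", "hand drum", "bell", "guiro",
              "jawbone", "slit drum", "vibraphone", "snare"),
    familiarity = factor(c("A", "A", "A", "A", "B", "B", "B", "B"),
                         levels = c("A", "B")),
    congruity = factor(c("X", "X", "Y", "Y", "X", "X", "Y", "Y"),
                       levels = c("X", "Y"))
  )
}

#' Default mapping from experimental conditions to model parameters
#'
#' Ties the 2x2 design to the information-gain model: familiarity sets the
#' prior uncertainty (unfamiliar instruments mean a wider prior over the
#' expected sound), congruity sets the prediction error (incongruent
#' sounds land far from the expectation). The numeric scale follows the
#' canonical gain-curve family (uncertainties 0.2 vs 1.0, noise 0.1); the
#' incongruent prediction error 2.0 lies well beyond the crossover point
#' (about 0.87), so the familiar-instrument curve is on top there.
#'
#' @return List with components \code{s_p} (named A/B), \code{delta}
#'   (named X/Y) and \code{s_l}.
#' @export
default_condition_mapping <- function() {
  list(s_p = c(A = 0.2, B = 1.0), delta = c(X = 0, Y = 2.0), s_l = 0.1)
}

validate_condition_mapping <- function(mapping) {
  sp <- mapping$s_p; d <- mapping$delta; sl <- mapping$s_l
  if (is.null(sp) || !all(c("A", "B") %in% names(sp)))
    stop("mapping$s_p must be named with levels A and B", call. = FALSE)
  if (is.null(d) || !all(c("X", "Y") %in% names(d)))
    stop("mapping$delta must be named with levels X and Y", call. = FALSE)
  check_variance(sl, "s_l")
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("uncertainties must be strictly positive", call. = FALSE)
  if (!(sp[["B"]] > sp[["A"]]))
    stop("configuration error: s_p(B) > s_p(A) required ",
         "(unfamiliar means more uncertain)", call. = FALSE)
  if (!(d[["Y"]] > d[["X"]]) || d[["X"]] < 0)
    stop("configuration error: delta(Y) > delta(X) >= 0 required",
         call. = FALSE)
  invisible(TRUE)
}

#' Model parameters and information gain for a design cell
#'
#' \code{condition_params} looks up the (uncertainty, prediction error,
#' noise) triple of one condition; \code{condition_gain} is vectorised
#' over conditions and returns the implied information gain in nats.
#' Under the default mapping the gains reproduce the arousal crossover
#' pattern: G(BX) > G(AX) but G(AY) > G(BY).
#'
#' @param familiarity "A" (familiar) or "B" (unfamiliar); vectorised in
#'   \code{condition_gain}.
#' @param congruity "X" (congruent) or "Y" (incongruent).
#' @param mapping A condition mapping, see
#'   \code{\link{default_condition_mapping}}.
#' @return \code{condition_params}: list with \code{s_p}, \code{delta},
#'   \code{s_l}. \code{condition_gain}: numeric vector of gains.
#' @export
condition_params <- function(familiarity, congruity,
                             mapping = default_condition_mapping()) {
  validate_condition_mapping(mapping)
  familiarity <- as.character(familiarity)
  congruity <- as.character(congruity)
  stopifnot(familiarity %in% c("A", "B"), congruity %in% c("X", "Y"))
  list(s_p = unname(mapping$s_p[familiarity]),
       delta = unname(mapping$delta[congruity]),
       s_l = mapping$s_l)
}

#' @rdname condition_params
#' @export
condition_gain <- function(familiarity, congruity,
                           mapping = default_condition_mapping()) {
  validate_condition_mapping(mapping)
  sp <- unname(mapping$s_p[as.character(familiarity)])
  d <- unname(mapping$delta[as.character(congruity)])
  co <- gain_coefficients(sp, mapping$s_l)
  co$alpha * d^2 + co$beta
}

#' Build a randomized trial schedule
#'
#' Per subject, \code{n_sets} presentation sets are generated; each set is
#' an independent random permutation of the stimulus list, so every
#' stimulus appears exactly once per set. Inter-stimulus intervals are
#' drawn uniformly from \code{isi_range_ms}. With the default 8 stimuli,
#' 20 sets reproduce the 160-trial main session and 5 sets the 40-trial
#' sound-only session.
#'
#' @param stimuli Stimulus data frame, see \code{\link{default_stimuli}}.
#' @param n_sets Number of presentation sets per subject, >= 1.
#' @param isi_range_ms Length-2 numeric, ISI bounds in ms.
#' @param n_subjects Number of subjects, >= 1.
#' @param seed RNG seed; \code{NULL} uses the current RNG stream (for
#'   composition inside an already-seeded simulation).
#' @return Data frame of class \code{trial_schedule}: \code{subject},
#'   \code{presentation_set}, \code{trial} (index within subject), the
#'   stimulus columns, and \code{isi_ms}.
#' @export
build_schedule <- function(stimuli = default_stimuli(), n_sets = 20L,
                           isi_range_ms = c(1000, 2000), n_subjects = 1L,
                           seed = NULL) {
  if (!is.data.frame(stimuli) || nrow(stimuli) == 0L)
    stop("'stimuli' must be a non-empty data frame", call. = FALSE)
  if (n_sets < 1 || n_subjects < 1)
    stop("'n_sets' and 'n_subjects' must be >= 1", call. = FALSE)
  if (length(isi_range_ms) != 2L || !all(is.finite(isi_range_ms)) ||
      isi_range_ms[1] > isi_range_ms[2] || isi_range_ms[1] < 0)
    stop("'isi_range_ms' must be a valid [lo, hi] range", call. = FALSE)
  build <- function() {
    k <- nrow(stimuli)
    rows <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      ord <- unlist(lapply(seq_len(n_sets), function(i) sample.int(k)))
      df <- stimuli[ord, , drop = FALSE]
      df$subject <- s
      df$presentation_set <- rep(seq_len(n_sets), each = k)
      df$trial <- seq_len(n_sets * k)
      df$isi_ms <- stats::runif(n_sets * k, isi_range_ms[1], isi_range_ms[2])
      rows[[s]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    front <- c("subject", "presentation_set", "trial")
    out <- out[c(front, setdiff(names(out), front))]
    class(out) <- c("trial_schedule", "data.frame")
    out
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Default Likert response-model settings
#'
#' Latent surprise is affine in the trial's information gain
#' (\code{intercept + slope * G}) plus a Gaussian per-subject offset and
#' per-trial noise, then discretised onto the 4-point scale by the fixed,
#' equally spaced cut points.
#'
#' @return List of \code{intercept}, \code{slope} (rating units per nat),
#'   \code{noise_sd}, \code{subject_sd}, \code{cut_points}.
#' @export
default_likert_config <- function() {
  list(intercept = 1.0, slope = 0.6, noise_sd = 0.5, subject_sd = 0.3,
       cut_points = c(1.5, 2.5, 3.5))
}

#' Simulate 4-level Likert surprise ratings for a schedule
#'
#' @param schedule A \code{\link{build_schedule}} result (needs columns
#'   \code{subject}, \code{familiarity}, \code{congruity}).
#' @param mapping Condition-to-parameter mapping.
#' @param config Response model settings, see
#'   \code{\link{default_likert_config}}.
#' @param seed RNG seed; \code{NULL} uses the current stream.
#' @return The schedule with extra columns \code{gain} (nats),
#'   \code{latent} and \code{rating} (integer 1-4).
#' @export
simulate_likert <- function(schedule, mapping = default_condition_mapping(),
                            config = default_likert_config(), seed = NULL) {
  stopifnot(all(c("subject", "familiarity", "congruity") %in% names(schedule)))
  if (config$noise_sd < 0 || config$subject_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  run <- function() {
    n <- nrow(schedule)
    G <- condition_gain(schedule$familiarity, schedule$congruity, mapping)
    subs <- sort(unique(schedule$subject))
    eff <- stats::rnorm(length(subs), 0, config$subject_sd)
    names(eff) <- as.character(subs)
    latent <- config$intercept + config$slope * G +
      eff[as.character(schedule$subject)] +
      stats::rnorm(n, 0, config$noise_sd)
    rating <- findInterval(latent, config$cut_points) + 1L
    out <- schedule
    out$gain <- G
    out$latent <- unname(latent)
    out$rating <- rating
    class(out) <- "data.frame"
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# --- ERP synthesis and P300 extraction ------------------------------------

#' Default synthetic ERP settings
#'
#' Epochs are sampled at 500 Hz from -200 ms to +1500 ms around video
#' onset (850 samples; sample i sits at -200 + 2i ms, the +1500 ms
#' endpoint excluded), with the percussive sound at +500 ms. Each epoch is
#' a Gaussian-shaped P300 bump (latency jittered around 350 ms post-sound,
#' width 50 ms) whose amplitude grows linearly with the trial's
#' information gain, plus a random linear drift and white sensor noise.
#' Amplitudes are in microvolts.
#'
#' @return List of timebase and generator settings; see source for fields.
#' @export
default_erp_config <- function() {
  list(sampling_hz = 500, t_start_ms = -200, n_samples = 850L,
       sound_onset_ms = 500,
       latency_mean_ms = 350, latency_sd_ms = 30, width_ms = 50,
       amp_intercept_uv = 2, amp_slope_uv_per_nat = 3,
       noise_sd_uv = 10, drift_sd_uv_per_s = 1, subject_sd_uv = 1,
       artifact_threshold_uv = 100,
       p300_window_ms = c(250, 600), baseline_ms = 200)
}

#' Sample times of an ERP epoch
#'
#' @param config ERP settings, see \code{\link{default_erp_config}}.
#' @return Numeric vector of sample times in ms relative to video onset.
#' @export
epoch_times <- function(config = default_erp_config()) {
  step <- 1000 / config$sampling_hz
  config$t_start_ms + step * (seq_len(config$n_samples) - 1L)
}

# Vectorised forward model: one row per trial. `amp_offset` carries
# subject-level amplitude effects; RNG comes from the current stream.
synthesize_epoch_matrix <- function(G, config = default_erp_config(),
                                    amp_offset = 0) {
  n <- length(G)
  t <- epoch_times(config)
  lat <- stats::rnorm(n, config$latency_mean_ms, config$latency_sd_ms)
  amp <- config$amp_intercept_uv + config$amp_slope_uv_per_nat * G + amp_offset
  center <- config$sound_onset_ms + lat
  bump <- amp * exp(-(outer(center, t, `-`))^2 / (2 * config$width_ms^2))
  drift <- if (config$drift_sd_uv_per_s > 0)
    outer(stats::rnorm(n, 0, config$drift_sd_uv_per_s), t / 1000)
  else 0
  noise <- if (config$noise_sd_uv > 0)
    matrix(stats::rnorm(n * length(t), 0, config$noise_sd_uv), nrow = n)
  else 0
  m <- bump + drift + noise
  dimnames(m) <- NULL
  m
}

#' Synthesize a single ERP epoch
#'
#' Forward model used to make the P300 extraction rules testable: a
#' Gaussian bump at \code{sound_onset + latency} with amplitude
#' \code{amp_intercept + amp_slope * G}, plus linear drift and white
#' noise. With noise, drift and latency jitter disabled the
#' synthesize-extract round trip is exact.
#'
#' @param G Information gain driving the P300 amplitude (nats).
#' @param config ERP settings, see \code{\link{default_erp_config}}.
#' @param seed RNG seed; \code{NULL} uses the current stream.
#' @param channel Channel label (default "Pz", the dominant P300 site).
#' @return Numeric vector of class \code{erp_epoch} (microvolts) with
#'   attributes \code{times_ms}, \code{sound_onset_ms}, \code{channel}.
#' @export
synthesize_epoch <- function(G, config = default_erp_config(), seed = NULL,
                             channel = "Pz") {
  check_scalar(G, "G")
  for (f in c("latency_sd_ms", "noise_sd_uv", "drift_sd_uv_per_s"))
    if (config[[f]] < 0) stop("configuration error: '", f, "' must be >= 0",
                              call. = FALSE)
  if (config$width_ms <= 0)
    stop("configuration error: 'width_ms' must be > 0", call. = FALSE)
  m <- if (is.null(seed)) synthesize_epoch_matrix(G, config)
  else with_seed(seed, synthesize_epoch_matrix(G, config))
  structure(as.numeric(m[1L, ]), class = "erp_epoch",
            times_ms = epoch_times(config),
            sound_onset_ms = config$sound_onset_ms, channel = channel)
}

#' Extract the P300 from an epoch or averaged waveform
#'
#' Applies the analysis rules of the ERP pipeline: the mean of the 200 ms
#' pre-onset segment is the baseline and is subtracted; epochs whose
#' baseline-corrected signal exceeds +/- 100 microvolts anywhere are
#' rejected as ocular artifacts; otherwise the P300 is the largest
#' positive peak 250-600 ms after sound onset, reported as
#' baseline-to-peak amplitude and latency (ties broken toward the
#' earliest latency).
#'
#' @param epoch Numeric vector of samples on the standard timebase (an
#'   \code{erp_epoch} or any vector of matching length).
#' @param config ERP settings (timebase, windows, artifact threshold).
#' @return List of class \code{p300_measurement}: \code{amplitude_uv},
#'   \code{latency_ms} (relative to sound onset; \code{NA} when
#'   rejected) and \code{rejected}.
#' @export
extract_p300 <- function(epoch, config = default_erp_config()) {
  x <- as.numeric(epoch)
  t <- epoch_times(config)
  if (length(x) != length(t))
    stop("epoch length does not match the configured timebase",
         call. = FALSE)
  win <- config$sound_onset_ms + config$p300_window_ms
  if (win[2] > max(t) || win[1] < min(t))
    stop("P300 search window lies outside the epoch", call. = FALSE)
  base_idx <- t >= config$t_start_ms & t < config$t_start_ms + config$baseline_ms
  if (!any(base_idx)) stop("empty baseline segment", call. = FALSE)
  x <- x - mean(x[base_idx])
  if (any(abs(x) > config$artifact_threshold_uv)) {
    return(structure(list(amplitude_uv = NA_real_, latency_ms = NA_real_,
                          rejected = TRUE), class = "p300_measurement"))
  }
  sel <- which(t >= win[1] & t <= win[2])
  i <- sel[which.max(x[sel])]  # which.max: first max = earliest latency
  structure(list(amplitude_uv = x[i],
                 latency_ms = t[i] - config$sound_onset_ms,
                 rejected = FALSE),
            class = "p300_measurement")
}

#' Average ERP epochs by group
#'
#' Pointwise mean of the baseline-corrected, artifact-free epochs within
#' each group (e.g. subject x condition), the standard ERP grand-average.
#' Rejected epochs (any baseline-corrected sample beyond the artifact
#' threshold) are excluded before averaging.
#'
#' @param epochs Numeric matrix, one row per epoch, columns on the
#'   standard timebase.
#' @param groups Vector or data frame of grouping keys, one row/element
#'   per epoch.
#' @param config ERP settings.
#' @return List with \code{waveforms} (matrix, one row per group),
#'   \code{n} (epochs averaged per group) and \code{n_rejected}. Groups
#'   left empty after artifact rejection are reported with \code{n = 0}
#'   and an all-\code{NA} waveform.
#' @export
average_erp <- function(epochs, groups, config = default_erp_config()) {
  epochs <- as.matrix(epochs)
  t <- epoch_times(config)
  if (ncol(epochs) != length(t))
    stop("epoch matrix does not match the configured timebase", call. = FALSE)
  key <- if (is.data.frame(groups))
    interaction(groups, drop = FALSE, lex.order = TRUE, sep = ".")
  else factor(groups)
  if (length(key) != nrow(epochs))
    stop("'groups' must have one entry per epoch", call. = FALSE)
  base_idx <- t >= config$t_start_ms & t < config$t_start_ms + config$baseline_ms
  corrected <- epochs - rowMeans(epochs[, base_idx, drop = FALSE])
  keep <- apply(abs(corrected) <= config$artifact_threshold_uv, 1L, all)
  lev <- levels(key)
  waves <- matrix(NA_real_, nrow = length(lev), ncol = ncol(epochs),
                  dimnames = list(lev, NULL))
  n <- table(factor(key[keep], levels = lev))
  if (any(keep)) {
    gk <- factor(key[keep], levels = lev)
    sums <- rowsum(corrected[keep, , drop = FALSE], group = gk)
    cnt <- as.integer(table(gk)[rownames(sums)])
    waves[rownames(sums), ] <- sums / cnt
  }
  list(waveforms = waves, n = as.integer(n),
       n_rejected = sum(!keep), groups = lev)
}

#' Simulate the full audiovisual-incongruity experiment
#'
#' End-to-end synthetic replica of the main video session: a randomized
#' schedule (\code{n_subjects} x \code{n_sets} sets x 8 stimuli), per-trial
#' Likert surprise ratings, per-trial ERP epochs with
#' information-gain-scaled P300s, per-subject-by-condition averaged
#' waveforms, and a P300 measurement table ready for repeated-measures
#' ANOVA.
#'
#' @param n_subjects Number of simulated subjects (default 9).
#' @param n_sets Presentation sets per subject (default 20).
#' @param stimuli Stimulus set (default the 8-video table).
#' @param mapping Condition-to-parameter mapping.
#' @param erp_config ERP generator/extraction settings.
#' @param likert_config Likert generator settings.
#' @param isi_range_ms ISI bounds in ms.
#' @param seed RNG seed (required: the run is stochastic).
#' @param keep_epochs Keep the raw epoch matrix in the result (default
#'   \code{TRUE}; disable to save memory in replicate studies).
#' @return List of class \code{experiment_sim}: \code{schedule},
#'   \code{ratings}, \code{epochs} (or \code{NULL}), \code{averages}
#'   (per subject x condition), \code{p300} (subject, familiarity,
#'   congruity, amplitude_uv, latency_ms, n_epochs), and the configs used.
#' @export
simulate_experiment <- function(n_subjects = 9L, n_sets = 20L,
                                stimuli = default_stimuli(),
                                mapping = default_condition_mapping(),
                                erp_config = default_erp_config(),
                                likert_config = default_likert_config(),
                                isi_range_ms = c(1000, 2000),
                                seed, keep_epochs = TRUE) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required: the simulation is stochastic", call. = FALSE)
  validate_condition_mapping(mapping)
  with_seed(seed, {
    sched <- build_schedule(stimuli, n_sets, isi_range_ms, n_subjects)
    ratings <- simulate_likert(sched, mapping, likert_config)
    G <- ratings$gain
    subs <- sort(unique(sched$subject))
    amp_eff <- stats::rnorm(length(subs), 0, erp_config$subject_sd_uv)
    epochs <- synthesize_epoch_matrix(G, erp_config,
                                      amp_offset = amp_eff[match(sched$subject, subs)])
    grp <- data.frame(subject = sched$subject,
                      familiarity = sched$familiarity,
                      congruity = sched$congruity)
    avg <- average_erp(epochs, grp, erp_config)
    keys <- do.call(rbind, strsplit(avg$groups, ".", fixed = TRUE))
    meas <- lapply(seq_along(avg$groups), function(i) {
      if (avg$n[i] == 0L)
        return(list(amplitude_uv = NA_real_, latency_ms = NA_real_,
                    rejected = TRUE))
      # averages are already baseline-corrected and artifact-free;
      # extract_p300 re-corrects, which is idempotent on a corrected wave
      extract_p300(avg$waveforms[i, ], erp_config)
    })
    p300 <- data.frame(
      subject = as.integer(keys[, 1]),
      familiarity = factor(keys[, 2], levels = c("A", "B")),
      congruity = factor(keys[, 3], levels = c("X", "Y")),
      amplitude_uv = vapply(meas, `[[`, numeric(1), "amplitude_uv"),
      latency_ms = vapply(meas, `[[`, numeric(1), "latency_ms"),
      n_epochs = avg$n)
    structure(list(schedule = sched, ratings = ratings,
                   epochs = if (keep_epochs) epochs else NULL,
                   averages = avg, p300 = p300,
                   mapping = mapping, erp_config = erp_config,
                   likert_config = likert_config, seed = seed),
              class = "experiment_sim")
  })
}

#' @export
print.experiment_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic audiovisual experiment: %d subjects, %d trials each (seed %s)\n",
    length(unique(x$schedule$subject)),
    max(x$schedule$trial), format(x$seed)))
  cat("Condition-mean P300 amplitude (uV):\n")
  print(round(tapply(x$p300$amplitude_uv,
                     list(x$p300$familiarity, x$p300$congruity),
                     mean, na.rm = TRUE), 3))
  invisible(x)
}
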