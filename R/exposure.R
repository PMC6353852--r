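#' Simulate repeated exposure to a stimulus (desensitization)
#'
#' Iterates the conjugate Gaussian update: at each exposure the current
#' belief is updated with an observation of the same stimulus, and the
#' posterior becomes the next prior while the noise \code{s_l} stays
#' fixed. Uncertainty shrinks deterministically by precision additivity
#' (after k exposures the variance is \eqn{1/(1/s_{p0} + k/s_l)}) and, in
#' the noise-free case, the prediction error shrinks geometrically
#' (\eqn{\delta_{k+1} = \delta_k\, s_l/(s_{p,k}+s_l)}). The per-exposure
#' information gain therefore eventually declines — the model's account of
#' emotional desensitization — and valence tracks the inverted-U curve
#' from the high-gain side back toward low gain.
#'
#' @param initial A \code{\link{gaussian_belief}}: the naive prior.
#' @param stimulus_value The true stimulus feature observed each time.
#' @param s_l Likelihood (external noise) variance per exposure, > 0.
#' @param n_steps Number of exposures, >= 1.
#' @param valence_params Optional \code{\link{valence_params}}; when
#'   supplied, a valence column is computed from each step's gain.
#' @param observation_noise_sd Standard deviation of Gaussian noise on the
#'   observed sample mean (0 = deterministic: every observation equals
#'   \code{stimulus_value} exactly).
#' @param seed RNG seed; required when \code{observation_noise_sd > 0}.
#' @return A data frame of class \code{exposure_trajectory}, one row per
#'   exposure: \code{exposure}, \code{prior_mean}, \code{prior_variance},
#'   \code{prediction_error}, \code{gain} (nats) and, if requested,
#'   \code{valence}.
#' @examples
#' traj <- simulate_exposures(gaussian_belief(0, 1), 2, s_l = 0.5,
#'                            n_steps = 10)
#' traj$gain  # declines as the stimulus becomes familiar
#' @export
simulate_exposures <- function(initial, stimulus_value, s_l, n_steps,
                               valence_params = NULL,
                               observation_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(initial, "gaussian_belief"))
  check_scalar(stimulus_value, "stimulus_value")
  check_variance(s_l, "s_l")
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1 ||
      n_steps != round(n_steps))
    stop("'n_steps' must be a single integer >= 1", call. = FALSE)
  check_scalar(observation_noise_sd, "observation_noise_sd")
  if (observation_noise_sd < 0)
    stop("'observation_noise_sd' must be >= 0", call. = FALSE)
  if (!is.null(valence_params)) validate_valence_params(valence_params)
  if (observation_noise_sd > 0 && is.null(seed))
    stop("a seed is required for a stochastic run", call. = FALSE)

  noise <- if (observation_noise_sd > 0)
    with_seed(seed, stats::rnorm(n_steps, 0, observation_noise_sd))
  else rep(0, n_steps)

  belief <- initial
  rows <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    obs <- observation(stimulus_value + noise[k], sl = s_l)
    dec <- gain_from_update(belief, obs)
    rows[[k]] <- data.frame(
      exposure = k,
      prior_mean = belief$mean,
      prior_variance = belief$variance,
      prediction_error = dec$prediction_error,
      gain = dec$gain)
    belief <- update_belief(belief, obs)
  }
  out <- do.call(rbind, rows)
  if (!is.null(valence_params))
    out$valence <- valence(out$gain, valence_params)
  class(out) <- c("exposure_trajectory", "data.frame")
  out
}
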