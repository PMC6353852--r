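#' Kullback-Leibler divergence between two Gaussians
#'
#' \eqn{D_{KL}(p \,\|\, q)} in nats for \eqn{p = N(\mu_p, v_p)} and
#' \eqn{q = N(\mu_q, v_q)}:
#' \deqn{\frac{1}{2}\left[\frac{v_p + (\mu_p-\mu_q)^2}{v_q} - 1 +
#'   \ln\frac{v_q}{v_p}\right]}
#' Non-negative, zero iff the two distributions coincide, and asymmetric
#' in its arguments.
#'
#' @param p_mean,p_var Mean and variance of \code{p} (the posterior, in the
#'   information-gain reading).
#' @param q_mean,q_var Mean and variance of \code{q} (the prior).
#' @return Divergence in nats.
#' @export
kl_gaussian <- function(p_mean, p_var, q_mean, q_var) {
  check_scalar(p_mean, "p_mean"); check_scalar(q_mean, "q_mean")
  check_variance(p_var, "p_var"); check_variance(q_var, "q_var")
  0.5 * ((p_var + (p_mean - q_mean)^2) / q_var - 1 + log(q_var / p_var))
}

#' Quadratic coefficients of information gain in the prediction error
#'
#' Holding uncertainty \code{s_p} and noise \code{s_l} fixed, information
#' gain is quadratic in the prediction error delta: \eqn{G = \alpha\delta^2
#' + \beta} with
#' \deqn{\alpha = \frac{s_p}{2(s_p+s_l)^2}, \qquad
#'   \beta = \frac{1}{2}\left[\ln\frac{s_p+s_l}{s_l} -
#'   \frac{s_p}{s_p+s_l}\right].}
#' \code{alpha} is strictly positive (gain always grows with the squared
#' prediction error) and \code{beta}, the gain at zero prediction error, is
#' strictly increasing in \code{s_p}: more uncertain observers gain more
#' from an unsurprising event. The partial derivative of beta in s_p equals
#' alpha, hence positive.
#'
#' @param s_p Prior uncertainty (variance), > 0. Vectorised.
#' @param s_l External noise (likelihood variance), > 0.
#' @return List with numeric components \code{alpha} and \code{beta}.
#' @export
gain_coefficients <- function(s_p, s_l) {
  if (!is.numeric(s_p) || !length(s_p) || any(!is.finite(s_p) | s_p <= 0))
    stop("'s_p' must be strictly positive and finite", call. = FALSE)
  if (!is.numeric(s_l) || !length(s_l) || any(!is.finite(s_l) | s_l <= 0))
    stop("'s_l' must be strictly positive and finite", call. = FALSE)
  tot <- s_p + s_l
  list(alpha = s_p / (2 * tot^2),
       beta = 0.5 * (log(tot / s_l) - s_p / tot))
}

#' Information gain (arousal) from prediction error, uncertainty and noise
#'
#' The closed form of the KL divergence of the Bayesian posterior from the
#' prior after a conjugate Gaussian update:
#' \deqn{G(\delta, s_p, s_l) = \frac{1}{2}\left[
#'   \frac{s_p\,\delta^2}{(s_p+s_l)^2} + \ln\frac{s_p+s_l}{s_l} -
#'   \frac{s_p}{s_p+s_l}\right]}
#' where \eqn{\delta = \bar{x} - \eta} is the prediction error (reality
#' minus expectation). G is even in delta, strictly increasing in
#' \eqn{\delta^2}, and non-negative; it is the model's arousal quantity.
#'
#' @param delta Prediction error; any real.
#' @param s_p Prior uncertainty (variance), > 0.
#' @param s_l External noise (likelihood variance), > 0.
#' @return An object of class \code{gain_decomposition}: a list with
#'   fields \code{prediction_error}, \code{uncertainty}, \code{noise},
#'   \code{alpha}, \code{beta} and \code{gain} (nats).
#' @examples
#' g <- information_gain(0, 0.1, 0.1)
#' g$gain  # 0.5 * (log(2) - 0.5), about 0.0966 nats
#' @export
information_gain <- function(delta, s_p, s_l) {
  check_scalar(delta, "delta")
  check_variance(s_p, "s_p")
  check_variance(s_l, "s_l")
  co <- gain_coefficients(s_p, s_l)
  structure(list(prediction_error = delta, uncertainty = s_p, noise = s_l,
                 alpha = co$alpha, beta = co$beta,
                 gain = co$alpha * delta^2 + co$beta),
            class = "gain_decomposition")
}

#' Information gain of an observation under a prior belief
#'
#' Convenience wrapper: sets \eqn{\delta = \bar{x} - \eta} and the two
#' variances from a prior/observation pair and returns the decomposed gain.
#' Identical (to floating point) to \code{kl_gaussian} of
#' \code{update_belief}'s posterior from the prior.
#'
#' @param prior A \code{\link{gaussian_belief}}.
#' @param obs An \code{\link{observation}}.
#' @return A \code{gain_decomposition}; see \code{\link{information_gain}}.
#' @export
gain_from_update <- function(prior, obs) {
  stopifnot(inherits(prior, "gaussian_belief"), inherits(obs, "observation"))
  information_gain(obs$sample_mean - prior$mean, prior$variance, obs$sl)
}

#' @export
print.gain_decomposition <- function(x, ...) {
  cat(sprintf(
    "Information gain: G = %.6g nats (delta %.4g, s_p %.4g, s_l %.4g)\n",
    x$gain, x$prediction_error, x$uncertainty, x$noise))
  cat(sprintf("  quadratic form: alpha %.6g, beta %.6g\n", x$alpha, x$beta))
  invisible(x)
}
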