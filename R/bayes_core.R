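#' Gaussian belief over an estimated stimulus mean
#'
#' A belief about the mean of a stimulus feature, held before (prior) an
#' event is experienced. The variance of the belief, \code{s_p}, is the
#' observer's *uncertainty*: it is monotone in the prior's differential
#' entropy, so an unfamiliar stimulus (little prior knowledge) corresponds
#' to a large \code{s_p}.
#'
#' @param mean Expected value of the stimulus feature (eta).
#' @param variance Strictly positive prior variance (s_p = tau^2).
#' @return An object of class \code{gaussian_belief} with fields
#'   \code{mean} and \code{variance}.
#' @examples
#' b <- gaussian_belief(0, 1)
#' prior_entropy(b)
#' @export
gaussian_belief <- function(mean, variance) {
  check_scalar(mean, "mean")
  check_variance(variance, "variance")
  structure(list(mean = mean, variance = variance),
            class = "gaussian_belief")
}

#' Observation of a stimulus feature
#'
#' Sensory data gathered from an event: the sample mean of \code{n} draws
#' with per-sample variance \code{sigma2}. The effective likelihood
#' variance, the *external noise*, is \code{s_l = sigma2 / n}. The noise
#' may be given directly via \code{sl} instead of \code{(sigma2, n)}.
#'
#' @param sample_mean Observed sample mean (x-bar), the likelihood peak.
#' @param sigma2 Per-sample variance; strictly positive. Ignored when
#'   \code{sl} is supplied.
#' @param n Number of samples (integer >= 1). Ignored when \code{sl} is
#'   supplied.
#' @param sl Likelihood variance supplied directly; strictly positive.
#' @return An object of class \code{observation} with fields
#'   \code{sample_mean}, \code{sigma2}, \code{n} and \code{sl}.
#' @examples
#' observation(1.5, sigma2 = 0.8, n = 4)  # s_l = 0.2
#' observation(1.5, sl = 0.2)             # equivalent
#' @export
observation <- function(sample_mean, sigma2 = NULL, n = 1L, sl = NULL) {
  check_scalar(sample_mean, "sample_mean")
  if (is.null(sl)) {
    check_variance(sigma2, "sigma2")
    if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
        n < 1 || n != round(n))
      stop("'n' must be a single integer >= 1", call. = FALSE)
    sl <- sigma2 / n
  } else {
    check_variance(sl, "sl")
    sigma2 <- sl * n
  }
  structure(list(sample_mean = sample_mean, sigma2 = sigma2,
                 n = as.integer(n), sl = sl),
            class = "observation")
}

#' Conjugate Gaussian belief update
#'
#' Updates a Gaussian prior \code{N(eta, s_p)} with a Gaussian likelihood
#' peaked at the sample mean with variance \code{s_l}, returning the
#' Gaussian posterior with precision-weighted mean
#' \eqn{(s_p \bar{x} + s_l \eta)/(s_p + s_l)} and variance
#' \eqn{s_p s_l/(s_p + s_l)}. Posterior precision is the sum of prior and
#' likelihood precisions, so the posterior variance is always smaller than
#' either input variance.
#'
#' @param prior A \code{\link{gaussian_belief}}.
#' @param obs An \code{\link{observation}}.
#' @return A \code{gaussian_belief} representing the posterior.
#' @examples
#' post <- update_belief(gaussian_belief(0, 1), observation(2, sl = 1))
#' post$mean      # 1: equal precisions, midpoint
#' post$variance  # 0.5
#' @export
update_belief <- function(prior, obs) {
  stopifnot(inherits(prior, "gaussian_belief"), inherits(obs, "observation"))
  sp <- prior$variance
  sl <- obs$sl
  # shift form of the precision-weighted mean: exact when xbar == eta
  gaussian_belief(
    mean = prior$mean + sp * (obs$sample_mean - prior$mean) / (sp + sl),
    variance = sp * sl / (sp + sl)
  )
}

#' Differential entropy of a Gaussian belief
#'
#' \eqn{H = \frac{1}{2}\ln(2\pi e\, s_p)} in nats; strictly increasing in
#' the uncertainty \code{s_p}, which is why prior variance stands in for
#' prior entropy throughout the model.
#'
#' @param belief A \code{\link{gaussian_belief}}.
#' @return Entropy in nats.
#' @export
prior_entropy <- function(belief) {
  stopifnot(inherits(belief, "gaussian_belief"))
  0.5 * log(2 * pi * exp(1) * belief$variance)
}

#' Density of a Gaussian belief
#'
#' Thin wrapper over \code{\link[stats]{dnorm}} on the belief's
#' (mean, variance); used by the quadrature oracles in the test suite.
#'
#' @param belief A \code{\link{gaussian_belief}}.
#' @param x Numeric vector of evaluation points.
#' @return Density values.
#' @export
belief_density <- function(belief, x) {
  stopifnot(inherits(belief, "gaussian_belief"))
  stats::dnorm(x, mean = belief$mean, sd = sqrt(belief$variance))
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("Gaussian belief: mean %.6g, variance %.6g (entropy %.4f nats)\n",
              x$mean, x$variance, prior_entropy(x)))
  invisible(x)
}

#' @export
print.observation <- function(x, ...) {
  cat(sprintf("Observation: x-bar %.6g, sigma^2 %.6g, n %d (s_l = %.6g)\n",
              x$sample_mean, x$sigma2, x$n, x$sl))
  invisible(x)
}

#' Read model parameters from a flat key/value config file
#'
#' The file is in DCF format (\code{key: value} lines). Recognised keys:
#' \code{prior_mean}, \code{prior_variance}, \code{obs_mean},
#' \code{obs_variance}, \code{n} (all numeric). Returns the assembled
#' prior and observation.
#'
#' @param path Path to the config file.
#' @return A list with elements \code{prior} (\code{gaussian_belief}) and
#'   \code{obs} (\code{observation}).
#' @export
read_model_config <- function(path) {
  kv <- read_config(path)
  need <- c("prior_mean", "prior_variance", "obs_mean", "obs_variance")
  miss <- setdiff(need, names(kv))
  if (length(miss))
    stop("config missing keys: ", paste(miss, collapse = ", "), call. = FALSE)
  n <- if ("n" %in% names(kv)) kv[["n"]] else 1
  list(prior = gaussian_belief(kv[["prior_mean"]], kv[["prior_variance"]]),
       obs = observation(kv[["obs_mean"]], sigma2 = kv[["obs_variance"]],
                         n = n))
}

# internal validators -------------------------------------------------------

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

check_variance <- function(x, name) {
  check_scalar(x, name)
  if (x <= 0)
    stop(sprintf("'%s' must be strictly positive (got %g)", name, x),
         call. = FALSE)
  invisible(x)
}

# Flat DCF config reader: all values coerced to numeric where possible.
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  m <- read.dcf(path)
  vals <- as.list(m[1L, ])
  lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) trimws(v) else num
  })
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is untouched (no hidden state contract).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
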