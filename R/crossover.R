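#' Does the arousal crossover occur between two uncertainty levels?
#'
#' Two gain curves \eqn{G_i = \alpha_i\delta^2 + \beta_i} at uncertainties
#' \code{s_p1}, \code{s_p2} (shared noise \code{s_l}) intersect at a real
#' prediction error iff \eqn{s_{p1} s_{p2} > s_l^2}: the more uncertain
#' observer gains more at small prediction errors, the less uncertain one
#' at large prediction errors. Since prior uncertainty typically exceeds
#' sensory noise, the crossover is the generic case.
#'
#' @param s_p1,s_p2 Two distinct uncertainty levels, > 0.
#' @param s_l Shared external noise, > 0.
#' @return \code{TRUE} iff the curves cross at some finite delta.
#' @export
crossover_exists <- function(s_p1, s_p2, s_l) {
  check_variance(s_p1, "s_p1"); check_variance(s_p2, "s_p2")
  check_variance(s_l, "s_l")
  if (s_p1 == s_p2)
    stop("degenerate input: s_p1 == s_p2 gives identical curves, no ",
         "well-defined crossover", call. = FALSE)
  s_p1 * s_p2 > s_l^2
}

#' Locate the arousal crossover point
#'
#' Solves \eqn{\alpha_1\delta^2 + \beta_1 = \alpha_2\delta^2 + \beta_2} for
#' the non-negative root \eqn{\delta^* = \sqrt{(\beta_2-\beta_1)/
#' (\alpha_1-\alpha_2)}} (curves are even in delta, so only the
#' non-negative root is reported; its mirror image is implied). On the
#' measure-zero boundary \eqn{s_{p1} s_{p2} = s_l^2} the quadratics are
#' parallel (equal alpha, distinct beta) and never meet; this returns
#' \code{exists = FALSE} rather than an error.
#'
#' @inheritParams crossover_exists
#' @return A list of class \code{crossover_result}: \code{exists}
#'   (logical), \code{delta_star} (crossing prediction error, \code{NA} if
#'   none) and \code{gain_at_crossover} (common gain value, \code{NA} if
#'   none).
#' @examples
#' crossover_point(0.2, 1.0, 0.1)  # crosses near delta = 0.87
#' @export
crossover_point <- function(s_p1, s_p2, s_l) {
  exists <- crossover_exists(s_p1, s_p2, s_l)
  if (!exists) {
    return(structure(list(exists = FALSE, delta_star = NA_real_,
                          gain_at_crossover = NA_real_),
                     class = "crossover_result"))
  }
  c1 <- gain_coefficients(s_p1, s_l)
  c2 <- gain_coefficients(s_p2, s_l)
  d2 <- (c2$beta - c1$beta) / (c1$alpha - c2$alpha)
  delta_star <- sqrt(d2)
  structure(list(exists = TRUE, delta_star = delta_star,
                 gain_at_crossover = c1$alpha * d2 + c1$beta),
            class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  if (x$exists)
    cat(sprintf("Arousal crossover at delta* = %.6g (G = %.6g nats)\n",
                x$delta_star, x$gain_at_crossover))
  else cat("No arousal crossover: curves do not intersect\n")
  invisible(x)
}

#' Family of information-gain curves over a prediction-error grid
#'
#' Tabulates G(delta) for several uncertainty levels at a shared noise,
#' over an evenly spaced grid of non-negative prediction errors — the
#' curve family whose pairwise intersections are the arousal crossover.
#' Larger uncertainty gives the larger intercept at delta = 0; each series
#' is nondecreasing in delta.
#'
#' @param s_p_list Numeric vector of uncertainty levels, all > 0.
#' @param s_l Shared external noise, > 0.
#' @param delta_max Right edge of the delta grid (default 5).
#' @param n_points Number of grid points (default 500, >= 2).
#' @return A data frame of class \code{gain_curve_table}: column
#'   \code{delta} then one gain column \code{sp_<level>} per uncertainty.
#' @export
gain_curve_family <- function(s_p_list, s_l, delta_max = 5, n_points = 500L) {
  if (!is.numeric(s_p_list) || !length(s_p_list))
    stop("'s_p_list' must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(s_p_list) | s_p_list <= 0))
    stop("all uncertainties must be strictly positive", call. = FALSE)
  check_variance(s_l, "s_l")
  check_scalar(delta_max, "delta_max")
  if (delta_max <= 0) stop("'delta_max' must be positive", call. = FALSE)
  if (n_points < 2) stop("'n_points' must be at least 2", call. = FALSE)
  delta <- seq(0, delta_max, length.out = n_points)
  out <- data.frame(delta = delta)
  for (sp in s_p_list) {
    co <- gain_coefficients(sp, s_l)
    out[[sprintf("sp_%g", sp)]] <- co$alpha * delta^2 + co$beta
  }
  attr(out, "s_l") <- s_l
  attr(out, "s_p_list") <- s_p_list
  class(out) <- c("gain_curve_table", "data.frame")
  out
}

#' @export
plot.gain_curve_table <- function(x, ...) {
  cols <- setdiff(names(x), "delta")
  graphics::matplot(x$delta, as.matrix(x[cols]), type = "l", lty = 1,
                    xlab = "prediction error", ylab = "information gain (nats)",
                    main = "Arousal crossover: gain curves by uncertainty", ...)
  graphics::legend("topleft", legend = cols, col = seq_along(cols), lty = 1,
                   bty = "n")
  invisible(x)
}
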