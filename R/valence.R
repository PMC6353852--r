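#' Parameters of the reward/aversion valence model
#'
#' Hedonic valence is modelled, following Berlyne's two-system account, as
#' the sum of a positive reward sigmoid and a negative aversion sigmoid of
#' information gain G:
#' \deqn{Reward(G) = \frac{h_r}{1 + e^{-c_r G + G_r}}, \qquad
#'   Aversion(G) = \frac{-h_a}{1 + e^{-c_a G + G_a}}}
#' Two orderings are structural: the aversion system activates later
#' (\eqn{G_r < G_a}) and saturates deeper (\eqn{h_r < h_a}), so valence
#' rises then falls with G (inverted U) and tends to the negative limit
#' \eqn{h_r - h_a} for extreme gain.
#'
#' The defaults (G_r 2, G_a 6, h_r 1, h_a 1.5, c_r 1, c_a 1) are a
#' concrete choice satisfying both orderings with a clear interior
#' optimum; the model itself fixes no numeric scale.
#'
#' @param G_r,G_a Activation thresholds (exponent offsets) of the reward
#'   and aversion systems; must satisfy \code{G_r < G_a}.
#' @param h_r,h_a Positive saturation magnitudes; must satisfy
#'   \code{h_r < h_a}.
#' @param c_r,c_a Positive sigmoid gradients in G.
#' @return A validated object of class \code{valence_params}.
#' @export
valence_params <- function(G_r = 2, G_a = 6, h_r = 1, h_a = 1.5,
                           c_r = 1, c_a = 1) {
  p <- structure(list(G_r = G_r, G_a = G_a, h_r = h_r, h_a = h_a,
                      c_r = c_r, c_a = c_a),
                 class = "valence_params")
  validate_valence_params(p)
  p
}

#' Validate valence parameters
#'
#' Checks the structural constraints of the two-system model, reporting
#' every violated constraint by name: \code{G_r < G_a} (reward activates
#' first), \code{h_r < h_a} (extreme gain is net negative), and strictly
#' positive maxima and gradients.
#'
#' @param p A \code{\link{valence_params}} (or a bare list with the same
#'   fields, as when probing deliberately invalid settings).
#' @return Invisibly \code{TRUE}; stops with a named-constraint error
#'   otherwise.
#' @export
validate_valence_params <- function(p) {
  for (f in c("G_r", "G_a", "h_r", "h_a", "c_r", "c_a"))
    check_scalar(p[[f]], f)
  bad <- character()
  if (!(p$G_r < p$G_a))
    bad <- c(bad, "threshold ordering violated: G_r < G_a required")
  if (!(p$h_r < p$h_a))
    bad <- c(bad, "maxima ordering violated: h_r < h_a required")
  if (p$h_r <= 0) bad <- c(bad, "h_r must be positive")
  if (p$h_a <= 0) bad <- c(bad, "h_a must be positive")
  if (p$c_r <= 0) bad <- c(bad, "c_r must be positive")
  if (p$c_a <= 0) bad <- c(bad, "c_a must be positive")
  if (length(bad))
    stop("invalid valence parameters: ", paste(bad, collapse = "; "),
         call. = FALSE)
  invisible(TRUE)
}

#' Reward, aversion and valence as functions of information gain
#'
#' \code{reward} is increasing in G with range \code{(0, h_r)};
#' \code{aversion} is decreasing with range \code{(-h_a, 0)};
#' \code{valence} is their sum, bounded in \code{(-h_a, h_r)} and tending
#' to \code{h_r - h_a < 0} as G grows without bound. All are vectorised
#' in \code{G}.
#'
#' @param G Information gain (nats); non-negative in the model's reading,
#'   though the sigmoids are defined for any real.
#' @param p A validated \code{\link{valence_params}}.
#' @return Numeric vector of the same length as \code{G}.
#' @examples
#' p <- valence_params()
#' reward(p$G_r / p$c_r, p)  # h_r / 2: the sigmoid midpoint
#' valence(c(0, 2, 20), p)
#' @export
reward <- function(G, p) {
  validate_valence_params(p)
  p$h_r / (1 + exp(-p$c_r * G + p$G_r))
}

#' @rdname reward
#' @export
aversion <- function(G, p) {
  validate_valence_params(p)
  -p$h_a / (1 + exp(-p$c_a * G + p$G_a))
}

#' @rdname reward
#' @export
valence <- function(G, p) {
  reward(G, p) + aversion(G, p)
}

#' Information gain maximising valence
#'
#' Locates the peak of the inverted-U valence curve on
#' \code{[0, search_bound]} by a dense grid scan followed by
#' \code{\link[stats]{optimize}} refinement on the bracketing cell
#' (tolerance 1e-8 in G). For the default parameters the optimum lies
#' between the two sigmoid midpoints \code{G_r/c_r} and \code{G_a/c_a}.
#'
#' @param p A validated \code{\link{valence_params}}.
#' @param search_bound Right edge of the search interval, > 0; default
#'   covers both sigmoid midpoints with room to saturate.
#' @param n_grid Grid size for the initial scan (default 10001).
#' @return The argmax G (a single number). If the curve is flat to within
#'   numerical resolution across the grid, an error is raised (no unique
#'   optimum).
#' @export
optimal_gain <- function(p, search_bound = NULL, n_grid = 10001L) {
  validate_valence_params(p)
  if (is.null(search_bound))
    search_bound <- 2 * max(p$G_r / p$c_r, p$G_a / p$c_a) + 10
  check_scalar(search_bound, "search_bound")
  if (search_bound <= 0) stop("'search_bound' must be > 0", call. = FALSE)
  grid <- seq(0, search_bound, length.out = n_grid)
  v <- valence(grid, p)
  if (diff(range(v)) < 1e-12)
    stop("no unique optimum: valence is flat over the search interval",
         call. = FALSE)
  i <- which.max(v)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  if (lo == hi) return(grid[i])
  opt <- stats::optimize(function(g) valence(g, p), lower = lo, upper = hi,
                         maximum = TRUE, tol = 1e-8)
  # grid endpoints can beat the interior refinement when the max is a boundary
  cand <- c(opt$maximum, grid[i])
  cand[which.max(valence(cand, p))]
}

#' Tabulate the valence curve
#'
#' @param p A validated \code{\link{valence_params}}.
#' @param G_max Right edge of the gain grid.
#' @param n_points Grid size.
#' @return Data frame with columns \code{G}, \code{reward},
#'   \code{aversion}, \code{valence}.
#' @export
valence_curve <- function(p, G_max = 12, n_points = 500L) {
  validate_valence_params(p)
  if (n_points < 2) stop("'n_points' must be at least 2", call. = FALSE)
  G <- seq(0, G_max, length.out = n_points)
  data.frame(G = G, reward = reward(G, p), aversion = aversion(G, p),
             valence = valence(G, p))
}

#' @export
print.valence_params <- function(x, ...) {
  cat(sprintf(
    "Valence parameters: G_r %.3g < G_a %.3g; h_r %.3g < h_a %.3g; c_r %.3g, c_a %.3g\n",
    x$G_r, x$G_a, x$h_r, x$h_a, x$c_r, x$c_a))
  invisible(x)
}
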