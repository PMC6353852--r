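# Independent numerical oracles used across the suite. Each reimplements
# the target quantity by brute force (dense grids, quadrature, bisection,
# stats::aov) and never calls the closed-form path it is checking.

# Posterior mean/variance by normalizing prior x likelihood on a dense grid.
oracle_grid_posterior <- function(eta, sp, xbar, sl, n = 200001L) {
  half <- 10 * sqrt(max(sp, sl))
  mu <- seq(min(eta, xbar) - half, max(eta, xbar) + half, length.out = n)
  w <- stats::dnorm(mu, eta, sqrt(sp)) * stats::dnorm(xbar, mu, sqrt(sl))
  w <- w / sum(w)
  m <- sum(w * mu)
  list(mean = m, variance = sum(w * (mu - m)^2))
}

# Differential entropy by adaptive quadrature of -p log p.
oracle_entropy <- function(mean, var) {
  f <- function(x) {
    p <- stats::dnorm(x, mean, sqrt(var))
    ifelse(p > 0, -p * log(p), 0)
  }
  stats::integrate(f, mean - 12 * sqrt(var), mean + 12 * sqrt(var),
                   rel.tol = 1e-10)$value
}

# KL divergence of N(pm, pv) from N(qm, qv) by quadrature of p log(p/q).
oracle_kl <- function(pm, pv, qm, qv) {
  f <- function(x) {
    p <- stats::dnorm(x, pm, sqrt(pv))
    ifelse(p > 0,
           p * (stats::dnorm(x, pm, sqrt(pv), log = TRUE) -
                  stats::dnorm(x, qm, sqrt(qv), log = TRUE)),
           0)
  }
  lo <- pm - 15 * sqrt(pv)
  hi <- pm + 15 * sqrt(pv)
  stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
}

gain_closed <- function(delta, sp, sl) {
  0.5 * (sp * delta^2 / (sp + sl)^2 + log((sp + sl) / sl) - sp / (sp + sl))
}

# Does G1 - G2 change sign on a dense delta scan over [0, dmax]?
oracle_crossover_scan <- function(sp1, sp2, sl, dmax = 50, n = 20001L) {
  d <- seq(0, dmax, length.out = n)
  diff <- gain_closed(d, sp1, sl) - gain_closed(d, sp2, sl)
  any(diff[-1] * diff[-n] < 0) || any(diff[-1] == 0)
}

# Root of G1 - G2 by bisection on a bracketing interval.
oracle_crossover_bisect <- function(sp1, sp2, sl, dmax = 50) {
  f <- function(d) gain_closed(d, sp1, sl) - gain_closed(d, sp2, sl)
  d <- seq(0, dmax, length.out = 20001L)
  v <- f(d)
  i <- which(v[-1] * v[-length(v)] <= 0)[1]
  stats::uniroot(f, c(d[i], d[i + 1]), tol = 1e-13)$root
}

# Argmax of valence by a two-stage dense grid (1e5 points, then 1e5 points
# on the bracketing cell): resolution far below 1e-6.
oracle_valence_argmax <- function(p, bound, n = 100001L) {
  g <- seq(0, bound, length.out = n)
  v <- valence(g, p)
  i <- which.max(v)
  lo <- g[max(1L, i - 1L)]; hi <- g[min(n, i + 1L)]
  g2 <- seq(lo, hi, length.out = n)
  g2[which.max(valence(g2, p))]
}

# Reference within-subject two-way ANOVA via stats::aov with Error strata.
oracle_aov_rm <- function(d) {
  d$subject <- factor(d$subject)
  d$A <- factor(d$A); d$B <- factor(d$B)
  fit <- stats::aov(value ~ A * B + Error(subject / (A * B)), data = d)
  s <- summary(fit)
  get_row <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- grep(paste0("^", term, "\\s*$"), rownames(tab))
    list(f = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  list(A = get_row("Error: subject:A", "A"),
       B = get_row("Error: subject:B", "B"),
       AB = get_row("Error: subject:A:B", "A:B"))
}

# Definitional brute-force SS computation with explicit loops (independent
# of the vectorised engine).
oracle_ss_brute <- function(cells) {
  ns <- dim(cells)[1]; na <- dim(cells)[2]; nb <- dim(cells)[3]
  gm <- mean(cells)
  ss <- c(S = 0, A = 0, B = 0, AB = 0, AS = 0, BS = 0, total = 0)
  for (k in 1:ns) ss["S"] <- ss["S"] + na * nb * (mean(cells[k, , ]) - gm)^2
  for (i in 1:na) ss["A"] <- ss["A"] + ns * nb * (mean(cells[, i, ]) - gm)^2
  for (j in 1:nb) ss["B"] <- ss["B"] + ns * na * (mean(cells[, , j]) - gm)^2
  for (i in 1:na) for (j in 1:nb)
    ss["AB"] <- ss["AB"] + ns * (mean(cells[, i, j]) - mean(cells[, i, ]) -
                                   mean(cells[, , j]) + gm)^2
  for (k in 1:ns) for (i in 1:na)
    ss["AS"] <- ss["AS"] + nb * (mean(cells[k, i, ]) - mean(cells[k, , ]) -
                                   mean(cells[, i, ]) + gm)^2
  for (k in 1:ns) for (j in 1:nb)
    ss["BS"] <- ss["BS"] + na * (mean(cells[k, , j]) - mean(cells[k, , ]) -
                                   mean(cells[, , j]) + gm)^2
  ss["total"] <- sum((cells - gm)^2)
  ss["ABS"] <- ss["total"] - sum(ss[c("S", "A", "B", "AB", "AS", "BS")])
  ss
}

# Balanced null long table: subject effects only, no condition effects.
null_long_table <- function(n_subjects = 9L) {
  d <- expand.grid(subject = seq_len(n_subjects), A = c("A", "B"),
                   B = c("X", "Y"), stringsAsFactors = FALSE)
  d$value <- rnorm(n_subjects)[d$subject] + rnorm(nrow(d))
  d
}

# Noise-free ERP settings for exact round-trip tests.
erp_config_noise_free <- function(amp = 10, latency = 350) {
  cfg <- default_erp_config()
  cfg$noise_sd_uv <- 0
  cfg$drift_sd_uv_per_s <- 0
  cfg$latency_sd_ms <- 0
  cfg$latency_mean_ms <- latency
  cfg$amp_intercept_uv <- amp
  cfg$amp_slope_uv_per_nat <- 0
  cfg
}
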