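#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA, the analysis applied to the
#' per-subject condition means of the P300 and Likert measures. Multiple
#' observations per subject x cell are averaged first (standard ERP
#' practice); the averaged design must then be complete and balanced — an
#' unbalanced design is an error, never silently imputed. Each effect is
#' tested against its own subject-interaction error stratum:
#' \eqn{F_A = MS_A / MS_{A \times S}} and likewise for B and A:B. With
#' 2-level factors every effect has 1 numerator df, so no sphericity
#' correction applies. A zero error stratum yields \code{F = Inf} with
#' \code{p = 0} when the effect is nonzero, and \code{F = NaN},
#' \code{p = NA} when both are zero.
#'
#' @param data Data frame in long format with columns \code{subject},
#'   \code{A}, \code{B}, \code{value} (names configurable).
#' @param subject,a,b,value Column names.
#' @return Data frame of class \code{rm_anova}: one row per effect
#'   (\code{A}, \code{B}, \code{A:B}) with \code{df_num}, \code{df_den},
#'   \code{ss}, \code{ss_error}, \code{f_value}, \code{p_value}.
#' @examples
#' d <- expand.grid(subject = 1:6, A = c("a1", "a2"), B = c("b1", "b2"))
#' d$value <- rnorm(nrow(d))
#' two_way_rm_anova(d)
#' @export
two_way_rm_anova <- function(data, subject = "subject", a = "A", b = "B",
                             value = "value") {
  d <- check_long_table(data, subject, a, b, value)
  str <- rm_anova_strata(d)
  eff <- c("A", "B", "A:B")
  out <- data.frame(
    effect = eff,
    df_num = c(str$df$A, str$df$B, str$df$AB),
    df_den = c(str$df$AS, str$df$BS, str$df$ABS),
    ss = c(str$ss$A, str$ss$B, str$ss$AB),
    ss_error = c(str$ss$AS, str$ss$BS, str$ss$ABS))
  ms <- out$ss / out$df_num
  mse <- out$ss_error / out$df_den
  out$f_value <- ifelse(mse > 0, ms / mse, ifelse(ms > 0, Inf, NaN))
  out$p_value <- ifelse(is.finite(out$f_value),
                        stats::pf(out$f_value, out$df_num, out$df_den,
                                  lower.tail = FALSE),
                        ifelse(is.infinite(out$f_value), 0, NA_real_))
  class(out) <- c("rm_anova", "data.frame")
  out
}

# Validate, average within cells, and return the balanced subject x A x B
# array of cell values.
check_long_table <- function(data, subject, a, b, value) {
  need <- c(subject, a, b, value)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  s <- factor(data[[subject]])
  fa <- factor(data[[a]])
  fb <- factor(data[[b]])
  v <- data[[value]]
  if (!is.numeric(v) || any(!is.finite(v)))
    stop("'", value, "' must be finite numeric", call. = FALSE)
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("both factors need at least 2 levels", call. = FALSE)
  if (nlevels(s) < 2)
    stop("at least 2 subjects required", call. = FALSE)
  cells <- tapply(v, list(s, fa, fb), mean)
  if (anyNA(cells))
    stop("unbalanced design: every subject x cell combination must be ",
         "present (no silent imputation)", call. = FALSE)
  cells  # array [subject, A, B]
}

# Sums of squares / dfs for all strata of the S x A x B within design,
# computed from cell and marginal means.
rm_anova_strata <- function(cells) {
  ns <- dim(cells)[1]; na <- dim(cells)[2]; nb <- dim(cells)[3]
  gm <- mean(cells)
  m_s <- apply(cells, 1, mean)
  m_a <- apply(cells, 2, mean)
  m_b <- apply(cells, 3, mean)
  m_sa <- apply(cells, c(1, 2), mean)
  m_sb <- apply(cells, c(1, 3), mean)
  m_ab <- apply(cells, c(2, 3), mean)
  ss <- list(
    S = na * nb * sum((m_s - gm)^2),
    A = ns * nb * sum((m_a - gm)^2),
    B = ns * na * sum((m_b - gm)^2))
  ss$AB <- ns * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + gm)^2)
  ss$AS <- nb * sum((m_sa - outer(m_s, rep(1, na)) -
                       outer(rep(1, ns), m_a) + gm)^2)
  ss$BS <- na * sum((m_sb - outer(m_s, rep(1, nb)) -
                       outer(rep(1, ns), m_b) + gm)^2)
  total <- sum((cells - gm)^2)
  ss$ABS <- total - ss$S - ss$A - ss$B - ss$AB - ss$AS - ss$BS
  ss$total <- total
  df <- list(S = ns - 1, A = na - 1, B = nb - 1,
             AB = (na - 1) * (nb - 1),
             AS = (na - 1) * (ns - 1), BS = (nb - 1) * (ns - 1),
             ABS = (na - 1) * (nb - 1) * (ns - 1))
  list(ss = ss, df = df)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-factor ANOVA: the effect is tested against the
#' factor-by-subject interaction stratum. Used standalone and by
#' \code{\link{simple_main_effects}}.
#'
#' @param data Long-format data frame.
#' @param subject,factor_col,value Column names.
#' @return One-row data frame with \code{df_num}, \code{df_den},
#'   \code{ss}, \code{ss_error}, \code{f_value}, \code{p_value}.
#' @export
one_way_rm_anova <- function(data, subject = "subject", factor_col = "A",
                             value = "value") {
  need <- c(subject, factor_col, value)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  s <- factor(data[[subject]])
  f <- factor(data[[factor_col]])
  v <- data[[value]]
  if (nlevels(f) < 2) stop("factor needs at least 2 levels", call. = FALSE)
  if (nlevels(s) < 2) stop("at least 2 subjects required", call. = FALSE)
  cells <- tapply(v, list(s, f), mean)
  if (anyNA(cells)) stop("unbalanced design", call. = FALSE)
  if (sum((cells - mean(cells))^2) == 0)
    stop("degenerate data: zero variance in this slice", call. = FALSE)
  ns <- nrow(cells); nf <- ncol(cells)
  gm <- mean(cells)
  m_s <- rowMeans(cells); m_f <- colMeans(cells)
  ss_f <- ns * sum((m_f - gm)^2)
  ss_err <- sum((cells - outer(m_s, rep(1, nf)) -
                   outer(rep(1, ns), m_f) + gm)^2)
  df1 <- nf - 1; df2 <- (nf - 1) * (ns - 1)
  msf <- ss_f / df1; mse <- ss_err / df2
  f_val <- if (mse > 0) msf / mse else if (msf > 0) Inf else NaN
  p <- if (is.finite(f_val)) stats::pf(f_val, df1, df2, lower.tail = FALSE)
  else if (is.infinite(f_val)) 0 else NA_real_
  data.frame(effect = factor_col, df_num = df1, df_den = df2,
             ss = ss_f, ss_error = ss_err, f_value = f_val, p_value = p)
}

#' Simple main effects in a two-way within-subject design
#'
#' Tests the effect of one factor separately at each level of the other,
#' as done after a significant interaction. Each slice is analysed as a
#' one-way within-subject ANOVA with its own (per-slice) error stratum.
#'
#' @param data Long-format data frame (as for
#'   \code{\link{two_way_rm_anova}}).
#' @param of_factor Column name of the factor whose effect is tested.
#' @param at_factor Column name of the factor defining the slices.
#' @param subject,value Column names.
#' @return Data frame, one row per level of \code{at_factor}, with an
#'   \code{at_level} column plus the one-way ANOVA columns.
#' @export
simple_main_effects <- function(data, of_factor, at_factor,
                                subject = "subject", value = "value") {
  lv <- levels(factor(data[[at_factor]]))
  rows <- lapply(lv, function(l) {
    slice <- data[data[[at_factor]] == l, , drop = FALSE]
    res <- one_way_rm_anova(slice, subject = subject,
                            factor_col = of_factor, value = value)
    cbind(at_level = l, res)
  })
  do.call(rbind, rows)
}

#' Detect the arousal crossover pattern in 2x2 cell means
#'
#' The model's qualitative signature: the unfamiliar condition elicits the
#' larger response when sounds are congruent (\code{B,X > A,X}) while the
#' familiar condition elicits the larger response when sounds are
#' incongruent (\code{A,Y > B,Y}).
#'
#' @param cell_means A 2x2 numeric matrix, rows named \code{A}/\code{B}
#'   (familiarity), columns \code{X}/\code{Y} (congruity); or a numeric
#'   vector with names \code{AX, AY, BX, BY}.
#' @return Logical scalar: \code{TRUE} iff both strict inequalities hold.
#'   Exact ties on either comparison give \code{FALSE} with attribute
#'   \code{tie = TRUE}.
#' @export
detect_crossover_pattern <- function(cell_means) {
  if (is.matrix(cell_means)) {
    stopifnot(all(dim(cell_means) == c(2, 2)),
              all(c("A", "B") %in% rownames(cell_means)),
              all(c("X", "Y") %in% colnames(cell_means)))
    ax <- cell_means["A", "X"]; ay <- cell_means["A", "Y"]
    bx <- cell_means["B", "X"]; by <- cell_means["B", "Y"]
  } else {
    stopifnot(all(c("AX", "AY", "BX", "BY") %in% names(cell_means)))
    ax <- cell_means[["AX"]]; ay <- cell_means[["AY"]]
    bx <- cell_means[["BX"]]; by <- cell_means[["BY"]]
  }
  if (any(!is.finite(c(ax, ay, bx, by))))
    stop("all four cell means must be finite", call. = FALSE)
  tie <- bx == ax || ay == by
  structure(bx > ax && ay > by, tie = tie)
}

#' Cell means of a per-subject measure table
#'
#' @param data Data frame with \code{familiarity}, \code{congruity} and a
#'   value column.
#' @param value Value column name.
#' @return 2x2 matrix of condition means (rows A/B, columns X/Y).
#' @export
condition_cell_means <- function(data, value = "amplitude_uv") {
  tapply(data[[value]], list(factor(data$familiarity, levels = c("A", "B")),
                             factor(data$congruity, levels = c("X", "Y"))),
         mean, na.rm = TRUE)
}

#' Analyze a simulated experiment
#'
#' Runs the confirmatory pipeline on a \code{\link{simulate_experiment}}
#' result: two-way within-subject ANOVA (familiarity x congruity) of the
#' P300 amplitudes and of the Likert ratings, simple main effects of
#' familiarity at each congruity level, and the crossover-pattern check
#' on both measures' cell means.
#'
#' @param sim An \code{experiment_sim} object.
#' @return List of class \code{experiment_analysis} with components
#'   \code{p300_anova}, \code{p300_simple_familiarity},
#'   \code{likert_anova}, \code{p300_cell_means},
#'   \code{likert_cell_means}, \code{p300_crossover},
#'   \code{likert_crossover}.
#' @export
analyze_experiment <- function(sim) {
  stopifnot(inherits(sim, "experiment_sim"))
  p300 <- sim$p300
  pd <- data.frame(subject = p300$subject, A = p300$familiarity,
                   B = p300$congruity, value = p300$amplitude_uv)
  rt <- sim$ratings
  ld <- data.frame(subject = rt$subject, A = rt$familiarity,
                   B = rt$congruity, value = as.numeric(rt$rating))
  res <- list(
    p300_anova = two_way_rm_anova(pd),
    p300_simple_familiarity = simple_main_effects(pd, "A", "B"),
    likert_anova = two_way_rm_anova(ld),
    p300_cell_means = condition_cell_means(p300, "amplitude_uv"),
    likert_cell_means = tapply(ld$value, list(ld$A, ld$B), mean))
  res$p300_crossover <- detect_crossover_pattern(res$p300_cell_means)
  res$likert_crossover <- detect_crossover_pattern(res$likert_cell_means)
  class(res) <- "experiment_analysis"
  res
}

#' @export
print.experiment_analysis <- function(x, ...) {
  cat("Two-way within-subject ANOVA, P300 amplitude:\n")
  print(format_anova(x$p300_anova))
  cat("\nSimple main effect of familiarity at each congruity level:\n")
  print(format_anova(x$p300_simple_familiarity))
  cat("\nTwo-way within-subject ANOVA, Likert surprise rating:\n")
  print(format_anova(x$likert_anova))
  cat(sprintf("\nCrossover pattern (BX>AX and AY>BY): P300 %s, Likert %s\n",
              x$p300_crossover, x$likert_crossover))
  invisible(x)
}

format_anova <- function(a) {
  d <- as.data.frame(a)
  d$f_value <- round(d$f_value, 3)
  d$p_value <- signif(d$p_value, 3)
  d$ss <- signif(d$ss, 4)
  d$ss_error <- signif(d$ss_error, 4)
  d
}

#' @export
print.rm_anova <- function(x, ...) {
  print(format_anova(x))
  invisible(x)
}
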