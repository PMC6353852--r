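test_that("two-way within-subject ANOVA matches stats::aov on random data", {
  set.seed(51)
  for (i in 1:5) {
    d <- expand.grid(subject = 1:8, A = c("a1", "a2", "a3"),
                     B = c("b1", "b2"), stringsAsFactors = FALSE)
    d$value <- rnorm(8)[d$subject] + rnorm(nrow(d))
    res <- two_way_rm_anova(d)
    ref <- oracle_aov_rm(d)
    expect_equal(res$f_value[res$effect == "A"], ref$A$f, tolerance = 1e-8)
    expect_equal(res$f_value[res$effect == "B"], ref$B$f, tolerance = 1e-8)
    expect_equal(res$f_value[res$effect == "A:B"], ref$AB$f, tolerance = 1e-8)
    expect_equal(res$p_value[res$effect == "A:B"], ref$AB$p, tolerance = 1e-8)
  }
})

test_that("sums of squares partition the total and match brute force", {
  set.seed(52)
  d <- expand.grid(subject = 1:6, A = c("a1", "a2", "a3"),
                   B = c("b1", "b2", "b3", "b4"), stringsAsFactors = FALSE)
  # two trials per cell: exercises the within-cell averaging path
  d <- rbind(d, d)
  d$value <- rnorm(nrow(d), sd = 2)
  cells <- noveltyGain:::check_long_table(d, "subject", "A", "B", "value")
  str <- noveltyGain:::rm_anova_strata(cells)
  ref <- oracle_ss_brute(cells)
  for (nm in c("S", "A", "B", "AB", "AS", "BS", "ABS", "total"))
    expect_equal(str$ss[[nm]], ref[[nm]], tolerance = 1e-8)
  parts <- with(str$ss, S + A + B + AB + AS + BS + ABS)
  expect_equal(parts, str$ss$total, tolerance = 1e-8)
})

test_that("pure interaction with zero noise: infinite interaction F, null mains", {
  d <- expand.grid(subject = 1:4, A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  sgn <- ifelse(d$A == "a1", 1, -1) * ifelse(d$B == "b1", 1, -1)
  d$value <- sgn  # +1 on the diagonal cells, -1 off it
  res <- two_way_rm_anova(d)
  expect_equal(res$f_value[res$effect == "A:B"], Inf)
  expect_equal(res$p_value[res$effect == "A:B"], 0)
  expect_equal(res$ss[res$effect == "A"], 0)
  expect_equal(res$ss[res$effect == "B"], 0)
})

test_that("unbalanced or malformed designs are rejected", {
  d <- expand.grid(subject = 1:4, A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  expect_error(two_way_rm_anova(d[-1, ]), "unbalanced")
  expect_error(two_way_rm_anova(d[, -4]), "missing columns")
  d1 <- d[d$subject == 1, ]
  expect_error(two_way_rm_anova(d1), "2 subjects")
})

test_that("simple main effects localize a one-sided effect and match slicing", {
  set.seed(53)
  d <- expand.grid(subject = 1:10, A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(10)[d$subject] + rnorm(nrow(d), sd = 0.3) +
    ifelse(d$B == "b2" & d$A == "a2", 3, 0)  # A effect only at b2
  sme <- simple_main_effects(d, "A", "B")
  expect_equal(sme$at_level, c("b1", "b2"))
  expect_gt(sme$p_value[1], 0.05)
  expect_lt(sme$p_value[2], 0.001)

  # equality with a one-way ANOVA run on the slice by hand
  slice <- d[d$B == "b2", ]
  ref <- one_way_rm_anova(slice, factor_col = "A")
  expect_equal(sme$f_value[2], ref$f_value, tolerance = 1e-12)

  # zero-variance slice is an explicit degenerate-data error
  dz <- d; dz$value[dz$B == "b1"] <- 1
  expect_error(simple_main_effects(dz, "A", "B"), "degenerate")
})

test_that("relabelling factor levels permutes results consistently", {
  set.seed(54)
  d <- expand.grid(subject = 1:6, A = c("a1", "a2"), B = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d))
  res <- two_way_rm_anova(d)
  swapped <- d
  swapped$A <- d$B; swapped$B <- d$A
  res2 <- two_way_rm_anova(swapped)
  expect_equal(res2$f_value[res2$effect == "A"],
               res$f_value[res$effect == "B"])
  expect_equal(res2$f_value[res2$effect == "A:B"],
               res$f_value[res$effect == "A:B"])
})

test_that("crossover pattern detector handles patterns, ties and bad input", {
  m <- matrix(c(1, 2, 4, 3), 2, 2, dimnames = list(c("A", "B"), c("X", "Y")))
  expect_true(detect_crossover_pattern(m))
  expect_false(attr(detect_crossover_pattern(m), "tie"))
  meq <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("X", "Y")))
  expect_false(detect_crossover_pattern(meq))
  expect_true(attr(detect_crossover_pattern(meq), "tie"))
  # reversed pattern
  mr <- matrix(c(2, 1, 3, 4), 2, 2, dimnames = list(c("A", "B"), c("X", "Y")))
  expect_false(detect_crossover_pattern(mr))
  expect_error(detect_crossover_pattern(
    c(AX = 1, AY = NA, BX = 2, BY = 0)), "finite")
})
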