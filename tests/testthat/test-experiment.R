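test_that("schedules reproduce the session trial counts and ISI contract", {
  # main session: 8 videos x 20 sets = 160 trials per subject
  main <- build_schedule(n_sets = 20, n_subjects = 3, seed = 1)
  expect_equal(nrow(main), 3 * 160)
  expect_equal(max(main$trial), 160)
  # sound-only session: 8 sounds x 5 sets = 40 trials
  sound <- build_schedule(n_sets = 5, n_subjects = 1, seed = 2)
  expect_equal(nrow(sound), 40)
  # ISIs inside [1000, 2000] ms, mean near 1500 for large n
  big <- build_schedule(n_sets = 20, n_subjects = 30, seed = 3)
  expect_true(all(big$isi_ms >= 1000 & big$isi_ms <= 2000))
  expect_equal(mean(big$isi_ms), 1500, tolerance = 0.01)
})

test_that("every presentation set is a permutation of the stimulus list", {
  sched <- build_schedule(n_sets = 20, n_subjects = 2, seed = 4)
  counts <- table(sched$subject, sched$presentation_set, sched$stimulus)
  expect_true(all(counts == 1))
  # randomized order: sets are not all in canonical order
  first_per_set <- tapply(sched$stimulus,
                          list(sched$subject, sched$presentation_set),
                          function(x) x[1])
  expect_gt(length(unique(as.vector(first_per_set))), 1)
  # reproducible per seed
  expect_identical(sched, build_schedule(n_sets = 20, n_subjects = 2, seed = 4))
  expect_error(build_schedule(stimuli = data.frame()), "non-empty")
})

test_that("condition mapping: lookup, validation, crossover-consistent gains", {
  cp <- condition_params("A", "X")
  expect_equal(cp$s_p, 0.2)
  expect_equal(cp$delta, 0)
  expect_equal(cp$s_l, 0.1)
  bad <- default_condition_mapping(); bad$s_p <- c(A = 1.0, B = 0.2)
  expect_error(condition_params("A", "X", bad), "s_p\\(B\\) > s_p\\(A\\)")
  bad2 <- default_condition_mapping(); bad2$delta <- c(X = 2, Y = 1)
  expect_error(condition_params("A", "X", bad2), "delta\\(Y\\) > delta\\(X\\)")

  # the default incongruent prediction error lies beyond the crossover
  m <- default_condition_mapping()
  dstar <- crossover_point(m$s_p[["A"]], m$s_p[["B"]], m$s_l)$delta_star
  expect_gt(m$delta[["Y"]], dstar)

  # hence the model's gains show the crossover pattern
  G <- condition_gain(c("A", "B", "A", "B"), c("X", "X", "Y", "Y"))
  names(G) <- c("AX", "BX", "AY", "BY")
  expect_gt(G[["BX"]], G[["AX"]])
  expect_gt(G[["AY"]], G[["BY"]])
  expect_true(detect_crossover_pattern(G[c("AX", "AY", "BX", "BY")]))
})

test_that("Likert generator: range, noise-free ordering, seed determinism", {
  sched <- build_schedule(n_sets = 5, n_subjects = 4, seed = 5)
  cfg0 <- default_likert_config()
  cfg0$noise_sd <- 0; cfg0$subject_sd <- 0
  r0 <- simulate_likert(sched, config = cfg0, seed = 6)
  # constant within condition, nondecreasing in G
  byc <- tapply(r0$rating, interaction(r0$familiarity, r0$congruity), unique)
  expect_true(all(lengths(byc) == 1))
  ord <- order(tapply(r0$gain, interaction(r0$familiarity, r0$congruity), unique))
  expect_true(all(diff(unlist(byc)[ord]) >= 0))

  r <- simulate_likert(sched, seed = 7)
  expect_true(all(r$rating %in% 1:4))
  expect_identical(r, simulate_likert(sched, seed = 7))
})

test_that("Likert condition means reproduce the crossover sign pattern across replicates", {
  hits <- 0L
  for (rep in 1:200) {
    sched <- build_schedule(n_sets = 20, n_subjects = 9, seed = 5000 + rep)
    r <- simulate_likert(sched, seed = 6000 + rep)
    cm <- tapply(r$rating, list(r$familiarity, r$congruity), mean)
    hits <- hits + isTRUE(detect_crossover_pattern(cm))
  }
  expect_gte(hits, 0.95 * 200)
})

test_that("epoch timebase follows the 500 Hz, -200..+1500 ms convention", {
  t <- epoch_times()
  expect_length(t, 850)
  expect_equal(t[1], -200)
  expect_equal(diff(t)[1], 2)
  expect_equal(t[850], 1498)  # +1500 ms endpoint excluded
  expect_equal(t[526], 850)   # 350 ms after the +500 ms sound onset
})

test_that("noise-free synthesize -> extract round trip is exact", {
  cfg <- erp_config_noise_free(amp = 10, latency = 350)
  ep <- synthesize_epoch(1, cfg, seed = 1)
  m <- extract_p300(ep, cfg)
  expect_false(m$rejected)
  expect_equal(m$amplitude_uv, 10)
  expect_equal(m$latency_ms, 350)
  # adding a constant offset changes nothing after baseline correction
  m2 <- extract_p300(as.numeric(ep) + 5, cfg)
  expect_equal(m2$amplitude_uv, 10)
  expect_equal(m2$latency_ms, 350)
})

test_that("P300 extraction: artifacts, degenerate input, tie-break", {
  cfg <- default_erp_config()
  flat <- rep(0, 850)
  m <- extract_p300(flat, cfg)
  expect_equal(m$amplitude_uv, 0)
  expect_equal(m$latency_ms, 250)  # first grid point of the search window

  spike <- flat; spike[400] <- 120
  expect_true(extract_p300(spike, cfg)$rejected)

  # two equal maxima: earliest latency wins
  tie <- flat
  tie[c(501, 601)] <- 7  # 800 ms and 1000 ms, both in the window
  mt <- extract_p300(tie, cfg)
  expect_equal(mt$amplitude_uv, 7)
  expect_equal(mt$latency_ms, (-200 + 2 * 500) - 500)
  expect_error(extract_p300(rep(0, 10), cfg), "timebase")
})

test_that("epoch averaging: idempotence, cancellation, rejection, empty groups", {
  cfg <- default_erp_config()
  e <- synthesize_epoch(2, erp_config_noise_free(), seed = 1)
  stackd <- rbind(as.numeric(e), as.numeric(e), as.numeric(e))
  avg <- average_erp(stackd, rep("g", 3), cfg)
  base <- as.numeric(e) - mean(as.numeric(e)[1:100])
  expect_equal(as.numeric(avg$waveforms[1, ]), base)
  expect_equal(avg$n, 3L)

  # +1 and -1 constants cancel to zero
  two <- rbind(rep(1, 850), rep(-1, 850))
  avg2 <- average_erp(two, c("g", "g"), cfg)
  expect_equal(as.numeric(avg2$waveforms[1, ]), rep(0, 850))

  # artifact epochs are excluded; a fully rejected group is flagged empty
  spike <- rep(0, 850); spike[300] <- 150
  avg3 <- average_erp(rbind(spike, rep(1, 850)), c("bad", "good"), cfg)
  expect_equal(avg3$n, c(0L, 1L))
  expect_true(all(is.na(avg3$waveforms["bad", ])))
  expect_equal(avg3$n_rejected, 1L)
})

test_that("amplitude grows with information gain in the synthetic ERPs", {
  cfg <- default_erp_config()
  G <- condition_gain(c("A", "B", "A", "B"), c("X", "X", "Y", "Y"))
  set.seed(77)
  amps <- vapply(G, function(g) {
    eps <- noveltyGain:::synthesize_epoch_matrix(rep(g, 60), cfg)
    avg <- average_erp(eps, rep("g", 60), cfg)
    extract_p300(avg$waveforms[1, ], cfg)$amplitude_uv
  }, 0)
  expect_true(all(diff(amps[order(G)]) > 0))
})

test_that("simulated experiment is reproducible and crossover-patterned", {
  sim <- simulate_experiment(n_subjects = 9, seed = 99, keep_epochs = FALSE)
  expect_equal(nrow(sim$p300), 9 * 4)
  expect_true(all(sim$p300$n_epochs > 0))
  sim2 <- simulate_experiment(n_subjects = 9, seed = 99, keep_epochs = FALSE)
  expect_identical(sim$p300, sim2$p300)
  expect_identical(sim$ratings$rating, sim2$ratings$rating)

  cm <- condition_cell_means(sim$p300)
  expect_true(detect_crossover_pattern(cm))
  lm_ <- tapply(sim$ratings$rating, list(sim$ratings$familiarity,
                                         sim$ratings$congruity), mean)
  expect_true(detect_crossover_pattern(lm_))
  expect_error(simulate_experiment(n_subjects = 2), "seed")
})
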