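test_that("configuration invariants are enforced", {
  expect_error(simulation_config(epoch_duration_s = 0), "positive sample count")
  expect_error(simulation_config(baseline_coupling = c("precuneus_L|precuneus_R.alpha" = 1.2)),
               "\\[0, 1\\)")
  expect_error(simulation_config(band_effects = c("nowhere.alpha" = 0.1)), "unknown")
  expect_error(simulation_config(coupling_effects = c("precuneus_L|mars.alpha" = 0.1)),
               "unknown")
  # over-constrained correlation structure: rho(A,B)=rho(B,C)=0.9, rho(A,C)=0
  expect_error(simulation_config(baseline_coupling = c(
    "precuneus_L|precuneus_R.alpha" = 0.9,
    "PCC_L|precuneus_R.alpha" = 0.9)), "positive semi-definite")
  bad_mix <- default_mixing_matrix()
  bad_mix[, 2] <- bad_mix[, 1]
  expect_error(simulation_config(mixing_matrix = bad_mix), "rank")
  expect_error(simulation_config(event_spacing_s = 5), "12 mean IBIs")
})

test_that("generation is bit-identical per seed and per-participant substream", {
  cfg <- tiny_config(seed = 3)
  a <- generate_epochs(cfg, keep_roi = TRUE)
  b <- generate_epochs(cfg, keep_roi = TRUE)
  expect_identical(a$sets[["P002.negative"]]$data, b$sets[["P002.negative"]]$data)
  expect_identical(a$power_truth, b$power_truth)
  # subsetting reproduces the same participant exactly
  only2 <- generate_epochs(cfg, participants = 2, keep_roi = TRUE)
  expect_identical(only2$sets[["P002.control"]]$data, a$sets[["P002.control"]]$data)
  # a different seed changes the data
  c_ <- generate_epochs(tiny_config(seed = 4), participants = 1)
  expect_false(identical(c_$sets[["P001.control"]]$data, a$sets[["P001.control"]]$data))
})

test_that("identity mixing without noise makes channel data equal region data", {
  regions <- names(roi_catalog())
  M <- diag(10)
  dimnames(M) <- list(paste0("ch_", regions), regions)
  cfg <- tiny_config(seed = 5, mixing_matrix = M, sensor_noise_sd = 0)
  sim <- generate_epochs(cfg, participants = 1, keep_roi = TRUE)
  expect_equal(sim$sets[["P001.control"]]$data, sim$roi_sets[["P001.control"]]$data,
               tolerance = 1e-12)
  # and unmixing inverts the default (non-square) mixing up to sensor noise
  cfg2 <- tiny_config(seed = 5, sensor_noise_sd = 0)
  sim2 <- generate_epochs(cfg2, participants = 1, keep_roi = TRUE)
  rec <- unmix_epochs(sim2$sets[["P001.control"]], cfg2$mixing_matrix)
  expect_equal(rec$data, sim2$roi_sets[["P001.control"]]$data, tolerance = 1e-8)
})

test_that("requested envelope coupling is realized on the envelope scale", {
  # 0.05 is tighter than the Monte-Carlo noise of one 60-epoch series of
  # <= 1 Hz envelopes (sd ~0.03), so the pooled correlation is averaged over
  # 2 participants x 2 conditions (4 independent 60-epoch series)
  cfg <- coupled_config(rho = 0.5, seed = 17, n_epochs = 60)
  cfg$n_participants <- 2
  i <- match(c("precuneus_L", "precuneus_R"), names(roi_catalog()))
  sim <- generate_epochs(cfg, keep_envelopes = TRUE)
  rs <- vapply(sim$envelopes, function(bands_) {
    env <- bands_[["alpha"]]
    cor(env[, i[1]], env[, i[2]])
  }, numeric(1))
  expect_length(rs, 4)
  expect_lt(abs(mean(rs) - 0.5), 0.05)
  expect_true(all(abs(sim$coupling_truth$env_corr_truth) <= 1))
})

test_that("zero-effect worlds are exchangeable between conditions", {
  cfg <- simulation_config(n_participants = 6, n_epochs_per_condition = 8,
                           random_seed = 19,
                           band_effects = c("precuneus_R.alpha" = 0),
                           coupling_effects = c("precuneus_L|precuneus_R.alpha" = 0),
                           ibi_effect_ms = 0)
  sim <- generate_epochs(cfg)
  pt <- sim$power_truth
  alpha <- pt[pt$band == "alpha" & pt$region == "precuneus_R", ]
  d <- data.frame(participant = alpha$participant, condition = alpha$condition,
                  value = alpha$rel_power_truth)
  fit <- fit_condition_model(d, allow_gamma = FALSE)
  expect_gt(fit$p_raw, 0.01)
})

test_that("too few epochs fail the inclusion rule for every participant", {
  cfg <- simulation_config(n_participants = 2, n_epochs_per_condition = 14,
                           random_seed = 23)
  sim <- generate_epochs(cfg)
  kept <- inclusion_filter(epoch_counts(sim$sets), min_epochs = 15)
  expect_length(kept, 0)
  expect_length(attr(kept, "excluded"), 2)
})

test_that("questionnaire scores honour the Likert bounds and the gamma support", {
  cfg <- simulation_config(n_participants = 10, random_seed = 25)
  sc <- generate_scores(cfg, "valence")
  expect_true(all(sc$value >= 1 & sc$value <= 9))
  expect_true(all(sc$value == round(sc$value)))
  expect_setequal(unique(sc$condition), c("control", "negative"))
  expect_true(all(participant_info(cfg)$sex %in% c("F", "M")))
  raw <- generate_scores(cfg, "valence", likert = FALSE)
  expect_false(all(raw$value == round(raw$value)))
  expect_error(generate_scores(cfg, "dominance"), "unknown scale")
  cfg_bad <- simulation_config(n_participants = 3, random_seed = 25,
                               score_mean = 0.5,
                               score_shifts = c(valence = -1, arousal = 0),
                               score_participant_sd = 0.01)
  expect_error(generate_scores(cfg_bad, "valence"), "non-positive")
})

test_that("a configured score shift is recovered within its confidence interval", {
  covered <- 0L
  n_rep <- 8
  for (r in seq_len(n_rep)) {
    cfg <- simulation_config(n_participants = 73, random_seed = 400 + r,
                             score_shifts = c(valence = -1, arousal = 0))
    sc <- generate_scores(cfg, "valence", likert = FALSE)
    d <- aggregate(value ~ participant + condition, sc, mean)
    fit <- fit_condition_model(d, allow_gamma = FALSE)
    lo <- fit$beta - qnorm(0.975) * fit$se
    hi <- fit$beta + qnorm(0.975) * fit$se
    covered <- covered + (lo <= -1 && -1 <= hi)
  }
  expect_gte(covered, ceiling(0.9 * n_rep) - 1) # >= 90% coverage, 1 miss allowed
})

test_that("rpeak trains warn when events sit too close to the series edge", {
  cfg <- simulation_config(n_participants = 1, random_seed = 27)
  expect_warning(generate_rpeaks(cfg, event_times = c(1, 30), condition = "negative"),
                 "edge")
  expect_error(generate_rpeaks(cfg, event_times = c(20, 22)), "12 mean IBIs")
})
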