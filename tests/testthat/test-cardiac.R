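test_that("a constant train yields constant IBIs and zero difference scores", {
  peaks <- seq(0, 60, by = 1) # 1000 ms train
  al <- align_ibis(peaks, event_time = 30)
  expect_equal(al$index, -3:8)
  expect_equal(al$ibi, rep(1000, 12))
  expect_equal(al$ibi_diff, rep(0, 12))
})

test_that("post-event shortening appears at exactly the constructed indices", {
  ibis <- rep(0.8, 40)
  anchor <- 20L
  ibis[(anchor + 2):(anchor + 7)] <- 0.8 - 0.03
  peaks <- cumsum(ibis)
  al <- align_ibis(peaks, event_time = peaks[anchor])
  expect_equal(al$ibi_diff[al$index %in% 2:7], rep(-30, 6))
  expect_equal(al$ibi_diff[!al$index %in% 2:7], rep(0, 6))
  expect_equal(al$ibi_diff[al$index == -2], 0)
})

test_that("events tie-break toward the earlier peak and edge events drop", {
  peaks <- seq(0.5, 30, by = 0.8)
  mid <- (peaks[15] + peaks[16]) / 2 # equidistant between two peaks
  al <- align_ibis(peaks, mid)
  al_earlier <- align_ibis(peaks, peaks[15])
  expect_equal(al$ibi, al_earlier$ibi)
  expect_warning(expect_null(align_ibis(peaks, peaks[2])), "dropped")
  expect_warning(expect_null(align_ibis(peaks, peaks[length(peaks) - 3])), "dropped")
  expect_error(align_ibis(c(1, 1, 2), 1), "increasing")
})

test_that("difference scores are invariant to a constant IBI offset", {
  set.seed(11)
  for (k in 1:5) {
    ibis <- runif(30, 0.7, 1.0)
    al1 <- align_ibis(cumsum(ibis), event_time = cumsum(ibis)[15])
    al2 <- align_ibis(cumsum(ibis + 0.2), event_time = cumsum(ibis + 0.2)[15])
    expect_equal(al1$ibi_diff, al2$ibi_diff, tolerance = 1e-9)
    expect_equal(al1$ibi_diff[al1$index == -2], 0)
  }
})

test_that("generated trains recover the configured cardiac effect", {
  cfg <- simulation_config(n_participants = 2, random_seed = 31, n_events = 40,
                           ibi_effect_ms = 30, ibi_sd_ms = 40)
  events <- 20 + (0:39) * 15
  rp <- generate_rpeaks(cfg, events, "negative", 1)
  rc <- generate_rpeaks(cfg, events, "control", 1)
  expect_true(all(diff(rp) > 0))
  al <- do.call(rbind, lapply(events, function(ev) align_ibis(rp, ev)))
  alc <- do.call(rbind, lapply(events, function(ev) align_ibis(rc, ev)))
  mdiff <- tapply(al$ibi_diff, al$index, mean)
  mdiff_c <- tapply(alc$ibi_diff, alc$index, mean)
  # Monte-Carlo tolerance: sd of a mean difference of two N(., 40ms) IBIs
  # over 40 events is sqrt(2) * 40 / sqrt(40) ~= 8.9 ms; use 3 sigma
  tol <- 3 * sqrt(2) * 40 / sqrt(40)
  for (k in 2:7) expect_lt(abs(mdiff[as.character(k)] + 30), tol)
  for (k in c(-3, -1, 0, 1, 8)) {
    expect_lt(abs(mdiff[as.character(k)]), tol)
    expect_lt(abs(mdiff_c[as.character(k)]), tol)
  }
  # zero-effect generator: all mean differences near zero
  cfg0 <- simulation_config(n_participants = 1, random_seed = 32, n_events = 40,
                            ibi_effect_ms = 0)
  rp0 <- generate_rpeaks(cfg0, events, "negative", 1)
  al0 <- do.call(rbind, lapply(events, function(ev) align_ibis(rp0, ev)))
  expect_lt(max(abs(tapply(al0$ibi_diff, al0$index, mean))), tol)
})

test_that("the IBI condition contrast is negative exactly at the injected indices", {
  cfg <- simulation_config(n_participants = 6, random_seed = 33, n_events = 30,
                           ibi_effect_ms = 30, ibi_sd_ms = 20)
  cd <- generate_cardiac(cfg, participants = 1:6)
  tbl <- ibi_table(cd$rpeaks, cd$events)
  expect_named(tbl, c("participant", "condition", "event", "index", "ibi", "ibi_diff"))
  ic <- condition_contrast_ibi(tbl)
  expect_true(all(ic$estimate[ic$index %in% 2:7] < -15))
  expect_true(all(ic$p[ic$index %in% 2:7] < 0.01))
  off <- ic$index %in% c(-3, -1, 0, 1, 8)
  expect_true(all(abs(ic$estimate[off]) < 15))
  # single participant: the random-intercept model is declared degenerate
  one <- tbl[tbl$participant == "P001", ]
  expect_error(condition_contrast_ibi(one), "fixed-effects")
})
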