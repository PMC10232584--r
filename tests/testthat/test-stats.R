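test_that("the inclusion rule is boundary-inclusive and needs both conditions", {
  counts <- data.frame(
    participant = rep(c("a", "b", "c"), each = 2),
    condition = rep(c("control", "negative"), 3),
    n_epochs = c(15, 15, 14, 40, 30, 30))
  kept <- inclusion_filter(counts)
  expect_setequal(kept, c("a", "c"))
  expect_identical(attr(kept, "excluded"), "b")
  empty <- inclusion_filter(counts[0, ])
  expect_length(empty, 0)
  only_one_cond <- data.frame(participant = "d", condition = "control", n_epochs = 40)
  expect_length(inclusion_filter(only_one_cond), 0)
})

test_that("identical values in both conditions give a zero contrast", {
  d <- data.frame(participant = rep(c("a", "b"), each = 2),
                  condition = rep(c("control", "negative"), 2),
                  value = c(5, 5, 7, 7))
  fit <- fit_condition_model(d)
  expect_lt(abs(fit$beta), 1e-6)
  expect_error(fit_condition_model(d[d$participant == "a", ]), "2 participants")
})

test_that("family selection picks gamma for skewed data and respects positivity", {
  set.seed(12)
  n <- 40
  d <- data.frame(participant = rep(sprintf("p%02d", 1:n), each = 2),
                  condition = rep(c("control", "negative"), n),
                  value = rgamma(2 * n, shape = 2, rate = 0.5))
  fit <- fit_condition_model(d)
  expect_true(fit$family %in% c("linear", "gamma"))
  expect_true(is.finite(fit$aic_linear) && is.finite(fit$aic_gamma))
  expect_true(fit$p_raw >= 0 && fit$p_raw <= 1)
  expect_true(fit$ses_ci[1] <= fit$ses && fit$ses <= fit$ses_ci[2])
  # negative values force the linear family
  d$value[1] <- -1
  fit2 <- fit_condition_model(d)
  expect_identical(fit2$family, "linear")
  expect_true(is.na(fit2$aic_gamma))
  expect_match(paste(fit2$notes, collapse = " "), "linear")
})

test_that("a known contrast is recovered by the selected family", {
  set.seed(13)
  n <- 60
  b <- rnorm(n, sd = 0.5)
  d <- do.call(rbind, lapply(1:n, function(i) {
    mu <- c(5 + b[i], 5 + b[i] - 1)
    data.frame(participant = sprintf("p%02d", i),
               condition = c("control", "negative"),
               value = rgamma(2, shape = (mu / 0.8)^2, rate = mu / 0.8^2))
  }))
  fit <- fit_condition_model(d)
  expect_lt(abs(fit$beta - (-1)), 3 * fit$se)
  expect_lt(fit$p_raw, 0.001)
})

test_that("the sex covariate check retains sex only when it matters", {
  set.seed(14)
  n <- 40
  sex <- rep(c("F", "M"), length.out = n)
  base <- rnorm(n, 5, 0.3)
  mk <- function(sex_effect, b = base) {
    do.call(rbind, lapply(1:n, function(i) {
      data.frame(participant = sprintf("p%02d", i), sex = sex[i],
                 condition = c("control", "negative"),
                 value = b[i] + sex_effect * (sex[i] == "M") + rnorm(2, sd = 0.2))
    }))
  }
  strong <- sex_covariate_check(mk(3), allow_gamma = FALSE)
  expect_true(strong$retain)
  expect_lt(strong$p, 0.001)
  # single-sex sample: skipped with a warning
  d1 <- mk(0)
  d1$sex <- "F"
  expect_warning(res <- sex_covariate_check(d1), "one sex")
  expect_false(res$retain)
  # null retention rate stays near the nominal level
  hits <- 0L
  for (r in 1:40) {
    set.seed(100 + r)
    hits <- hits + sex_covariate_check(mk(0, rnorm(n, 5, 0.3)),
                                       allow_gamma = FALSE)$retain
  }
  expect_lte(hits, 6) # Binomial(40, 0.05): P(X > 6) < 0.4%
})

test_that("BF01 follows the BIC closed form and tracks injected effects", {
  expect_equal(bf01_from_bic(10, 10), 1)
  expect_equal(bf01_from_bic(12, 10), exp(1))
  expect_equal(bf01_from_bic(8, 10), exp(-1))
  expect_match(jeffreys_label(8.79), "moderate evidence for H0")
  expect_match(jeffreys_label(1.24), "anecdotal evidence for H0")
  expect_match(jeffreys_label(0.05), "strong evidence for H1")
  set.seed(15)
  n <- 50
  b <- rnorm(n, sd = 0.3)
  d <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(participant = sprintf("p%02d", i),
               condition = c("control", "negative"),
               value = 5 + b[i] + c(0, -1.5) + rnorm(2, sd = 0.4))
  }))
  bf <- bayes_factor_bic(d, family = "linear")
  expect_lt(bf$bf01, 1 / 10) # strong evidence against the null
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(0.037), 0.037)
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  # property: matches the classical step-up rejection set for random inputs
  set.seed(16)
  for (rep_ in 1:20) {
    p <- runif(sample(3:67, 1))^sample(1:3, 1)
    q <- 0.05
    adj <- fdr_correct(p)
    o <- order(p)
    k <- which(p[o] <= q * seq_along(p) / length(p))
    classical <- logical(length(p))
    if (length(k)) classical[o[seq_len(max(k))]] <- TRUE
    expect_identical(adj <= q, classical)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    expect_false(is.unsorted(adj[o]))
  }
})

test_that("the test family enumerates to 67 with stable identifiers", {
  fam <- enumerate_tests()
  expect_equal(nrow(fam), 67)
  expect_equal(sum(fam$layer == "sensor_power"), 3)
  expect_equal(sum(fam$layer == "source_power"), 30)
  expect_equal(sum(fam$layer == "fc"), 34)
  expect_false(any(duplicated(fam$measure_id)))
  expect_equal(nrow(enumerate_tests(source = FALSE, fc = FALSE)), 3)
  expect_equal(nrow(enumerate_tests(sensor = FALSE, source = FALSE, fc = FALSE)), 0)
})
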