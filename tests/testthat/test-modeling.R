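test_that("cyclic spline design is periodic and a partition of unity", {
  b0 <- nightshift:::cyclic_basis(0, knots = 10)
  b24 <- nightshift:::cyclic_basis(24, knots = 10)
  expect_equal(b0, b24)
  set.seed(61)
  h <- runif(200, 0, 24)
  B <- nightshift:::cyclic_basis(h, knots = 10)
  expect_true(all(abs(rowSums(B) - 1) < 1e-10))
  # no fixed terms: design is intercept + spline columns only
  d <- data.frame(hour = h)
  des <- build_design(d, model_spec("log2_odba", character(), knots = 10))
  expect_true(all(des$columns %in% c("(Intercept)", "circadian")))
  # unstandardized covariate is rejected
  d$temp <- rnorm(200, 5, 3)
  expect_error(
    build_design(d, model_spec("log2_odba", "temp")), "standardized")
  # marginality enforced at spec construction
  expect_error(model_spec("log2_odba", "temp_sq"), "requires")
  expect_error(model_spec("log2_odba", c("bci_temp", "bci")), "requires")
})

test_that("ICC and MCC follow their closed forms", {
  expect_equal(compute_icc(0, 3), 0)
  expect_equal(compute_icc(2, 2), 0.5)
  expect_equal(compute_icc(2, 6), 0.25)
  expect_equal(compute_icc(3, 1), 0.75)
  expect_error(compute_icc(0, 0), "both be zero")
  expect_error(compute_icc(-1, 2), "non-negative")

  expect_equal(as.numeric(compute_mcc(40, 60, 0, 0)), 1)
  expect_equal(as.numeric(compute_mcc(0, 0, 55, 45)), -1)
  expect_equal(as.numeric(compute_mcc(25, 25, 25, 25)), 0)
  expect_error(compute_mcc(-1, 0, 0, 1), "non-negative")
  und <- compute_mcc(0, 10, 0, 0) # no predicted or true positives
  expect_equal(as.numeric(und), 0)
  expect_true(attr(und, "undefined"))
})

test_that("the hourly LMM recovers generative parameters on one cohort", {
  sim <- sim_cohort_hours(n_ind = 15, n_days = 7, seed = 71)
  spec <- model_spec("log2_odba", c("temp", "temp_sq", "bci", "bci_temp"),
                     knots = 8)
  fit <- fit_lmm_ar1(sim, spec)
  expect_true(fit$converged)
  expect_lt(abs(fit$rho - 0.4), 0.12)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_lt(abs(est[["temp"]] - 0.3), 0.15)
  expect_lt(abs(est[["temp_sq"]] - (-0.2)), 0.1)
  # AIC identity
  expect_equal(fit$aic, -2 * fit$logLik + 2 * fit$n_params)
  expect_true(fit$icc >= 0 && fit$icc <= 1)
})

test_that("shifting the response by one log2 unit moves only the intercept", {
  sim <- sim_cohort_hours(n_ind = 6, n_days = 4, seed = 72)
  spec <- model_spec("log2_odba", "temp", knots = 6)
  f1 <- fit_lmm_ar1(sim, spec)
  sim2 <- sim
  sim2$log2_odba <- sim$log2_odba + 1
  sim2$hourly_odba <- 2^sim2$log2_odba
  f2 <- fit_lmm_ar1(sim2, spec)
  e1 <- setNames(f1$coefficients$estimate, f1$coefficients$term)
  e2 <- setNames(f2$coefficients$estimate, f2$coefficients$term)
  expect_equal(e2[["(Intercept)"]] - e1[["(Intercept)"]], 1,
               tolerance = 1e-4)
  others <- setdiff(names(e1), "(Intercept)")
  expect_equal(e2[others], e1[others], tolerance = 1e-4)
})

test_that("binomial activity model hits its analytic endpoints", {
  # near-deterministic generator: classification approaches perfection
  sim <- sim_cohort_hours(
    n_ind = 8, n_days = 6, seed = 73,
    activity_logit_params = list(intercept = 0, beta = c(temp = 20)))
  spec <- model_spec("active", "temp", knots = 6, ar1 = FALSE)
  fit <- fit_glmm_binomial(sim, spec, nAGQ = 0)
  expect_gt(fit$accuracy, 0.97)
  expect_gt(fit$mcc, 0.9)
  # null generator with balanced classes: accuracy ~ 0.5, MCC ~ 0
  sim0 <- sim_cohort_hours(
    n_ind = 20, n_days = 9, seed = 74,
    activity_logit_params = list(intercept = 0, beta = c()))
  fit0 <- fit_glmm_binomial(sim0, spec, nAGQ = 0)
  expect_lt(abs(fit0$accuracy - 0.5), 0.05)
  expect_lt(abs(fit0$mcc), 0.05)
  # sign of a real temperature effect is recovered
  simt <- sim_cohort_hours(
    n_ind = 12, n_days = 7, seed = 75,
    activity_logit_params = list(intercept = -0.5, beta = c(temp = 1)))
  fitt <- fit_glmm_binomial(simt, spec, nAGQ = 1)
  est <- setNames(fitt$coefficients$estimate, fitt$coefficients$term)
  expect_gt(est[["temp"]], 0)
})

test_that("subset enumeration respects marginality and forbidden pairs", {
  terms <- c("temp", "temp_sq", "rain", "bci", "bci_temp", "soilt10")
  forb <- tibble::tibble(var1 = "soilt10", var2 = "temp")
  subsets <- nightshift:::enumerate_subsets(terms, forb)
  for (s in subsets) {
    if ("temp_sq" %in% s) expect_true("temp" %in% s)
    if ("bci_temp" %in% s) expect_true(all(c("bci", "temp") %in% s))
    expect_false(all(c("temp", "soilt10") %in% s))
  }
  # every marginality-valid, pair-free subset is present exactly once
  expect_equal(anyDuplicated(vapply(subsets, paste, "", collapse = "+")), 0L)
})

test_that("single-term selection orders candidates like direct fits", {
  sim <- sim_cohort_hours(n_ind = 8, n_days = 5, seed = 76,
                          beta = c(temp = 0.8))
  full <- model_spec("log2_odba", "temp", knots = 6)
  sel <- all_subsets_selection(sim, full)
  expect_equal(nrow(sel$table), 2)
  f_with <- fit_lmm_ar1(sim, full, method = "ML")
  f_without <- fit_lmm_ar1(sim, model_spec("log2_odba", character(),
                                           knots = 6), method = "ML")
  expect_equal(sort(sel$table$aic), sort(c(f_with$aic, f_without$aic)),
               tolerance = 1e-6)
  expect_equal(sel$table$terms[1], "temp") # strong effect wins
  expect_equal(sel$table$delta_aic[1], 0)
})

test_that("daily prediction is pure and matches a Monte-Carlo oracle", {
  sim <- sim_cohort_hours(n_ind = 10, n_days = 6, seed = 77)
  spec <- model_spec("log2_odba", c("temp", "temp_sq"), knots = 8)
  fit <- fit_lmm_ar1(sim, spec)
  scen <- tibble::tibble(hour = 0:23, temp = 0.5)
  p1 <- predict_daily_odba(fit, scen)
  p2 <- predict_daily_odba(fit, scen)
  expect_identical(p1, p2)
  expect_equal(p1$daily_odba, sum(p1$hourly))
  # delta-method SE against simulation from the coefficient distribution
  set.seed(78)
  V <- as.matrix(vcov(fit$fit))
  beta <- nlme::fixef(fit$fit)
  X <- nightshift:::build_design_unchecked(scen, spec)$X
  draws <- MASS::mvrnorm(3000, beta, V)
  totals <- apply(draws, 1, function(b) sum(2^(X %*% b)))
  expect_lt(abs(mean(totals) - p1$daily_odba) / p1$daily_odba, 0.02)
  expect_lt(abs(sd(totals) - p1$se) / p1$se, 0.25)
  expect_error(predict_daily_odba(fit, scen[1:10, ]), "24")
  expect_error(
    predict_daily_odba(fit, tibble::tibble(hour = 0:23, rain = 0)),
    "missing covariates")
})

test_that("nightly model recovers repeatability from variance components", {
  # equal variance components: ICC near 0.5 across a small seeded batch
  icc_batch <- vapply(1:5, function(i) {
    nd <- simulate_nightly_records(20, 14, sigma_individual = 1,
                                   sigma_resid = 1, seed = 80 + i)
    fit_nightly_model(nd, c("temp", "rain"))$decomposition$icc
  }, numeric(1))
  expect_lt(abs(mean(icc_batch) - 0.5), 0.1)
  nd <- simulate_nightly_records(20, 14, sigma_individual = 1,
                                 sigma_resid = 1, seed = 81)
  # no individual signal: ICC stays near zero in most replicates
  iccs <- vapply(1:10, function(i) {
    nd0 <- simulate_nightly_records(20, 14, sigma_individual = 0,
                                    sigma_resid = 1, seed = 81 + i)
    fit_nightly_model(nd0, "temp")$decomposition$icc
  }, numeric(1))
  expect_gte(mean(iccs <= 0.1), 0.9)
  expect_error(fit_nightly_model(nd[nd$individual_id == "ind01", ], "temp"),
               "replication")
})

test_that("grouped cross-validation scores classifiers honestly", {
  # deterministic activity rule: near-perfect held-out classification
  sim <- sim_cohort_hours(n_ind = 8, n_days = 6, seed = 82)
  sim$active <- sim$temp > 0
  spec <- model_spec("active", "temp", knots = 6, ar1 = FALSE)
  cv <- k_fold_cv(sim, spec, k = 5, seed = 83)
  expect_gte(cv$accuracy, 0.99)
  # leave-one-group-out equals a brute-force loop over groups
  small <- sim[sim$individual_id %in% sprintf("ind%02d", 1:5), ]
  small$night_id <- nightshift:::night_id_of(small$hour_start)
  grp <- interaction(small$individual_id, small$night_id, drop = TRUE)
  k <- nlevels(grp)
  cv_loo <- k_fold_cv(small, spec, k = k, seed = 84)
  acc_oracle <- vapply(levels(grp), function(g) {
    train <- small[grp != g, ]
    test <- small[grp == g, ]
    f <- fit_glmm_binomial(train, spec, nAGQ = 0,
                           check_standardized = FALSE)
    mfr <- nightshift:::make_fit_frame(test, spec,
                                       check_standardized = FALSE)
    p <- predict(f$fit, newdata = mfr$frame, type = "response",
                 allow.new.levels = TRUE)
    mean((p > 0.5) == (mfr$frame$.response == 1))
  }, numeric(1))
  expect_equal(sort(cv_loo$folds$accuracy), sort(unname(acc_oracle)),
               tolerance = 1e-8)
})

test_that("random-slope comparison detects and rejects slope variance", {
  base_spec <- model_spec("log2_odba", "temp", knots = 6, ar1 = FALSE)
  # null: no slope variance, the simpler model usually wins on AIC
  null_pref <- vapply(1:10, function(i) {
    sim <- sim_cohort_hours(n_ind = 12, n_days = 4, seed = 90 + i,
                            beta = c(temp = 0.3), rho = 0)
    cmp <- compare_random_slopes(sim, base_spec, "temp")
    cmp$delta_aic > 0
  }, logical(1))
  expect_gte(mean(null_pref), 0.8)
  # power: strong individual slope variance flips the preference
  slope_pref <- vapply(1:10, function(i) {
    sim <- sim_cohort_hours(n_ind = 12, n_days = 4, seed = 190 + i,
                            beta = c(temp = 0.3), rho = 0)
    slopes <- rnorm(12, 0, 0.5)
    names(slopes) <- sprintf("ind%02d", 1:12)
    sim$log2_odba <- sim$log2_odba +
      slopes[sim$individual_id] * sim$temp
    sim$hourly_odba <- 2^sim$log2_odba
    cmp <- compare_random_slopes(sim, base_spec, "temp")
    cmp$delta_aic < 0
  }, logical(1))
  expect_gte(mean(slope_pref), 0.8)
})

test_that("plasticity surfaces recover the interaction geometry", {
  sim <- sim_cohort_hours(n_ind = 16, n_days = 7, seed = 95,
                          beta = c(temp = 0.3, bci = 0.1,
                                   bci_temp = -0.3))
  spec <- model_spec("log2_odba", c("temp", "bci", "bci_temp"), knots = 8)
  fit <- fit_lmm_ar1(sim, spec)
  surf <- plasticity_surface(fit, c(low = -1, high = 1),
                             temp_grid = c(-1, 0, 1))
  # negative interaction: high-BCI response to temperature is flatter
  slope_of <- function(lvl) {
    s <- surf[surf$bci_level == lvl, ]
    diff(log2(range(s$daily_odba[order(s$temp)])[c(1, 2)]))
    coef(lm(log2(daily_odba) ~ temp, data = s))[["temp"]]
  }
  expect_gt(slope_of("low"), slope_of("high"))
  # grid of one point equals a direct daily prediction
  one <- plasticity_surface(fit, c(mid = 0), temp_grid = 0.4)
  scen <- tibble::tibble(hour = 0:23, temp = 0.4, bci = 0)
  expect_equal(one$daily_odba, predict_daily_odba(fit, scen)$daily_odba)
  expect_false(one$extrapolated)
  far <- plasticity_surface(fit, c(mid = 0), temp_grid = 9)
  expect_true(far$extrapolated)
  # the interaction term is required
  fit0 <- fit_lmm_ar1(sim, model_spec("log2_odba", "temp", knots = 8))
  expect_error(plasticity_surface(fit0, c(low = -1), 0), "bci_temp")
})

test_that("cross-season intercept consistency uses Spearman on the overlap", {
  a <- tibble::tibble(individual_id = sprintf("i%02d", 1:10),
                      intercept = 1:10 / 10)
  b <- a
  out <- intercept_consistency(list(spring = a, summer = b))
  expect_equal(out$correlations$spearman, 1)
  b$intercept <- rev(a$intercept)
  expect_equal(
    intercept_consistency(list(spring = a, summer = b))$correlations$spearman,
    -1)
  # fewer than 3 shared individuals: correlation omitted with a note
  c2 <- tibble::tibble(individual_id = c("i01", "i02", "x1"),
                       intercept = c(1, 2, 3))
  out2 <- intercept_consistency(list(spring = a, autumn = c2))
  expect_true(is.na(out2$correlations$spearman))
  expect_match(out2$correlations$note, "fewer than 3")
  # independent intercepts rarely correlate strongly
  set.seed(96)
  rs <- replicate(100, {
    x <- tibble::tibble(individual_id = sprintf("i%02d", 1:30),
                        intercept = rnorm(30))
    y <- tibble::tibble(individual_id = sprintf("i%02d", 1:30),
                        intercept = rnorm(30))
    intercept_consistency(list(s1 = x, s2 = y))$correlations$spearman
  })
  expect_gte(mean(abs(rs) < 0.5), 0.95)
})

test_that("nightly disparity ratios scale with individual heterogeneity", {
  nr <- tibble::tibble(
    individual_id = rep(c("a", "b"), 3),
    night_id = rep(as.Date("2018-05-01") + 0:2, each = 2),
    total_odba = c(6, 3, 4, 4, 10, 2))
  disp <- nightly_disparity(nr)
  expect_equal(disp$per_night$ratio, c(2, 1, 5))
  # identical individuals: ratio 1 every night
  nr1 <- nr
  nr1$total_odba <- 5
  expect_true(all(nightly_disparity(nr1)$per_night$ratio == 1))
  # disparity grows with the individual SD (natural-scale totals)
  mean_ratio <- vapply(c(0.1, 0.5, 1), function(s) {
    nd <- simulate_nightly_records(10, 10, sigma_individual = s,
                                   sigma_resid = 0.3, beta = c(),
                                   seed = 97)
    nd$total_odba <- 2^nd$total_odba
    nightly_disparity(nd)$mean_ratio
  }, numeric(1))
  expect_true(all(diff(mean_ratio) > 0))
})
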