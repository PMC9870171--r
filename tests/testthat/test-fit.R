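test_that("objective matches hand-computed value on a symmetric class", {
  # one haul, q = 1, a single class at L50: r = 0.5 exactly
  counts <- data.frame(haul_id = "a", length = 20, n_codend = 5,
                       n_cover = 5)
  hauls <- data.frame(haul_id = "a", treatment = "t", q_codend = 1,
                      q_cover = 1)
  x <- catch_data(counts, hauls)
  expect_equal(neg_log_likelihood(x, "logit", c(L50 = 20, SR = 4)),
               10 * log(2), tolerance = 1e-12)
})

test_that("objective is linear in the raised counts", {
  counts <- data.frame(haul_id = "a", length = c(18, 22),
                       n_codend = c(2, 6), n_cover = c(5, 1))
  hauls <- data.frame(haul_id = "a", treatment = "t", q_codend = 0.5,
                      q_cover = 0.25)
  x1 <- catch_data(counts, hauls)
  hauls2 <- hauls; hauls2$q_codend <- 1; hauls2$q_cover <- 0.5
  x2 <- catch_data(counts, hauls2)
  p <- c(L50 = 20, SR = 4)
  expect_equal(neg_log_likelihood(x1, "logit", p),
               2 * neg_log_likelihood(x2, "logit", p), tolerance = 1e-12)
})

test_that("objective equals an independent double-loop oracle", {
  set.seed(31)
  for (i in 1:50) {
    x <- random_tiny_dataset()
    m <- sample(sel_models(), 1)
    p <- random_params(m)
    oracle <- brute_force_nll(x, function(l) retention(m, p, l))
    expect_equal(neg_log_likelihood(x, m, p), oracle, tolerance = 1e-10)
  }
})

test_that("objective ignores class order and empty classes", {
  x <- tiny_catch()
  p <- c(L50 = 18, SR = 3)
  v <- neg_log_likelihood(x, "logit", p)
  shuffled <- x$counts[sample(nrow(x$counts)), ]
  x2 <- catch_data(shuffled, x$hauls)
  expect_equal(neg_log_likelihood(x2, "logit", p), v, tolerance = 1e-12)
  extra <- rbind(x$counts, data.frame(haul_id = "a", length = c(25, 30),
                                      n_codend = 0, n_cover = 0))
  x3 <- catch_data(extra, x$hauls)
  expect_equal(neg_log_likelihood(x3, "logit", p), v, tolerance = 1e-12)
})

test_that("MLE matches an exhaustive grid search on toy data", {
  sim <- simulate_catch(catch_sim_config(n_hauls = 2, fish_per_haul = 400,
                                         seed = 99))
  fit <- fit_selection(sim$data, "logit")
  # independent vectorised grid evaluation of the pooled objective
  pooled <- codendsel:::pooled_raised(sim$data)
  l50s <- seq(17, 23, by = 0.01)
  srs <- seq(1, 8, by = 0.01)
  nll_grid <- function(L50, SR) {
    r <- plogis(outer(pooled$length, L50, "-") * (2 * log(3) / SR))
    r <- pmin(pmax(r, 1e-12), 1 - 1e-12)
    -colSums(pooled$raised_codend * log(r) +
               pooled$raised_cover * log(1 - r))
  }
  best <- c(Inf, NA, NA)
  for (SR in srs) {
    v <- nll_grid(l50s, SR)
    if (min(v) < best[1]) best <- c(min(v), l50s[which.min(v)], SR)
  }
  expect_lt(abs(coef(fit)[["L50"]] - best[2]), 0.011)
  expect_lt(abs(coef(fit)[["SR"]] - best[3]), 0.011)
  expect_lte(fit$nll, best[1] + 1e-6)
})

test_that("fit recovers the truth on a seeded synthetic dataset", {
  sim <- simulate_catch(catch_sim_config(seed = 1))
  fit <- fit_selection(sim$data, "logit")
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["L50"]] - 20), 0.3)
  expect_false(fit$boundary)
})

test_that("all-in-cover data is flagged as a boundary fit", {
  counts <- data.frame(haul_id = "a", length = 15:20, n_codend = 0,
                       n_cover = c(9, 11, 10, 12, 9, 10))
  hauls <- data.frame(haul_id = "a", treatment = "t", q_codend = 1,
                      q_cover = 1)
  fit <- fit_selection(catch_data(counts, hauls), "logit")
  expect_true(fit$boundary)
})

test_that("refitting is deterministic", {
  sim <- simulate_catch(catch_sim_config(n_hauls = 3, fish_per_haul = 300,
                                         seed = 4))
  f1 <- fit_selection(sim$data, "clogit")
  f2 <- fit_selection(sim$data, "clogit")
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$aic, f2$aic)
})

test_that("goodness of fit is exact on saturated-like predictions and dof
           follows the occupied-classes-minus-k convention", {
  sim <- simulate_catch(catch_sim_config(seed = 12))
  fit <- fit_selection(sim$data, "logit")
  pooled <- codendsel:::pooled_raised(sim$data)
  occupied <- sum(pooled$raised_codend + pooled$raised_cover > 0)
  expect_equal(fit$dof, occupied - 2)
  rich <- fit_selection(sim$data, "richard")
  expect_equal(rich$dof, occupied - 3)
  cgom <- fit_selection(sim$data, "cgompertz")
  expect_equal(cgom$dof, occupied - 3)

  # a curve that reproduces the observed proportions has deviance 0
  counts <- data.frame(haul_id = "a", length = c(19, 21),
                       n_codend = c(25, 75), n_cover = c(75, 25))
  hauls <- data.frame(haul_id = "a", treatment = "t", q_codend = 1,
                      q_cover = 1)
  x <- catch_data(counts, hauls)
  fit2 <- fit_selection(x, "logit")
  # logit through (19, .25), (21, .75): L50 = 20, SR = 2 reproduces data
  expect_equal(coef(fit2)[["L50"]], 20, tolerance = 1e-4)
  expect_equal(fit2$deviance, 0, tolerance = 1e-6)
})

test_that("gof p-values are approximately uniform under the true model", {
  # the chi-square reference requires informative cells: keep the length
  # range where retention is bounded away from 0 and 1, since saturated
  # classes contribute no deviance yet count towards the dof
  pv <- vapply(1:200, function(s) {
    sim <- simulate_catch(catch_sim_config(
      params = c(L50 = 21, SR = 6), length_mean = 21, length_sd = 3,
      length_range = c(16, 26), seed = 5000 + s))
    fit_selection(sim$data, "logit")$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("AIC selection picks the generating contact family", {
  wins <- vapply(1:50, function(s) {
    sim <- simulate_catch(catch_sim_config(
      model = "cgompertz", params = c(L50 = 22, SR = 4, C = 0.5),
      n_hauls = 10, fish_per_haul = 2000, seed = 7000 + s))
    fits <- fit_selection_all(sim$data,
                              c("logit", "probit", "gompertz",
                                "cgompertz", "crichard"))
    tab <- aic_table(fits)
    best <- tab$model[1]
    best %in% c("cgompertz", "crichard") ||
      tab$delta_aic[tab$model == "cgompertz"] < 2
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("select_model returns the lowest-AIC converged fit", {
  sim <- simulate_catch(catch_sim_config(n_hauls = 3, fish_per_haul = 500,
                                         seed = 2))
  fits <- fit_selection_all(sim$data, c("logit", "probit"))
  best <- select_model(fits)
  expect_equal(best$aic, min(aic_table(fits)$aic))
  expect_error(select_model(list()), "no converged fits")
})

test_that("parameter recovery is unbiased over 100 seeded datasets", {
  est <- vapply(1:100, function(s) {
    sim <- simulate_catch(catch_sim_config(seed = s))
    coef(fit_selection(sim$data, "logit"))
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 20), 0.1)
  expect_lt(abs(mean(est[2, ]) - 4), 0.2)
})

test_that("contact parameter estimates straddle the truth at small m", {
  Cs <- vapply(1:30, function(s) {
    sim <- simulate_catch(catch_sim_config(
      model = "cgompertz", params = c(L50 = 22, SR = 4, C = 0.5),
      n_hauls = 4, fish_per_haul = 600, seed = 9000 + s))
    coef(fit_selection(sim$data, "cgompertz"))[["C"]]
  }, numeric(1))
  qs <- quantile(Cs, c(0.025, 0.975))
  expect_lte(qs[[1]], 0.5)
  expect_gte(qs[[2]], 0.5)
})

test_that("fit methods expose the expected interface", {
  sim <- simulate_catch(catch_sim_config(n_hauls = 3, fish_per_haul = 500,
                                         seed = 8))
  fit <- fit_selection(sim$data, "logit")
  expect_named(coef(fit), c("L50", "SR"))
  expect_equal(AIC(fit), fit$aic)
  pr <- predict(fit, length = c(19, 20, 21))
  expect_equal(pr$retention[2],
               retention("logit", coef(fit), 20))
  rs <- residuals(fit)
  expect_true(all(is.finite(rs$residual)))
  expect_equal(sum(rs$residual^2), fit$deviance, tolerance = 1e-8)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(count_measured(sims[[1]]), count_measured(sim$data))
  expect_output(print(summary(fit)), "Codend selection curve fit")
})
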