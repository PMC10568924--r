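make_big_play <- function(n_per_cell = 300, seed = 2) {
  big <- cohort_design(batches = list(
    A = list(n_per_treatment = c(control = n_per_cell, kinematic_reduced = 5,
                                 social_reduced = n_per_cell), n_days = 1),
    C = list(n_per_treatment = c(control = n_per_cell, kinematic_reduced = 5,
                                 social_reduced = n_per_cell), n_days = 1)), seed = seed)
  simulate_play_bouts(big, seed = seed + 1)
}

test_that("the pinning GLM recovers its generating coefficients at large n", {
  fit <- fit_pinning_glm(make_big_play(500))
  est <- tidy(fit)$estimate
  expect_equal(est[1], 3.20, tolerance = 0.05)
  expect_equal(est[2], -0.45, tolerance = 0.07)
  expect_equal(est[3], -0.82, tolerance = 0.07)
  expect_equal(fit$family, "poisson")

  # constant counts -> intercept log(c), slopes 0
  play_c <- tibble::tibble(
    treatment = rep(c("control", "social_reduced"), each = 4),
    batch = rep(c("A", "C"), 4),
    pinnings_received = 7L, pinnings_delivered = 7L)
  td <- tidy(fit_pinning_glm(play_c))
  expect_equal(td$estimate[1], log(7), tolerance = 1e-6)
  expect_equal(td$estimate[-1], c(0, 0), tolerance = 1e-6)

  # single-level factor is a degenerate design
  expect_error(fit_pinning_glm(dplyr::filter(make_big_play(20), batch == "A")),
               "degenerate")
})

test_that("Poisson GLM bias shrinks with sample size on its own simulated output", {
  bias <- vapply(c(50, 500, 5000), function(n) {
    ests <- vapply(1:5, function(i) {
      set.seed(n + i)
      x <- rep(c(0, 1), length.out = n)
      y <- rpois(n, exp(1.0 + 0.5 * x))
      coef(glm(y ~ x, family = poisson()))[["x"]]
    }, numeric(1))
    abs(mean(ests) - 0.5)
  }, numeric(1))
  expect_lt(bias[3], 0.02)
  expect_lt(bias[3], bias[1] + 0.02)
})

test_that("the asymmetry LM behaves like OLS and recovers simulated effects", {
  play_c <- tibble::tibble(
    treatment = rep(c("control", "social_reduced"), each = 4),
    batch = rep(c("A", "C"), 4),
    pinnings_delivered = 6L, pinnings_received = 2L)
  td <- suppressWarnings(tidy(fit_asymmetry_lm(play_c)))
  expect_equal(td$estimate[1], 0.5, tolerance = 1e-9)
  expect_equal(td$estimate[-1], c(0, 0), tolerance = 1e-9)

  # direct simulation at published coefficients with small noise
  set.seed(9)
  n <- 200
  d <- tibble::tibble(
    treatment = sample(c("control", "social_reduced"), n, TRUE),
    batch = sample(c("A", "C"), n, TRUE))
  lp <- 1.30 - 1.33 * (d$treatment == "social_reduced") - 1.82 * (d$batch == "C")
  d$asymmetry <- lp + rnorm(n, 0, 0.3)
  d$pinnings_delivered <- 1; d$pinnings_received <- 0
  td2 <- tidy(fit_asymmetry_lm(d))
  for (i in seq_len(3)) {
    expect_lt(abs(td2$estimate[i] - c(1.30, -1.33, -1.82)[i]),
              3 * td2$std.error[i])
  }
})

test_that("AICc obeys its algebraic identity and ranks candidates correctly", {
  d <- cohort_design()
  sess <- simulate_usv_counts(d, seed = 11)
  fit <- suppressWarnings(suppressMessages(fit_usv_lmm(sess, method = "ML")))
  g <- glance(fit)
  expect_equal(g$AICc - g$AIC, 2 * g$k * (g$k + 1) / (g$n - g$k - 1))

  one <- aicc_rank(list(full = fit))
  expect_equal(one$delta_AICc, 0)

  tiny <- new_env_fit <- fit
  tiny$n <- fit$df + 1
  expect_error(aicc(tiny), "AICc undefined")

  # with a real day effect and no order effect, dropping day hurts the rank
  pr <- generative_params(usv50 = list(order = 0))
  worse <- 0
  for (seed in 1:10) {
    s <- simulate_usv_counts(d, pr, seed = 100 + seed)
    f_day <- suppressMessages(fit_usv_lmm(
      s, n50 ~ treatment + batch + day + (1 | rat_id) + (1 | litter_id), "ML"))
    f_noday <- suppressMessages(fit_usv_lmm(
      s, n50 ~ treatment + batch + (1 | rat_id) + (1 | litter_id), "ML"))
    rk <- aicc_rank(list(day = f_day, noday = f_noday))
    if (rk$model[1] == "day") worse <- worse + 1
  }
  expect_gte(worse, 9)
})

test_that("repeatability matches the variance-ratio closed form and its invariances", {
  # many rats and litters: with few litters a zero litter variance sits on
  # the boundary and absorbs rat variance, biasing R downward
  d <- cohort_design(batches = list(
    A = list(n_per_treatment = c(control = 70, kinematic_reduced = 70,
                                 social_reduced = 70), n_days = 8)),
    n_litters_per_batch = 30, seed = 3)
  pr <- generative_params(usv50 = list(sd_rat = 30, sd_litter = 0, sd_resid = 30,
                                       intercept = 150))
  sess <- simulate_usv_counts(d, pr, seed = 12)
  fit <- suppressMessages(fit_usv_lmm(
    sess, n50 ~ treatment + day + order + (1 | rat_id) + (1 | litter_id)))
  r <- repeatability(fit, "rat_id", n_boot = 50, seed = 1)
  expect_equal(r$R, 0.5, tolerance = 0.06)
  expect_true(r$ci[1] <= r$R && r$R <= r$ci[2])
  expect_true(all(r$boot >= 0 & r$boot <= 1))

  # shifting the response by a constant leaves R unchanged (Gaussian case)
  sess_shift <- dplyr::mutate(sess, n50 = n50 + 1000)
  fit_shift <- suppressMessages(fit_usv_lmm(
    sess_shift, n50 ~ treatment + day + order + (1 | rat_id) + (1 | litter_id)))
  expect_equal(repeatability(fit_shift, "rat_id", n_boot = 0)$R, r$R,
               tolerance = 1e-4)

  expect_error(repeatability(fit, "day", n_boot = 0), "not a random intercept")
})

test_that("marginal means on a balanced one-factor design equal the cell means", {
  set.seed(13)
  d <- tibble::tibble(
    treatment = rep(c("control", "social_reduced"), each = 30),
    batch = rep(c("A", "C"), 30),
    pinnings_received = rpois(60, 10), pinnings_delivered = rpois(60, 10))
  fit <- fit_pinning_glm(d)
  mm <- marginal_means(fit, "treatment")
  # equal-weight marginal means on the response scale: geometric mean over batches
  cell <- d |>
    dplyr::group_by(treatment, batch) |>
    dplyr::summarise(m = mean(pinnings_received), .groups = "drop") |>
    dplyr::group_by(treatment) |>
    dplyr::summarise(m = exp(mean(log(m))))
  expect_equal(mm$means$mean, cell$m, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(nrow(mm$contrasts), 1)
  expect_error(marginal_means(fit, "period_type"), "not a term")
})

test_that("Spearman correlation agrees with a brute-force rank computation", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)

  x <- c(3, 1, 4, 1, 5)
  y <- c(9, 2, 6, 5, 3)
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      mean(which(sort(v) == v[i]))
    }, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_cor(x, y)$rho, manual, tolerance = 1e-12)

  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:3, 1:4), "equal length")
})

test_that("the contact-rate model recovers flat and elevated period effects", {
  d <- cohort_design()
  pr_flat <- generative_params(rates = list(ventral = 0, dorsal = 0))
  rates0 <- simulate_period_rates(d, pr_flat, seed = 14)
  td0 <- tidy(suppressMessages(contact_rate_model(rates0)))
  expect_lt(max(abs(td0$estimate[grepl("period_type", td0$term)])), 0.15)

  pr_up <- generative_params(rates = list(ventral = 1.2, dorsal = 1.2))
  rates1 <- simulate_period_rates(d, pr_up, seed = 15)
  td1 <- tidy(suppressMessages(contact_rate_model(rates1)))
  expect_equal(td1$estimate[td1$term == "period_typeventral"], 1.2, tolerance = 0.15)
  expect_equal(td1$estimate[td1$term == "period_typedorsal"], 1.2, tolerance = 0.15)
})
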