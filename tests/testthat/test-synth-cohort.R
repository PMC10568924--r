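test_that("the default cohort reproduces the study design", {
  d <- cohort_design()
  expect_equal(nrow(d$rats), 53)
  expect_equal(sum(d$rats$n_days), 476)
  counts <- table(d$rats$batch, d$rats$treatment)
  expect_equal(unname(counts["A", "control"]), 5)
  expect_true(all(counts[, "kinematic_reduced"] == 6))
  # tickling order is a permutation within each batch
  for (b in unique(d$rats$batch)) {
    o <- d$rats$order[d$rats$batch == b]
    expect_setequal(o, seq_along(o))
  }
})

test_that("pinning simulation matches its Poisson generative model", {
  # large balanced design for tight Monte-Carlo checks
  big <- cohort_design(batches = list(
    A = list(n_per_treatment = c(control = 400, kinematic_reduced = 50,
                                 social_reduced = 400), n_days = 1),
    C = list(n_per_treatment = c(control = 400, kinematic_reduced = 50,
                                 social_reduced = 400), n_days = 1)), seed = 1)
  play <- simulate_play_bouts(big, seed = 2)

  kin <- dplyr::filter(play, treatment == "kinematic_reduced")
  expect_true(all(kin$pinnings_received == 0))
  expect_true(all(kin$pinnings_delivered == 0))

  # sum of n iid Poisson(lambda) draws is Poisson(n*lambda): exact test
  ctrA <- dplyr::filter(play, treatment == "control", batch == "A")
  pt <- poisson.test(sum(ctrA$pinnings_received),
                     T = nrow(ctrA), r = exp(3.20))
  expect_gt(pt$p.value, 0.01)
  socC <- dplyr::filter(play, treatment == "social_reduced", batch == "C")
  pt2 <- poisson.test(sum(socC$pinnings_received),
                      T = nrow(socC), r = exp(3.20 - 0.45 - 0.82))
  expect_gt(pt2$p.value, 0.01)

  # all coefficients zero -> mean 1 in every cell
  p0 <- generative_params(pinning = list(intercept = 0, social_reduced = 0,
                                         batch_C = 0, delivered_shift_social = 0))
  play0 <- simulate_play_bouts(big, p0, seed = 3)
  nz <- dplyr::filter(play0, treatment != "kinematic_reduced")
  expect_gt(poisson.test(sum(nz$pinnings_received), T = nrow(nz), r = 1)$p.value, 0.01)
})

test_that("USV count simulation carries the intended variance structure", {
  d <- cohort_design(batches = list(
    A = list(n_per_treatment = c(control = 70, kinematic_reduced = 70,
                                 social_reduced = 70), n_days = 8)),
    n_litters_per_batch = 30, seed = 3)
  pr <- generative_params(usv50 = list(sd_rat = 30, sd_litter = 0, sd_resid = 30,
                                       intercept = 150))
  sess <- simulate_usv_counts(d, pr, seed = 4)
  fit <- suppressMessages(fit_usv_lmm(
    sess, n50 ~ treatment + day + order + (1 | rat_id) + (1 | litter_id)))
  r <- repeatability(fit, "rat_id", n_boot = 0)
  expect_equal(r$R, 0.5, tolerance = 0.06)

  pr0 <- generative_params(usv50 = list(sd_rat = 0, sd_litter = 0, sd_resid = 10,
                                        intercept = 100))
  sess0 <- simulate_usv_counts(d, pr0, seed = 5)
  fit0 <- suppressMessages(fit_usv_lmm(
    sess0, n50 ~ treatment + day + order + (1 | rat_id) + (1 | litter_id)))
  expect_lt(repeatability(fit0, "rat_id", n_boot = 0)$R, 0.1)

  # counts are non-negative integers and 22-kHz counts are Poisson-like
  sess2 <- simulate_usv_counts(d, seed = 6)
  expect_true(all(sess2$n50 >= 0), all(sess2$n50 == round(sess2$n50)))
  expect_true(all(sess2$n22 >= 0))
})

test_that("generating-model coefficients are recovered by refitting", {
  d <- cohort_design()
  sess <- simulate_usv_counts(d, seed = 7)
  fit <- suppressMessages(fit_usv_lmm(sess))
  td <- tidy(fit)
  truth <- c("day" = 3.09, "order" = 4.31,
             "treatmentsocial_reduced" = -33.35)
  for (term in names(truth)) {
    row <- td[td$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$std.error)
  }
})

test_that("the contact schedule alternates hover and tickle blocks and tiles the session", {
  s120 <- make_contact_schedule(120)
  expect_equal(sum(s120$period_type == "none"), 4)
  expect_equal(sum(s120$period_type == "dorsal"), 4)
  expect_equal(sum(s120$period_type == "ventral"), 4)
  expect_equal(sum(s120$end_s - s120$start_s), 120)
  # periods tile without overlap
  o <- order(s120$start_s)
  expect_equal(s120$start_s[o][-1], s120$end_s[o][-nrow(s120)])

  s30 <- make_contact_schedule(30)
  expect_equal(sum(s30$period_type == "none"), 1)
  expect_equal(sum(s30$period_type %in% c("dorsal", "ventral")), 2)
  expect_error(make_contact_schedule(20), "at least one")

  s100 <- make_contact_schedule(100)   # truncated trailing block
  expect_equal(sum(s100$end_s - s100$start_s), 100)
})

test_that("period-rate simulation elevates contact periods as parameterised", {
  d <- cohort_design()
  rates <- simulate_period_rates(d, seed = 8)
  expect_setequal(unique(rates$period_type), c("none", "dorsal", "ventral"))
  fit <- suppressMessages(contact_rate_model(rates))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "period_typeventral"], 1.24, tolerance = 0.15)
  expect_equal(td$estimate[td$term == "period_typedorsal"], 1.22, tolerance = 0.15)
})
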