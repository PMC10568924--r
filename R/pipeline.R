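# End-to-end commands: detector benchmark, reproduction of the published
# analysis from session/play/rate tables, and the full synthetic pipeline.

#' Published reference estimates
#'
#' The published coefficient estimates, marginal means and repeatabilities
#' of the rat tickling study whose analysis this package reimplements, used
#' by [run_reproduction()] to attach pass/fail tolerance flags. Values are
#' as printed (two decimals).
#'
#' @return A tibble: `table`, `term`, `reference`.
#' @export
reference_estimates <- function() {
  tibble::tribble(
    ~table,          ~term,                       ~reference,
    "pinning_glm",   "(Intercept)",               3.20,
    "pinning_glm",   "treatmentsocial_reduced",  -0.45,
    "pinning_glm",   "batchC",                   -0.82,
    "asymmetry_lm",  "(Intercept)",               1.30,
    "asymmetry_lm",  "treatmentsocial_reduced",  -1.33,
    "asymmetry_lm",  "batchC",                   -1.82,
    "usv50_lmm",     "(Intercept)",             136.27,
    "usv50_lmm",     "treatmentsocial_reduced", -33.35,
    "usv50_lmm",     "treatmentkinematic_reduced", -8.59,
    "usv50_lmm",     "day",                       3.09,
    "usv50_lmm",     "order",                     4.31,
    "usv50_lmm",     "batchB",                  -25.56,
    "usv50_lmm",     "batchC",                  -23.58,
    "usv22_glmm",    "(Intercept)",              -0.72,
    "usv22_glmm",    "day",                       0.17,
    "usv22_glmm",    "batchB",                    2.13,
    "usv22_glmm",    "batchC",                   -0.01,
    "rate_lmm",      "(Intercept)",               0.80,
    "rate_lmm",      "treatmentsocial_reduced",  -0.38,
    "rate_lmm",      "treatmentkinematic_reduced", -0.46,
    "rate_lmm",      "period_typeventral",        1.24,
    "rate_lmm",      "period_typedorsal",         1.22,
    "marginal_means","control",                  17.7,
    "marginal_means","social_reduced",           11.2,
    "repeatability", "usv50_rat",                 0.519,
    "repeatability", "usv50_litter",              0.137,
    "repeatability", "usv22_rat",                 0.381
  )
}

#' Run the detector validation benchmark
#'
#' Simulates the default synthetic benchmark (200 calls of mixed 50-kHz
#' types over tilted background noise at >= 15 dB in-band SNR), runs the
#' two-pass detector at the printed parameters and scores it against ground
#' truth, overall and per call type.
#'
#' @param seed Integer seed for the recording plan.
#' @param n_calls,duration_s,snr_db_range Benchmark plan settings.
#' @param profile A [detector_profile()].
#' @param plan Optional pre-built [recording_plan()] (overrides the plan
#'   settings).
#' @param iou_min,onset_tol_ms Matching tolerances.
#' @return A list of class `usv_benchmark`: `eval` (a `usv_eval`),
#'   `by_type` tibble, `detections`, `truth`, `config`.
#' @export
run_benchmark <- function(seed = 1, n_calls = 200, duration_s = 60,
                          snr_db_range = c(15, 30),
                          profile = detector_profile("usv50"),
                          plan = NULL, iou_min = 0.3, onset_tol_ms = 5) {
  plan <- plan %||% recording_plan(duration_s = duration_s, n_calls = n_calls,
                                   snr_db_range = snr_db_range, seed = seed)
  synth <- synth_recording(plan)
  dets <- detect_recording(synth$recording, profile,
                           stft_params(fs = synth$recording$fs))
  ev <- evaluate_detections(dets, synth$truth, iou_min = iou_min,
                            onset_tol_ms = onset_tol_ms)
  matched_truth <- ev$pairs$truth
  by_type <- synth$truth |>
    mutate(.row = dplyr::row_number(),
           matched = .data$.row %in% matched_truth) |>
    group_by(.data$call_type) |>
    summarise(n_truth = n(), n_matched = sum(.data$matched),
              recall = mean(.data$matched), .groups = "drop")
  structure(list(eval = ev, by_type = by_type, detections = dets,
                 truth = synth$truth,
                 config = list(seed = seed, n_calls = nrow(plan$calls),
                               duration_s = plan$duration_s,
                               snr_db_range = snr_db_range,
                               profile = profile$name)),
            class = "usv_benchmark")
}

#' @export
print.usv_benchmark <- function(x, ...) {
  cat(sprintf("<usv_benchmark: %d calls, %.0f s, seed %d>\n",
              x$config$n_calls, x$config$duration_s, x$config$seed))
  print(x$eval)
  print(x$by_type)
  invisible(x)
}

#' Write a benchmark evaluation to JSON
#'
#' @param bench A `usv_benchmark`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_json <- function(bench, path) {
  jsonlite::write_json(
    list(config = bench$config,
         overall = as.list(tidy(bench$eval)),
         by_type = bench$by_type),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

compare_reference <- function(tb, table_name, tol = 0.25) {
  ref <- filter(reference_estimates(), .data$table == table_name) |>
    select("term", "reference")
  tb |>
    left_join(ref, by = "term") |>
    mutate(rel_diff = abs(.data$estimate - .data$reference) /
             pmax(abs(.data$reference), 1),
           within_tolerance = .data$rel_diff <= tol)
}

#' Reproduce the published analysis from data tables
#'
#' Runs the full statistical stage on session, play and (optionally) rate
#' tables following the documented CSV schema: the Poisson GLM on received
#' pinnings and the linear model on asymmetry; the Gaussian mixed model on
#' 50-kHz counts with its AICc candidate ranking, treatment marginal means
#' and rat/litter repeatability; the Poisson mixed model on 22-kHz counts;
#' the Spearman correlation between per-session total call duration and
#' count (when a `total_dur_s` column is present); and the contact-period
#' rate model. Each coefficient table carries the published reference value
#' and a tolerance flag.
#'
#' @param sessions Session tibble (`rat_id`, `litter_id`, `treatment`,
#'   `batch`, `day`, `order`, `n50`, `n22`, optionally `total_dur_s`).
#' @param play Play tibble (`rat_id`, `treatment`, `batch`,
#'   `pinnings_delivered`, `pinnings_received`).
#' @param rates Optional rates tibble for the contact-period model.
#' @param n_boot Bootstrap draws for the repeatability intervals.
#' @param seed Seed for the bootstrap.
#' @param compare Attach published-reference comparison columns.
#' @return A list of class `usv_report` with tibbles/objects per analysis.
#' @export
run_reproduction <- function(sessions, play, rates = NULL, n_boot = 200,
                             seed = 1, compare = TRUE) {
  check_columns(sessions, c("rat_id", "litter_id", "treatment", "batch",
                            "day", "order", "n50", "n22"), "session table")
  check_columns(play, c("treatment", "batch", "pinnings_delivered",
                        "pinnings_received"), "play table")
  pin <- fit_pinning_glm(play)
  asym <- fit_asymmetry_lm(play)
  lmm_full <- fit_usv_lmm(sessions, method = "REML")
  cand50 <- list(
    "treatment + batch + days + order" = n50 ~ treatment + batch + day + order + (1 | rat_id) + (1 | litter_id),
    "treatment + batch + days"         = n50 ~ treatment + batch + day + (1 | rat_id) + (1 | litter_id),
    "treatment + days + order"         = n50 ~ treatment + day + order + (1 | rat_id) + (1 | litter_id),
    "batch + days + order"             = n50 ~ batch + day + order + (1 | rat_id) + (1 | litter_id),
    "treatment + batch + order"        = n50 ~ treatment + batch + order + (1 | rat_id) + (1 | litter_id)
  )
  rank50 <- aicc_rank(map(cand50, function(f) fit_usv_lmm(sessions, f, method = "ML")))
  glmm22 <- fit_usv22_glmm(sessions)
  cand22 <- list(
    "batch + days"                     = n22 ~ batch + day + (1 | rat_id) + (1 | litter_id),
    "batch + days + order"             = n22 ~ batch + day + order + (1 | rat_id) + (1 | litter_id),
    "treatment + batch + days"         = n22 ~ treatment + batch + day + (1 | rat_id) + (1 | litter_id),
    "treatment + batch + days + order" = n22 ~ treatment + batch + day + order + (1 | rat_id) + (1 | litter_id),
    "days"                             = n22 ~ day + (1 | rat_id) + (1 | litter_id)
  )
  rank22 <- aicc_rank(map(cand22, function(f) fit_usv22_glmm(sessions, f)))
  rpt <- list(
    usv50_rat = repeatability(lmm_full, "rat_id", n_boot = n_boot, seed = seed),
    usv50_litter = repeatability(lmm_full, "litter_id", n_boot = n_boot, seed = seed + 1),
    usv22_rat = repeatability(glmm22, "rat_id", n_boot = 0)
  )
  mm <- marginal_means(pin, "treatment")
  mm50 <- marginal_means(lmm_full, "treatment")
  sp <- if ("total_dur_s" %in% names(sessions)) {
    spearman_cor(sessions$total_dur_s, sessions$n50)
  } else NULL
  rate_fit <- if (!is.null(rates)) contact_rate_model(rates) else NULL
  rate_rank <- if (!is.null(rates)) {
    cand_r <- list(
      "contact + treatment"            = rate_per_s ~ period_type + treatment + (1 | rat_id) + (1 | litter_id),
      "contact + treatment + duration" = rate_per_s ~ period_type + treatment + total_duration_s + (1 | rat_id) + (1 | litter_id),
      "contact * treatment + duration" = rate_per_s ~ period_type * treatment + total_duration_s + (1 | rat_id) + (1 | litter_id),
      "contact * treatment"            = rate_per_s ~ period_type * treatment + (1 | rat_id) + (1 | litter_id),
      "contact + treatment + days"     = rate_per_s ~ period_type + treatment + day + (1 | rat_id) + (1 | litter_id)
    )
    aicc_rank(map(cand_r, function(f) contact_rate_model(rates, f, method = "ML")))
  } else NULL
  coefs <- list(pinning_glm = tidy(pin), asymmetry_lm = tidy(asym),
                usv50_lmm = tidy(lmm_full), usv22_glmm = tidy(glmm22))
  if (!is.null(rate_fit)) coefs$rate_lmm <- tidy(rate_fit)
  if (compare) coefs <- imap(coefs, function(tb, nm) compare_reference(tb, nm))
  structure(list(
    coefficients = coefs,
    model_ranking = list(usv50 = rank50, usv22 = rank22, rates = rate_rank),
    repeatability = map(rpt, tidy) |> list_rbind() |>
      mutate(term = names(rpt)),
    marginal_means = list(pinnings = mm, usv50 = mm50),
    spearman = sp,
    fits = list(pinning = pin, asymmetry = asym, usv50 = lmm_full,
                usv22 = glmm22, rates = rate_fit),
    session_summary = tibble(
      mean_n50 = mean(sessions$n50), sd_n50 = sd(sessions$n50),
      mean_n22 = mean(sessions$n22), sd_n22 = sd(sessions$n22),
      n_sessions = nrow(sessions))
  ), class = "usv_report")
}

#' @export
print.usv_report <- function(x, ...) {
  cat("<usv_report>\n\n-- coefficient tables --\n")
  for (nm in names(x$coefficients)) {
    cat(sprintf("\n%s:\n", nm))
    print(as.data.frame(x$coefficients[[nm]]), digits = 3)
  }
  cat("\n-- repeatability --\n")
  print(as.data.frame(x$repeatability), digits = 3)
  cat("\n-- marginal means (pinnings) --\n")
  print(as.data.frame(x$marginal_means$pinnings$means), digits = 3)
  invisible(x)
}

#' Write a reproduction report to a directory
#'
#' Writes the coefficient tables and model rankings as CSV and the whole
#' report as JSON.
#'
#' @param report A `usv_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$coefficients)) {
    utils::write.csv(report$coefficients[[nm]],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  for (nm in names(report$model_ranking)) {
    if (!is.null(report$model_ranking[[nm]])) {
      utils::write.csv(report$model_ranking[[nm]],
                       file.path(dir, paste0("aicc_", nm, ".csv")), row.names = FALSE)
    }
  }
  utils::write.csv(report$repeatability, file.path(dir, "repeatability.csv"),
                   row.names = FALSE)
  utils::write.csv(report$marginal_means$pinnings$means,
                   file.path(dir, "marginal_means_pinnings.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(coefficients = report$coefficients,
         repeatability = report$repeatability,
         session_summary = report$session_summary,
         spearman = report$spearman),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full synthetic pipeline
#'
#' Cohort simulation, per-session audio synthesis, detection, counting,
#' per-period emission rates and (optionally) the statistical stage. Session
#' call counts are drawn from the cohort generative model, scaled to the
#' (shorter) synthetic session duration; before any model is fitted the
#' detected per-session counts are checked against the planted ground truth
#' and a mismatch beyond `max_count_mismatch` aborts with a per-session
#' diff.
#'
#' @param n_rats Rats to simulate (single batch, balanced treatments).
#' @param n_days Sessions per rat.
#' @param session_s Synthetic session duration in seconds.
#' @param count_scale Factor applied to the generative-model session counts
#'   to fit the shorter session.
#' @param snr_db_range In-band SNR range of the planted calls.
#' @param seed Integer seed driving every stage.
#' @param fit_models Fit the statistical stage on the detected counts.
#' @param max_count_mismatch Allowed |detected - planted| per session.
#' @return A list of class `usv_synthetic_run`: `sessions` (planted and
#'   detected counts), `rates`, `mismatches`, optionally `lmm`, plus the
#'   `config`.
#' @export
run_full_synthetic <- function(n_rats = 6, n_days = 3, session_s = 20,
                               count_scale = 0.08, snr_db_range = c(20, 30),
                               seed = 1, fit_models = TRUE,
                               max_count_mismatch = 0) {
  design <- cohort_design(batches = list(
    A = list(n_per_treatment = c(control = ceiling(n_rats / 3),
                                 kinematic_reduced = ceiling(n_rats / 3),
                                 social_reduced = n_rats - 2 * ceiling(n_rats / 3)),
             n_days = n_days)), seed = seed)
  design$rats <- head(design$rats, n_rats)
  sessions <- simulate_usv_counts(design, seed = seed + 1) |>
    mutate(n_planted = pmax(1, round(.data$n50 * count_scale)))
  # shrink the 15 s hover/tickle blocks proportionally for short sessions
  block_s <- min(15, session_s / 4)
  sched <- make_contact_schedule(session_s, hover_s = block_s, tickle_s = block_s)
  profile <- detector_profile("usv50")
  res <- pmap(list(sessions$rat_id, sessions$day, sessions$n_planted,
                   seq_len(nrow(sessions))),
    function(rat, day, n_planted, i) {
      plan <- recording_plan(duration_s = session_s, n_calls = n_planted,
                             snr_db_range = snr_db_range, seed = seed * 1000 + i)
      synth <- synth_recording(plan)
      dets <- detect_recording(synth$recording, profile)
      ev <- evaluate_detections(dets, synth$truth)
      rates <- emission_rates(dets, sched)
      list(n_detected = nrow(dets), n_matched = ev$n_matched,
           rates = mutate(rates, rat_id = rat, day = day))
    })
  sessions$n_detected <- map_dbl(res, "n_detected")
  mism <- filter(sessions, abs(.data$n_detected - .data$n_planted) > max_count_mismatch)
  if (nrow(mism) > 0) {
    abort(paste0("detected counts diverge from planted counts:\n",
                 paste(sprintf("  %s day %d: planted %d, detected %d",
                               mism$rat_id, mism$day, mism$n_planted,
                               mism$n_detected), collapse = "\n")))
  }
  rates <- map(res, "rates") |> list_rbind() |>
    left_join(select(design$rats, "rat_id", "litter_id", "treatment"),
              by = "rat_id")
  out <- list(sessions = sessions, rates = rates,
              config = list(n_rats = n_rats, n_days = n_days,
                            session_s = session_s, seed = seed))
  if (fit_models) {
    out$lmm <- tryCatch(
      fit_usv_lmm(mutate(sessions, n50 = .data$n_detected),
                  n50 ~ treatment + day + (1 | rat_id), method = "REML"),
      error = function(e) NULL)
  }
  structure(out, class = "usv_synthetic_run")
}

#' @export
print.usv_synthetic_run <- function(x, ...) {
  cat(sprintf("<usv_synthetic_run: %d rats x %d sessions of %g s, seed %d>\n",
              x$config$n_rats, x$config$n_days, x$config$session_s,
              x$config$seed))
  cat(sprintf("  planted = detected in all %d sessions\n", nrow(x$sessions)))
  if (!is.null(x$lmm)) print(glance(x$lmm))
  invisible(x)
}
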