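# Seeded generators for cohort-structured behavioural tables: the study
# design (3 treatments x 3 batches, litters, repeated tickling sessions)
# with the generative structure the statistical stage assumes.

#' Cohort design
#'
#' Builds the rat table of a simulated cohort. Defaults reproduce the study
#' design: three batches of male rats (A: 17 = 5 control + 6 + 6; B and C:
#' 18 = 6 per treatment), four litters per batch with litter mates spread
#' across treatments, ten tickling sessions per rat in batches A and C and
#' seven in batch B (476 sessions in total), and a fixed but randomly drawn
#' tickling order within each batch.
#'
#' @param batches Named list: for each batch, `n_per_treatment` (named
#'   control / kinematic_reduced / social_reduced) and `n_days`.
#' @param n_litters_per_batch Litters per batch.
#' @param seed Integer seed for the order permutation and litter assignment.
#' @return A list of class `cohort_design` with a `rats` tibble
#'   (`rat_id`, `litter_id`, `treatment`, `batch`, `order`, `n_days`).
#' @examples
#' design <- cohort_design()
#' nrow(design$rats)      # 53 rats
#' sum(design$rats$n_days) # 476 sessions
#' @export
cohort_design <- function(batches = NULL, n_litters_per_batch = 4, seed = 1) {
  batches <- batches %||% list(
    A = list(n_per_treatment = c(control = 5, kinematic_reduced = 6, social_reduced = 6),
             n_days = 10),
    B = list(n_per_treatment = c(control = 6, kinematic_reduced = 6, social_reduced = 6),
             n_days = 7),
    C = list(n_per_treatment = c(control = 6, kinematic_reduced = 6, social_reduced = 6),
             n_days = 10)
  )
  withr::local_seed(seed)
  rats <- imap(batches, function(b, bname) {
    treatment <- rep(names(b$n_per_treatment), b$n_per_treatment)
    n <- length(treatment)
    tibble(
      rat_id = sprintf("%s%02d", bname, seq_len(n)),
      # litter mates are spread across treatments: cycle litters within batch
      litter_id = sprintf("%s_L%d", bname,
                          rep_len(seq_len(n_litters_per_batch), n)),
      treatment = treatment,
      batch = bname,
      order = sample(n),
      n_days = b$n_days
    )
  }) |> list_rbind()
  structure(list(rats = rats, seed = seed), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design: %d rats, %d batches, %d sessions>\n",
              nrow(x$rats), length(unique(x$rats$batch)), sum(x$rats$n_days)))
  invisible(x)
}

#' Generative parameters for the behavioural tables
#'
#' Coefficients of the generating models for pinning counts, per-session
#' 50-kHz and 22-kHz USV counts and per-contact-period emission rates.
#' Fixed-effect defaults are the study's published estimates (log-link
#' Poisson for received pinnings: intercept 3.20, social reduction -0.45,
#' batch C -0.82; Gaussian mixed model for 50-kHz counts: intercept 136.27,
#' day slope 3.09, order slope 4.31, etc.). Variance components are not
#' published; defaults are chosen so the total random SD and the variance
#' shares match the published session SD and repeatabilities.
#'
#' @param ... Named overrides of any default component.
#' @return A list of class `generative_params`.
#' @export
generative_params <- function(...) {
  p <- list(
    pinning = list(intercept = 3.20, social_reduced = -0.45, batch_C = -0.82,
                   # delivered counts: symmetric for controls, shifted up for
                   # socially reduced rats (their partners rarely pin back)
                   delivered_shift_social = 1.0),
    usv50 = list(intercept = 136.27, social_reduced = -33.35,
                 kinematic_reduced = -8.59, day = 3.09, order = 4.31,
                 batch_B = -25.56, batch_C = -23.58,
                 sd_rat = 50, sd_litter = 26, sd_resid = 41.5),
    usv22 = list(intercept = -0.72, day = 0.17, batch_B = 2.13,
                 batch_C = -0.01, sd_rat = 0.4, sd_litter = 0.1),
    rates = list(intercept = 0.80, social_reduced = -0.38,
                 kinematic_reduced = -0.46, ventral = 1.24, dorsal = 1.22,
                 sd_rat = 0.4, sd_litter = 0.15, sd_resid = 0.5)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) abort(sprintf("unknown component '%s'", nm))
    p[[nm]][names(dots[[nm]])] <- dots[[nm]]
  }
  stopifnot(p$usv50$sd_rat >= 0, p$usv50$sd_litter >= 0, p$usv50$sd_resid >= 0,
            p$usv22$sd_rat >= 0, p$usv22$sd_litter >= 0)
  structure(p, class = "generative_params")
}

#' Simulate rough-and-tumble play pinning counts
#'
#' Received pinnings are Poisson with log-linear treatment and batch
#' effects; rats with kinematically reduced play receive (and deliver) no
#' pinnings at all, matching the design in which a lowered ceiling prevents
#' pinning entirely. Delivered pinnings are Poisson at the same rate for
#' controls and at a shifted (higher) rate for socially reduced rats, whose
#' less playful partners rarely pin back. Only batches A and C are scored,
#' as in the study.
#'
#' @param design A [cohort_design()].
#' @param params A [generative_params()].
#' @param seed Integer seed.
#' @param scored_batches Batches whose play is scored.
#' @return A play tibble: `rat_id`, `litter_id`, `treatment`, `batch`,
#'   `pinnings_delivered`, `pinnings_received`.
#' @export
simulate_play_bouts <- function(design, params = generative_params(), seed = 1,
                                scored_batches = c("A", "C")) {
  withr::local_seed(seed)
  pp <- params$pinning
  design$rats |>
    filter(.data$batch %in% scored_batches) |>
    mutate(
      lp = pp$intercept +
        pp$social_reduced * (.data$treatment == "social_reduced") +
        pp$batch_C * (.data$batch == "C"),
      pinnings_received = ifelse(.data$treatment == "kinematic_reduced",
                                 0L, rpois(n(), exp(.data$lp))),
      lp_d = .data$lp +
        pp$delivered_shift_social * (.data$treatment == "social_reduced"),
      pinnings_delivered = ifelse(.data$treatment == "kinematic_reduced",
                                  0L, rpois(n(), exp(.data$lp_d)))
    ) |>
    select("rat_id", "litter_id", "treatment", "batch",
           "pinnings_delivered", "pinnings_received")
}

#' Simulate per-session USV counts
#'
#' One row per rat and tickling session. 50-kHz counts follow the Gaussian
#' mixed model of the analysis stage -- fixed treatment/batch effects, day
#' and order covariates, Normal rat and litter random intercepts and a
#' Normal residual -- rounded and floored at zero. 22-kHz counts follow a
#' log-link Poisson analogue with rat and litter random intercepts.
#'
#' @param design A [cohort_design()].
#' @param params A [generative_params()].
#' @param seed Integer seed.
#' @return A session tibble: `rat_id`, `litter_id`, `treatment`, `batch`,
#'   `day`, `order`, `n50`, `n22`.
#' @examples
#' sessions <- simulate_usv_counts(cohort_design(), seed = 2)
#' mean(sessions$n50)   # ~160 calls per session
#' @export
simulate_usv_counts <- function(design, params = generative_params(), seed = 1) {
  withr::local_seed(seed)
  rats <- design$rats
  g50 <- params$usv50
  g22 <- params$usv22
  rat_b50 <- setNames(rnorm(nrow(rats), 0, g50$sd_rat), rats$rat_id)
  rat_b22 <- setNames(rnorm(nrow(rats), 0, g22$sd_rat), rats$rat_id)
  litters <- unique(rats$litter_id)
  lit_b50 <- setNames(rnorm(length(litters), 0, g50$sd_litter), litters)
  lit_b22 <- setNames(rnorm(length(litters), 0, g22$sd_litter), litters)
  sessions <- rats |>
    mutate(day = map(.data$n_days, seq_len)) |>
    tidyr::unnest("day")
  lp50 <- with(sessions, g50$intercept +
    g50$social_reduced * (treatment == "social_reduced") +
    g50$kinematic_reduced * (treatment == "kinematic_reduced") +
    g50$day * day + g50$order * order +
    g50$batch_B * (batch == "B") + g50$batch_C * (batch == "C") +
    rat_b50[rat_id] + lit_b50[litter_id])
  lp22 <- with(sessions, g22$intercept + g22$day * day +
    g22$batch_B * (batch == "B") + g22$batch_C * (batch == "C") +
    rat_b22[rat_id] + lit_b22[litter_id])
  sessions |>
    mutate(
      n50 = pmax(0, round(lp50 + rnorm(n(), 0, g50$sd_resid))),
      n22 = rpois(n(), exp(lp22))
    ) |>
    select("rat_id", "litter_id", "treatment", "batch", "day", "order",
           "n50", "n22")
}

#' Build the alternating hover/tickle contact schedule
#'
#' The standardised play procedure alternates 15 s of hand hovering (no
#' contact) with 15 s of tickling; each tickle block is subdivided into a
#' dorsal (nape) and a ventral (belly) sub-period. Periods tile the session
#' without overlap; a trailing partial block is truncated at the session
#' end.
#'
#' @param session_duration_s Session length in seconds (>= 30; default the
#'   2-minute procedure).
#' @param hover_s,tickle_s Block lengths in seconds.
#' @param tickle_split Fraction of each tickle block scored as dorsal
#'   contact (the remainder is ventral).
#' @return A periods tibble: `period_type` (`none`/`dorsal`/`ventral`),
#'   `start_s`, `end_s`.
#' @examples
#' make_contact_schedule(120)  # 4 hover + 4 tickle blocks
#' @export
make_contact_schedule <- function(session_duration_s = 120, hover_s = 15,
                                  tickle_s = 15, tickle_split = 0.5) {
  if (session_duration_s < hover_s + tickle_s) {
    abort("session must fit at least one hover + tickle block")
  }
  out <- list()
  t <- 0
  while (t < session_duration_s) {
    h_end <- min(t + hover_s, session_duration_s)
    out[[length(out) + 1]] <- tibble(period_type = "none", start_s = t, end_s = h_end)
    t <- h_end
    if (t >= session_duration_s) break
    tk_end <- min(t + tickle_s, session_duration_s)
    d_end <- min(t + (tk_end - t) * tickle_split, tk_end)
    out[[length(out) + 1]] <- tibble(period_type = "dorsal", start_s = t, end_s = d_end)
    if (d_end < tk_end) {
      out[[length(out) + 1]] <- tibble(period_type = "ventral",
                                       start_s = d_end, end_s = tk_end)
    }
    t <- tk_end
  }
  bind_rows(out) |> filter(.data$end_s > .data$start_s)
}

#' Simulate per-contact-period emission rates
#'
#' Generates the rates table the contact-period model consumes directly
#' (bypassing audio synthesis): one row per rat, session and period type,
#' with Gaussian rates elevated during dorsal and ventral contact, rat and
#' litter random intercepts and a Normal residual, floored at zero.
#'
#' @param design A [cohort_design()]; by default only batch C is used, as in
#'   the study's rate analysis.
#' @param params A [generative_params()].
#' @param seed Integer seed.
#' @param batches Batches to include.
#' @param session_duration_s Session length used for the period durations.
#' @return A rates tibble: `rat_id`, `litter_id`, `treatment`, `batch`,
#'   `day`, `period_type`, `total_duration_s`, `rate_per_s`.
#' @export
simulate_period_rates <- function(design, params = generative_params(),
                                  seed = 1, batches = "C",
                                  session_duration_s = 120) {
  withr::local_seed(seed)
  g <- params$rates
  rats <- filter(design$rats, .data$batch %in% batches)
  rat_b <- setNames(rnorm(nrow(rats), 0, g$sd_rat), rats$rat_id)
  litters <- unique(rats$litter_id)
  lit_b <- setNames(rnorm(length(litters), 0, g$sd_litter), litters)
  sched <- make_contact_schedule(session_duration_s)
  durs <- sched |>
    group_by(.data$period_type) |>
    summarise(total_duration_s = sum(.data$end_s - .data$start_s), .groups = "drop")
  rows <- rats |>
    mutate(day = map(.data$n_days, seq_len)) |>
    tidyr::unnest("day") |>
    tidyr::expand_grid(period_type = durs$period_type) |>
    left_join(durs, by = "period_type") |>
    # hand-timed contact periods vary from session to session
    mutate(total_duration_s = pmax(5, .data$total_duration_s + rnorm(n(), 0, 2)))
  lp <- with(rows, g$intercept +
    g$social_reduced * (treatment == "social_reduced") +
    g$kinematic_reduced * (treatment == "kinematic_reduced") +
    g$ventral * (period_type == "ventral") +
    g$dorsal * (period_type == "dorsal") +
    rat_b[rat_id] + lit_b[litter_id])
  rows |>
    mutate(rate_per_s = pmax(0, lp + rnorm(n(), 0, g$sd_resid))) |>
    select("rat_id", "litter_id", "treatment", "batch", "day",
           "period_type", "total_duration_s", "rate_per_s")
}
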