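# The analysis stage: GLM/LM on play, mixed models on call counts, AICc
# ranking, variance-component repeatability, marginal means, Spearman.

new_usv_fit <- function(fit, label, family, method) {
  ll <- logLik(fit)
  structure(list(fit = fit, label = label, family = family, method = method,
                 loglik = as.numeric(ll), df = attr(ll, "df"),
                 n = stats::nobs(fit)),
            class = "usv_fit")
}

#' @export
print.usv_fit <- function(x, ...) {
  cat(sprintf("<usv_fit '%s': %s (%s), n = %d, logLik = %.2f, k = %d>\n",
              x$label, x$family, x$method, x$n, x$loglik, x$df))
  print(tidy(x), n = 20)
  invisible(x)
}

#' Tidy coefficient table of a fitted model
#'
#' @param x A `usv_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (where the fitting engine provides one).
#' @method tidy usv_fit
#' @export
tidy.usv_fit <- function(x, ...) {
  co <- stats::coef(summary(x$fit))
  stat_col <- intersect(c("t value", "z value"), colnames(co))[1]
  pcol <- grep("^Pr\\(", colnames(co))
  tibble(term = rownames(co),
         estimate = unname(co[, "Estimate"]),
         std.error = unname(co[, "Std. Error"]),
         statistic = if (!is.na(stat_col)) unname(co[, stat_col]) else NA_real_,
         p.value = if (length(pcol) == 1) unname(co[, pcol]) else NA_real_)
}

#' One-line fit summary
#'
#' @param x A `usv_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `k`, `logLik`, `AIC`, `AICc`,
#'   `method`, `family`.
#' @method glance usv_fit
#' @export
glance.usv_fit <- function(x, ...) {
  tibble(n = x$n, k = x$df, logLik = x$loglik,
         AIC = -2 * x$loglik + 2 * x$df, AICc = aicc(x),
         method = x$method, family = x$family)
}

#' Variance components of a mixed-model fit
#'
#' @param x A `usv_fit` wrapping an lme4 fit.
#' @return Tibble with `group` and `variance` (includes `Residual` for
#'   Gaussian fits).
#' @export
varcomp_tbl <- function(x) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  vc <- vc[is.na(vc$var2), ]
  tibble(group = vc$grp, variance = vc$vcov)
}

check_columns <- function(tbl, cols, what) {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
}

prep_factors <- function(tbl) {
  if ("treatment" %in% names(tbl)) {
    lev <- intersect(c("control", "kinematic_reduced", "social_reduced"),
                     unique(tbl$treatment))
    tbl$treatment <- factor(tbl$treatment, levels = lev)
  }
  if ("batch" %in% names(tbl)) tbl$batch <- factor(tbl$batch)
  if ("period_type" %in% names(tbl)) {
    lev <- intersect(c("none", "ventral", "dorsal"), unique(tbl$period_type))
    tbl$period_type <- factor(tbl$period_type, levels = lev)
  }
  tbl
}

#' Poisson GLM for received pinnings
#'
#' Log-link Poisson regression of received pinnings on treatment and batch.
#' Rats with kinematically reduced play are excluded before fitting: that
#' group received no pinnings at all (the arena prevented pinning), and the
#' all-zero cell would otherwise inflate zeros. Reference levels are
#' `control` and batch `A`.
#'
#' @param play Play tibble (`pinnings_received`, `treatment`, `batch`).
#' @return A `usv_fit`.
#' @export
fit_pinning_glm <- function(play) {
  check_columns(play, c("pinnings_received", "treatment", "batch"), "play table")
  d <- play |>
    filter(.data$treatment != "kinematic_reduced") |>
    prep_factors()
  d$treatment <- droplevels(d$treatment)
  d$batch <- droplevels(d$batch)
  for (v in c("treatment", "batch")) {
    if (length(unique(d[[v]])) < 2) abort(sprintf("degenerate design: '%s' has one level", v))
  }
  fit <- stats::glm(pinnings_received ~ treatment + batch, data = d,
                    family = stats::poisson())
  new_usv_fit(fit, "pinnings_received ~ treatment + batch", "poisson", "ML")
}

#' Linear model for the play asymmetry score
#'
#' Ordinary least squares on the asymmetry score with treatment and batch
#' fixed factors. Rows with undefined scores (no pinnings in either
#' direction) are dropped with a message.
#'
#' @param play Play tibble; the `asymmetry` column is computed via
#'   [add_asymmetry()] if absent.
#' @return A `usv_fit`.
#' @export
fit_asymmetry_lm <- function(play) {
  if (!"asymmetry" %in% names(play)) play <- add_asymmetry(play)
  d <- play |> filter(!is.na(.data$asymmetry)) |> prep_factors()
  d$treatment <- droplevels(d$treatment)
  d$batch <- droplevels(d$batch)
  fit <- stats::lm(asymmetry ~ treatment + batch, data = d)
  new_usv_fit(fit, "asymmetry ~ treatment + batch", "gaussian", "OLS")
}

#' Gaussian mixed model for per-session 50-kHz counts
#'
#' Linear mixed model with treatment and batch fixed factors, day and order
#' covariates and rat and litter random intercepts (the full model of the
#' analysis). `REML` is used for reported coefficient tables; `ML` for
#' fixed-effect structure comparisons via AICc. A singular fit is reported
#' via a message, never silently dropped.
#'
#' @param sessions Session tibble (`n50`, `treatment`, `batch`, `day`,
#'   `order`, `rat_id`, `litter_id`).
#' @param formula Model formula; the default is the full model.
#' @param method `"REML"` or `"ML"`.
#' @return A `usv_fit`.
#' @export
fit_usv_lmm <- function(sessions,
                        formula = n50 ~ treatment + batch + day + order +
                          (1 | rat_id) + (1 | litter_id),
                        method = c("REML", "ML")) {
  method <- match.arg(method)
  vars <- all.vars(formula)
  check_columns(sessions, vars, "session table")
  d <- prep_factors(sessions)
  for (g in intersect(c("rat_id", "litter_id"), vars)) {
    if (length(unique(d[[g]])) < 2) {
      abort(sprintf("random term '%s' needs >= 2 levels", g))
    }
  }
  fit <- lmerTest::lmer(formula, data = d, REML = method == "REML")
  if (lme4::isSingular(fit)) message("mixed-model fit is singular (a variance component is ~0)")
  new_usv_fit(fit, deparse1(formula), "gaussian", method)
}

#' Poisson mixed model for per-session 22-kHz counts
#'
#' Log-link Poisson GLMM; the default fixed structure is the best model of
#' the 22-kHz analysis (day + batch) with rat and litter random intercepts.
#'
#' @param sessions Session tibble.
#' @param formula Model formula.
#' @return A `usv_fit`.
#' @export
fit_usv22_glmm <- function(sessions,
                           formula = n22 ~ day + batch +
                             (1 | rat_id) + (1 | litter_id)) {
  check_columns(sessions, all.vars(formula), "session table")
  d <- prep_factors(sessions)
  fit <- lme4::glmer(formula, data = d, family = stats::poisson())
  if (lme4::isSingular(fit)) message("mixed-model fit is singular (a variance component is ~0)")
  new_usv_fit(fit, deparse1(formula), "poisson", "ML")
}

#' Gaussian mixed model for contact-period emission rates
#'
#' Linear mixed model on the per-period emission rate. The default fixed
#' structure is the best model of the rate analysis (contact period +
#' treatment) with rat and litter random intercepts; candidate structures
#' with the period-by-treatment interaction, period duration or day can be
#' compared via [aicc_rank()].
#'
#' @param rates Rates tibble (`rate_per_s`, `period_type`, `treatment`,
#'   `rat_id`, `litter_id`, optionally `total_duration_s`, `day`).
#' @param formula Model formula.
#' @param method `"REML"` or `"ML"`.
#' @return A `usv_fit`.
#' @export
contact_rate_model <- function(rates,
                               formula = rate_per_s ~ period_type + treatment +
                                 (1 | rat_id) + (1 | litter_id),
                               method = c("REML", "ML")) {
  method <- match.arg(method)
  check_columns(rates, all.vars(formula), "rates table")
  d <- prep_factors(rates)
  fit <- lmerTest::lmer(formula, data = d, REML = method == "REML")
  if (lme4::isSingular(fit)) message("mixed-model fit is singular (a variance component is ~0)")
  new_usv_fit(fit, deparse1(formula), "gaussian", method)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`, with `k` the number of
#' estimated parameters: fixed effects plus variance components (including
#' the Gaussian residual), i.e. the fitting engine's log-likelihood degrees
#' of freedom. Errors when `n <= k + 1`.
#'
#' @param fit A `usv_fit`, or anything with a [stats::logLik()] method.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  if (inherits(fit, "usv_fit")) {
    ll <- fit$loglik; k <- fit$df; n <- fit$n
  } else {
    l <- logLik(fit); ll <- as.numeric(l); k <- attr(l, "df"); n <- stats::nobs(fit)
  }
  if (n <= k + 1) abort("AICc undefined: n <= k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank candidate models by AICc
#'
#' Candidates must be fitted to identical data by maximum likelihood (use
#' `method = "ML"` for mixed models when comparing fixed-effect
#' structures).
#'
#' @param fits Named list of `usv_fit` objects.
#' @return A tibble of class `usv_model_comparison`: `model`, `k`, `AICc`,
#'   `delta_AICc`, ordered by AICc.
#' @export
aicc_rank <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  ns <- map_dbl(fits, function(f) f$n)
  if (length(unique(ns)) > 1) abort("candidates must be fitted to identical data")
  tb <- tibble(model = names(fits),
               k = unname(map_dbl(fits, function(f) f$df)),
               AICc = unname(map_dbl(fits, aicc))) |>
    arrange(.data$AICc) |>
    mutate(delta_AICc = .data$AICc - min(.data$AICc))
  class(tb) <- c("usv_model_comparison", class(tb))
  tb
}

#' Variance-component repeatability (intra-class correlation)
#'
#' Point estimate `R = sigma^2_term / (sum of all random-intercept variances
#' + residual variance)` from a Gaussian mixed model, with a seeded
#' parametric-bootstrap percentile confidence interval (simulate from the
#' fitted model, refit, recompute R). For log-link Poisson mixed models the
#' ratio is computed on the latent scale with the distribution-specific
#' variance `ln(1 + 1/lambda)` (lambda the mean fitted rate) in place of the
#' residual variance.
#'
#' @param fit A `usv_fit` from [fit_usv_lmm()], [contact_rate_model()] or
#'   [fit_usv22_glmm()].
#' @param term Grouping factor name, e.g. `"rat_id"`.
#' @param n_boot Parametric bootstrap draws (0 skips the interval).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level.
#' @return A list of class `usv_repeatability`: `term`, `R`, `ci`
#'   (or `NULL`), `boot` (vector of bootstrap R values), `n_boot`.
#' @export
repeatability <- function(fit, term = "rat_id", n_boot = 1000, seed = 1,
                          level = 0.95) {
  point_r <- function(model) {
    vc <- as.data.frame(lme4::VarCorr(model))
    vc <- vc[is.na(vc$var2), ]
    v <- setNames(vc$vcov, vc$grp)
    if (!term %in% names(v)) abort(sprintf("'%s' is not a random intercept of the fit", term))
    denom_extra <- if ("Residual" %in% names(v)) 0 else {
      lambda <- mean(stats::fitted(model))   # latent-scale Poisson variance
      log(1 + 1 / lambda)
    }
    tot <- sum(v) + denom_extra
    if (tot == 0) abort("all variance components are zero: R undefined")
    unname(v[term] / tot)
  }
  R <- point_r(fit$fit)
  boot <- numeric(0)
  ci <- NULL
  if (n_boot > 0) {
    withr::local_seed(seed)
    sims <- stats::simulate(fit$fit, nsim = n_boot)
    boot <- vapply(seq_len(n_boot), function(i) {
      tryCatch(point_r(suppressMessages(suppressWarnings(
        lme4::refit(fit$fit, sims[[i]])))),
        error = function(e) NA_real_)
    }, numeric(1))
    boot <- boot[!is.na(boot)]
    a <- (1 - level) / 2
    ci <- unname(stats::quantile(boot, c(a, 1 - a)))
  }
  structure(list(term = term, R = R, ci = ci, boot = boot,
                 n_boot = n_boot, level = level),
            class = "usv_repeatability")
}

#' @export
print.usv_repeatability <- function(x, ...) {
  if (is.null(x$ci)) {
    cat(sprintf("<repeatability %s: R = %.3f (no bootstrap)>\n", x$term, x$R))
  } else {
    cat(sprintf("<repeatability %s: R = %.3f [%.3f, %.3f] (%d boot)>\n",
                x$term, x$R, x$ci[1], x$ci[2], length(x$boot)))
  }
  invisible(x)
}

#' @method tidy usv_repeatability
#' @export
tidy.usv_repeatability <- function(x, ...) {
  tibble(term = x$term, R = x$R,
         conf.low = if (is.null(x$ci)) NA_real_ else x$ci[1],
         conf.high = if (is.null(x$ci)) NA_real_ else x$ci[2],
         n_boot = length(x$boot))
}

#' Histogram of bootstrap repeatability draws
#'
#' @param object A `usv_repeatability`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot usv_repeatability
#' @export
autoplot.usv_repeatability <- function(object, ...) {
  ggplot2::ggplot(tibble(R = object$boot), ggplot2::aes(.data$R)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$R, colour = "red") +
    ggplot2::labs(x = sprintf("bootstrap repeatability (%s)", object$term),
                  y = "draws") +
    ggplot2::theme_minimal()
}

#' Estimated marginal means and pairwise contrasts
#'
#' Marginal means of a fitted model for one factor, averaged with equal
#' weights over the other factor levels with covariates at their observed
#' means, back-transformed to the response scale for log-link models;
#' pairwise contrasts are Tukey-adjusted.
#'
#' @param fit A `usv_fit`.
#' @param factor Name of a fixed factor in the model.
#' @return A list with tibbles `means` (`level`, `mean`, `conf.low`,
#'   `conf.high`) and `contrasts` (`contrast`, `estimate`, `p.value`).
#' @export
marginal_means <- function(fit, factor = "treatment") {
  if (!factor %in% all.vars(stats::formula(fit$fit))) {
    abort(sprintf("factor '%s' is not a term of the model", factor))
  }
  em <- emmeans::emmeans(fit$fit, specs = factor, type = "response")
  ms <- as.data.frame(em)
  names(ms)[1] <- "level"
  mean_col <- intersect(c("rate", "response", "emmean"), names(ms))[1]
  lo_col <- intersect(c("asymp.LCL", "lower.CL"), names(ms))[1]
  hi_col <- intersect(c("asymp.UCL", "upper.CL"), names(ms))[1]
  means <- tibble(level = as.character(ms$level),
                  mean = ms[[mean_col]],
                  conf.low = ms[[lo_col]], conf.high = ms[[hi_col]])
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
  contrasts <- tibble(contrast = as.character(ct$contrast),
                      estimate = ct$estimate, p.value = ct$p.value)
  list(means = means, contrasts = contrasts)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, plus the test p-value
#' (normal approximation when ties are present).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row tibble: `rho`, `p.value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) abort("correlation undefined for constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}
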