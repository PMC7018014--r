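# Observer-agreement models: rating repeatability and the experience GLMM.
#
# Both are binomial mixed models with a logit link, fitted by Laplace
# maximum likelihood (lme4::glmer). Repeatability is computed on the latent
# (link) scale, where the logistic residual variance is pi^2/3. In the
# experience model the same-individual class is coded 1 -- the class with
# the larger error -- so the intercept row predicts FPR and the
# similarity-class contrast lifts it to FNR.

LOGISTIC_RESIDUAL_VAR <- pi^2 / 3

rating_to_binary <- function(rating) {
  if (is.numeric(rating)) {
    stopifnot(all(rating %in% 0:1))
    return(as.integer(rating))
  }
  stopifnot(all(rating %in% c("S", "D")))
  as.integer(rating == "S")
}

# capture convergence/singularity messages without losing the fit
quiet_glmer <- function(formula, data, ...) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(formula, data = data, family = stats::binomial(), ...),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(fit = fit, messages = msgs)
}

re_variances <- function(fit) {
  vc <- lme4::VarCorr(fit)
  vapply(vc, function(v) v[1, 1], numeric(1))
}

#' Assemble rating records for the observer models
#'
#' Joins classified outcomes with observer profiles and adds the model
#' codings: `experience` (0 = photogrammetry-experienced,
#' 1 = inexperienced) and `similarity_class` (1 = same individual, the
#' class whose errors are false negatives; 0 = different individuals).
#'
#' @param outcomes A [classify_outcomes()] tibble.
#' @param observers A [sim_observers()]-shaped tibble (needs
#'   `observer_id`, `experience_photogrammetry`).
#' @return A records tibble, one row per (observer, comparison).
#' @export
build_rating_records <- function(outcomes, observers) {
  left_join(outcomes,
            observers[, c("observer_id", "experience_photogrammetry")],
            by = "observer_id") |>
    mutate(experience = as.integer(!.data$experience_photogrammetry),
           similarity_class = as.integer(.data$truth == "same"))
}

#' Repeatability of ratings from a binomial random-effects model
#'
#' Fits `rating ~ 1 + (1 | comparison_id)` with a logit link and computes
#' the latent-scale repeatability
#' `R = v_comparison / (v_comparison + pi^2/3)`: the share of latent
#' variance attributable to comparison identity. A variant whose
#' denominator also includes an observer variance component (from a model
#' with both random effects) is reported alongside. The standard error
#' comes from a parametric bootstrap: responses are simulated from the
#' fitted model, the model is refitted, and the SD of the replicate `R`
#' values is taken.
#'
#' @param records Tibble with `comparison_id`, `observer_id` and a
#'   `rating` column (`"S"`/`"D"` or 0/1).
#' @param n_bootstrap Parametric bootstrap replicates for the SE.
#' @param seed Integer seed (bootstrap determinism).
#' @return An object of class `repeatability_fit` with elements `R`, `se`,
#'   `R_with_observer`, `var_comparison`, `var_observer`, `boot`
#'   (replicate values), `model`, `messages`. [glance()] returns the
#'   one-row summary.
#' @export
fit_rating_repeatability <- function(records, n_bootstrap = 1000, seed = 1) {
  stopifnot(length(unique(records$observer_id)) >= 2,
            length(unique(records$comparison_id)) >= 2)
  dat <- tibble(
    y = rating_to_binary(records$rating),
    comparison_id = factor(records$comparison_id),
    observer_id = factor(records$observer_id)
  )
  primary <- quiet_glmer(y ~ 1 + (1 | comparison_id), dat)
  v_comp <- re_variances(primary$fit)[["comparison_id"]]
  r_point <- v_comp / (v_comp + LOGISTIC_RESIDUAL_VAR)

  both <- quiet_glmer(y ~ 1 + (1 | comparison_id) + (1 | observer_id), dat)
  vb <- re_variances(both$fit)
  r_with_obs <- vb[["comparison_id"]] /
    (vb[["comparison_id"]] + vb[["observer_id"]] + LOGISTIC_RESIDUAL_VAR)

  boot <- numeric(0)
  se <- NA_real_
  if (n_bootstrap > 0) {
    sims <- stats::simulate(primary$fit, nsim = n_bootstrap,
                            seed = child_seed(seed, "repeatability"))
    boot <- vapply(sims, function(y_new) {
      refit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::refit(primary$fit, newresp = y_new))),
        error = function(e) NULL)
      if (is.null(refit)) return(NA_real_)
      v <- re_variances(refit)[["comparison_id"]]
      v / (v + LOGISTIC_RESIDUAL_VAR)
    }, numeric(1))
    n_failed <- sum(is.na(boot))
    if (n_failed > 0) {
      message(n_failed, " bootstrap refit(s) failed and were dropped")
    }
    se <- sd(boot, na.rm = TRUE)
  }
  structure(list(R = r_point, se = se, R_with_observer = r_with_obs,
                 var_comparison = v_comp,
                 var_observer = vb[["observer_id"]],
                 boot = boot, n_bootstrap = n_bootstrap,
                 model = primary$fit,
                 messages = c(primary$messages, both$messages)),
            class = "repeatability_fit")
}

#' @export
print.repeatability_fit <- function(x, ...) {
  cat(sprintf("<repeatability_fit> R = %.3f (SE %.3f), latent scale\n",
              x$R, x$se))
  cat(sprintf("  denominator incl. observer variance: R = %.3f\n",
              x$R_with_observer))
  if (length(x$messages)) {
    cat("  fit notes:", paste(unique(x$messages), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::glance
glance.repeatability_fit <- function(x, ...) {
  tibble(R = x$R, se = x$se, R_with_observer = x$R_with_observer,
         var_comparison = x$var_comparison, var_observer = x$var_observer,
         n_bootstrap = x$n_bootstrap)
}

#' Fit the observer-experience GLMM
#'
#' Models the binary outcome (0 = rating correct, 1 = incorrect) with
#' fixed effects for photogrammetric experience, similarity class and
#' their interaction, and random intercepts for observer and comparison ID
#' (nested within trial via globally unique comparison ids; an optional
#' trial intercept mirrors the nesting explicitly). Following the two-step
#' strategy used when interactions hinder convergence, the main-effects
#' model is fitted first and retained as a diagnostic; the interaction
#' model is the final model.
#'
#' @param records Tibble from [build_rating_records()] (columns `outcome`,
#'   `experience`, `similarity_class`, `observer_id`, `comparison_id`,
#'   `trial_id`).
#' @param include_trial Include a `(1 | trial_id)` intercept.
#' @param nAGQ Integration accuracy passed to [lme4::glmer()]: 1 (Laplace,
#'   default) or 0 (faster, less accurate; useful for bootstrap refits).
#' @return An object of class `experience_fit`: `fit` (final glmer fit),
#'   `fit_main` (main-effects diagnostic fit), `messages`, `data`.
#'   [tidy()] gives the coefficient table on the logit scale, [glance()]
#'   the variance components.
#' @export
fit_experience_model <- function(records, include_trial = TRUE,
                                 nAGQ = 1) {
  need <- c("outcome", "experience", "similarity_class", "observer_id",
            "comparison_id")
  stopifnot(all(need %in% names(records)))
  if (length(unique(records$experience)) < 2 ||
      length(unique(records$similarity_class)) < 2) {
    stop("both experience groups and both similarity classes are required")
  }
  dat <- tibble(
    outcome = as.integer(records$outcome),
    experience = as.numeric(records$experience),
    similarity_class = as.numeric(records$similarity_class),
    observer_id = factor(records$observer_id),
    comparison_id = factor(records$comparison_id),
    trial_id = factor(if ("trial_id" %in% names(records))
      records$trial_id else "trial1")
  )
  re <- "(1 | observer_id) + (1 | comparison_id)"
  if (include_trial && nlevels(dat$trial_id) > 1) {
    re <- paste(re, "+ (1 | trial_id)")
  }
  f_main <- stats::as.formula(
    paste("outcome ~ experience + similarity_class +", re))
  f_int <- stats::as.formula(
    paste("outcome ~ experience * similarity_class +", re))
  main <- quiet_glmer(f_main, dat, nAGQ = nAGQ)
  final <- tryCatch(quiet_glmer(f_int, dat, nAGQ = nAGQ),
                    error = function(e) {
    stop("interaction model failed to converge: ", conditionMessage(e),
         "\nmain-effects coefficients: ",
         paste(sprintf("%.3f", lme4::fixef(main$fit)), collapse = ", "))
  })
  structure(list(fit = final$fit, fit_main = main$fit,
                 messages = c(main$messages, final$messages), data = dat),
            class = "experience_fit")
}

#' @export
print.experience_fit <- function(x, ...) {
  cat("<experience_fit> outcome ~ experience * similarity_class + REs\n")
  print(tidy(x), digits = 3)
  if (length(x$messages)) {
    cat("fit notes:", paste(unique(x$messages), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.experience_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, "Estimate"],
         std.error = cf[, "Std. Error"], statistic = cf[, "z value"],
         p.value = cf[, "Pr(>|z|)"])
}

#' @exportS3Method generics::glance
glance.experience_fit <- function(x, ...) {
  v <- re_variances(x$fit)
  tibble(nobs = stats::nobs(x$fit), logLik = as.numeric(stats::logLik(x$fit)),
         AIC = stats::AIC(x$fit),
         var_observer = v[["observer_id"]],
         var_comparison = v[["comparison_id"]],
         var_trial = if ("trial_id" %in% names(v)) v[["trial_id"]]
                     else NA_real_)
}

# population-averaged inverse-logit: E[plogis(eta + u)], u ~ N(0, v)
marginal_rate <- function(eta, v) {
  if (v <= 0) return(plogis(eta))
  s <- sqrt(v)
  integrate(function(z) plogis(eta + s * z) * dnorm(z),
            lower = -8, upper = 8, rel.tol = 1e-9)$value
}

#' Predicted error rates per experience group
#'
#' Inverse-logit predictions from the fixed effects of an
#' [fit_experience_model()] fit: FPR at similarity class 0 (different
#' individuals), FNR at class 1 (same individual). `conditional` rates are
#' `plogis` of the fixed-effect combination (a random-effect level at
#' zero); `marginal` rates (default) average the inverse logit over the
#' fitted random-effect distribution, the population-averaged rate an
#' observer group realises over many comparisons.
#'
#' @param fit An `experience_fit`.
#' @param type `"marginal"` or `"conditional"`.
#' @return A tibble with `experience_group`, `fpr`, `fnr`.
#' @export
predict_group_rates <- function(fit, type = c("marginal", "conditional")) {
  type <- match.arg(type)
  b <- lme4::fixef(fit$fit)
  v <- if (type == "marginal") sum(re_variances(fit$fit)) else 0
  eta <- function(exp_, sim) {
    unname(b["(Intercept)"] + b["experience"] * exp_ +
             b["similarity_class"] * sim +
             b["experience:similarity_class"] * exp_ * sim)
  }
  tibble(
    experience_group = c("experienced", "inexperienced"),
    fpr = c(marginal_rate(eta(0, 0), v), marginal_rate(eta(1, 0), v)),
    fnr = c(marginal_rate(eta(0, 1), v), marginal_rate(eta(1, 1), v))
  )
}

#' Group rate table with Euclidean error rates
#'
#' The per-group FPR/FNR predictions of the experience model plus the
#' combined error rate `ER = sqrt(FPR^2 + FNR^2)`; optionally with
#' parametric-bootstrap standard errors and 95% percentile intervals
#' (responses simulated from the fitted model, model refitted, rates
#' recomputed).
#'
#' @param fit An `experience_fit`.
#' @param n_bootstrap Bootstrap replicates (0 = point estimates only).
#' @param seed Integer seed.
#' @param type Passed to [predict_group_rates()].
#' @return A tibble with `experience_group`, `fpr`, `fnr`, `error_rate`
#'   and, when bootstrapped, `*_se`, `*_lower`, `*_upper` columns.
#' @export
group_rate_table <- function(fit, n_bootstrap = 0, seed = 1,
                             type = "marginal") {
  point <- predict_group_rates(fit, type) |>
    mutate(error_rate = error_rate(.data$fpr, .data$fnr))
  if (n_bootstrap == 0) return(point)
  sims <- stats::simulate(fit$fit, nsim = n_bootstrap,
                          seed = child_seed(seed, "group_rates"))
  draws <- map(sims, function(y_new) {
    refit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::refit(fit$fit, newresp = y_new))),
      error = function(e) NULL)
    if (is.null(refit)) return(NULL)
    fit2 <- fit; fit2$fit <- refit
    predict_group_rates(fit2, type) |>
      mutate(error_rate = error_rate(.data$fpr, .data$fnr))
  })
  draws <- draws[!vapply(draws, is.null, logical(1))]
  if (length(draws) < n_bootstrap) {
    message(n_bootstrap - length(draws),
            " bootstrap refit(s) failed and were dropped")
  }
  boot <- bind_rows(draws)
  summ <- boot |>
    group_by(.data$experience_group) |>
    summarise(dplyr::across(c("fpr", "fnr", "error_rate"),
                            list(se = sd,
                                 lower = ~ quantile(.x, 0.025, names = FALSE),
                                 upper = ~ quantile(.x, 0.975,
                                                    names = FALSE))),
              .groups = "drop")
  left_join(point, summ, by = "experience_group")
}

#' Simulate a rating study from the experience GLMM
#'
#' Generates records under the model
#' `logit P(outcome = 1) = b0 + b1 experience + b2 similarity_class +
#' b3 experience x similarity_class + u_observer + u_comparison`, with the
#' published coefficient values as defaults, over a trial design built by
#' the synthetic-data generators (or one supplied). Ratings are derived
#' from outcomes (an incorrect rating of a same-pair is `"D"`, of a
#' different-pair `"S"`).
#'
#' @param coefficients Named vector `intercept`, `experience`,
#'   `similarity`, `interaction` on the logit scale.
#' @param sd_observer,sd_comparison,sd_trial Random-intercept SDs on the
#'   logit scale. The defaults give a total latent SD near 2.1, the value
#'   at which the default coefficients imply group error rates matching
#'   the fitted observer-study rates (FPR 0.003/0.009).
#' @param observers Profiles tibble ([sim_observers()] default: 4
#'   photogrammetry-experienced, 6 inexperienced).
#' @param trials Trial design tibble, or `NULL` for the default design (15
#'   individuals, 43 sets, 5 trials of 15 sets).
#' @param seed Integer seed.
#' @return A records tibble ready for [fit_experience_model()] /
#'   [fit_rating_repeatability()].
#' @export
sim_rating_study <- function(coefficients = c(intercept = -7.938,
                                              experience = 1.153,
                                              similarity = 5.486,
                                              interaction = 2.623),
                             sd_observer = 0.5, sd_comparison = 2.0,
                             sd_trial = 0, observers = sim_observers(),
                             trials = NULL, seed = 1) {
  if (is.null(trials)) {
    inds <- tibble(individual_id = sprintf("bear%02d", 1:15))
    sets <- tibble(
      individual_id = rep(inds$individual_id, c(rep(3, 14), 1))) |>
      group_by(.data$individual_id) |>
      mutate(set_id = sprintf("%s_s%d", .data$individual_id,
                              row_number())) |>
      ungroup()
    trials <- sim_trials(sets, n_trials = 5, seed = child_seed(seed, "design"))
  }
  comparisons <- build_comparison_table(trials)
  with_seed(child_seed(seed, "glmm_sim"), {
    u_obs <- setNames(rnorm(nrow(observers), 0, sd_observer),
                      observers$observer_id)
    cmp_ids <- comparisons$comparison_id
    u_cmp <- setNames(rnorm(length(cmp_ids), 0, sd_comparison), cmp_ids)
    trial_ids <- unique(comparisons$trial_id)
    u_trial <- setNames(rnorm(length(trial_ids), 0, sd_trial), trial_ids)
    grid <- tidyr::crossing(observer_id = observers$observer_id,
                            comparison_id = cmp_ids) |>
      left_join(comparisons, by = "comparison_id") |>
      left_join(observers[, c("observer_id", "experience_photogrammetry")],
                by = "observer_id") |>
      mutate(
        experience = as.integer(!.data$experience_photogrammetry),
        similarity_class = as.integer(.data$truth == "same"),
        eta = coefficients[["intercept"]] +
          coefficients[["experience"]] * .data$experience +
          coefficients[["similarity"]] * .data$similarity_class +
          coefficients[["interaction"]] * .data$experience *
            .data$similarity_class +
          u_obs[.data$observer_id] + u_cmp[.data$comparison_id] +
          u_trial[.data$trial_id],
        outcome = rbinom(n(), 1, plogis(.data$eta)),
        rating = ifelse(.data$outcome == 1,
                        ifelse(.data$truth == "same", "D", "S"),
                        ifelse(.data$truth == "same", "S", "D")),
        cell = case_when(
          .data$truth == "same" & .data$rating == "S" ~ "TP",
          .data$truth == "same" & .data$rating == "D" ~ "FN",
          .data$truth == "different" & .data$rating == "D" ~ "TN",
          TRUE ~ "FP")
      ) |>
      select("observer_id", "trial_id", "comparison_id", "set_a", "set_b",
             "truth", "similarity_class", "experience", "rating", "cell",
             "outcome")
    grid
  })
}
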