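# Random-process baseline for the rating experiment.
#
# For each trial the truth matrix (all sets rated against each other) is
# compared cell-by-cell with a copy of itself whose set order has been
# randomized; the agreement cells (TP/TN/FP/FN) yield one FPR/FNR draw per
# replicate. Under this null E[FPR] = s/N and E[FNR] = 1 - s/N, where s is
# the number of same-pairs and N the number of pairs, so
# E[FPR] + E[FNR] = 1 exactly.

#' Truth matrix of a trial
#'
#' Symmetric logical matrix over the trial's sets; entry `TRUE` when the
#' two sets portray the same individual. The diagonal is excluded from all
#' downstream scoring.
#'
#' @param trial Tibble with `set_id` and `individual_id` for one trial.
#' @return A k x k logical matrix with set ids as dimnames.
#' @export
truth_matrix <- function(trial) {
  stopifnot(!anyDuplicated(trial$set_id))
  m <- outer(trial$individual_id, trial$individual_id, `==`)
  diag(m) <- NA
  dimnames(m) <- list(trial$set_id, trial$set_id)
  m
}

#' Score a rated matrix against a truth matrix
#'
#' Cell-by-cell comparison over the upper triangle: truth-same cells rated
#' same are TP, rated different FN; truth-different cells rated same are
#' FP, rated different TN.
#'
#' @param truth,rated k x k logical matrices (`TRUE` = same).
#' @return A one-row tibble with `tp`, `tn`, `fp`, `fn`, `fpr`, `fnr`
#'   (rates `NA` when the class is absent).
#' @export
score_against_truth <- function(truth, rated) {
  stopifnot(all(dim(truth) == dim(rated)))
  ut <- upper.tri(truth)
  t_same <- truth[ut]; r_same <- rated[ut]
  tp <- sum(t_same & r_same); fn <- sum(t_same & !r_same)
  fp <- sum(!t_same & r_same); tn <- sum(!t_same & !r_same)
  tibble(tp = tp, tn = tn, fp = fp, fn = fn,
         fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
         fnr = if (tp + fn > 0) fn / (tp + fn) else NA_real_)
}

#' Simulate the permutation null of the rating experiment
#'
#' For each trial and replicate a uniform permutation of the set labels is
#' drawn; the permuted truth matrix plays the role of the random rater and
#' is scored against the unpermuted truth. Means are computed per rate and
#' 95% intervals from the 0.025/0.975 percentiles of the replicate draws
#' pooled across trials.
#'
#' @param trials Tibble with `trial_id`, `set_id`, `individual_id`.
#' @param n Replicates per trial.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param mode `"permute_labels"` (default: one permutation relabels rows
#'   and columns jointly) or `"shuffle_cells"` (the upper-triangle cells
#'   are shuffled independently); both have identical marginal
#'   expectations.
#' @return An object of class `null_summary`; [glance()] gives the pooled
#'   means and intervals, [tidy()] the per-trial means. Trials whose FNR is
#'   undefined (no same-pair) are excluded from the FNR summary with a
#'   recorded count.
#' @export
simulate_null <- function(trials, n = 1000, seed = 1,
                          mode = c("permute_labels", "shuffle_cells")) {
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  trial_ids <- unique(trials$trial_id)
  fpr_draws <- list(); fnr_draws <- list()
  per_trial <- list()
  n_excluded <- 0L
  for (tid in trial_ids) {
    tr <- trials[trials$trial_id == tid, ]
    m <- truth_matrix(tr)
    k <- nrow(m)
    ut <- upper.tri(m)
    rates <- with_seed(child_seed(seed, "null", tid), {
      t(vapply(seq_len(n), function(r) {
        rated <- m
        if (mode == "permute_labels") {
          p <- sample(k)
          rated <- m[p, p]
        } else {
          rated[ut] <- sample(m[ut]) # scoring reads the upper triangle only
        }
        s <- score_against_truth(m, rated)
        c(s$fpr, s$fnr)
      }, numeric(2)))
    })
    if (all(is.na(rates[, 2]))) {
      n_excluded <- n_excluded + 1L
      message("trial ", tid, " has no same-pair; FNR undefined, excluded")
    }
    fpr_draws[[tid]] <- rates[, 1]; fnr_draws[[tid]] <- rates[, 2]
    per_trial[[tid]] <- tibble(
      trial_id = tid, n_sets = k,
      n_same_pairs = sum(m[ut]),
      mean_fpr = mean(rates[, 1], na.rm = TRUE),
      mean_fnr = mean(rates[, 2], na.rm = TRUE))
  }
  fpr_all <- unlist(fpr_draws); fnr_all <- unlist(fnr_draws)
  structure(list(
    per_trial = bind_rows(per_trial),
    mean_fpr = mean(fpr_all, na.rm = TRUE),
    mean_fnr = mean(fnr_all, na.rm = TRUE),
    ci_fpr = quantile(fpr_all, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
    ci_fnr = quantile(fnr_all, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
    n_simulations = n, mode = mode, n_trials_excluded_fnr = n_excluded
  ), class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("<null_summary> %d replicates/trial x %d trials (%s)\n",
              x$n_simulations, nrow(x$per_trial), x$mode))
  cat(sprintf("  expected FPR %.3f (95%% CI %.3f-%.3f)\n",
              x$mean_fpr, x$ci_fpr[1], x$ci_fpr[2]))
  cat(sprintf("  expected FNR %.3f (95%% CI %.3f-%.3f)\n",
              x$mean_fnr, x$ci_fnr[1], x$ci_fnr[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.null_summary <- function(x, ...) x$per_trial

#' @exportS3Method generics::glance
glance.null_summary <- function(x, ...) {
  tibble(mean_fpr = x$mean_fpr, fpr_lower = x$ci_fpr[1],
         fpr_upper = x$ci_fpr[2], mean_fnr = x$mean_fnr,
         fnr_lower = x$ci_fnr[1], fnr_upper = x$ci_fnr[2],
         n_simulations = x$n_simulations,
         n_trials = nrow(x$per_trial))
}

#' Position observer error rates against the permutation null
#'
#' Reports, for each observer and rate, whether the observed value falls
#' below, inside, or above the null's 95% interval (closed interval:
#' a value on the boundary is inside). Undefined rates are reported as
#' `"not assessable"`.
#'
#' @param observer_rates Tibble with `observer_id`, `fpr`, `fnr`.
#' @param null A [simulate_null()] result.
#' @return A long tibble with `observer_id`, `metric`, `rate`,
#'   `null_lower`, `null_upper`, `position`.
#' @export
compare_to_null <- function(observer_rates, null) {
  stopifnot(inherits(null, "null_summary"))
  observer_rates |>
    tidyr::pivot_longer(c("fpr", "fnr"), names_to = "metric",
                        values_to = "rate") |>
    mutate(
      null_lower = ifelse(.data$metric == "fpr", null$ci_fpr[1],
                          null$ci_fnr[1]),
      null_upper = ifelse(.data$metric == "fpr", null$ci_fpr[2],
                          null$ci_fnr[2]),
      position = case_when(
        is.na(.data$rate) ~ "not assessable",
        .data$rate < .data$null_lower ~ "below",
        .data$rate > .data$null_upper ~ "above",
        TRUE ~ "inside")
    )
}
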