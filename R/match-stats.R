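# Confusion bookkeeping over pairwise set comparisons.
#
# Truth-same pairs are either recognised (true positive) or misrated as
# different (false negative); truth-different pairs are either recognised
# (true negative) or misrated as the same (false positive). Rates are
# pooled across all cells before division:
#   FNR = sum(FN) / (sum(TP) + sum(FN))
#   FPR = sum(FP) / (sum(TN) + sum(FP))
# and combined as the Euclidean error rate ER = sqrt(FPR^2 + FNR^2).
# Undefined rates (an absent similarity class) propagate as NA, never as a
# silent 0.

#' Build the comparison table for a trial design
#'
#' One row per unordered within-trial pair of sets, with the ground-truth
#' similarity class (`same` when both sets portray the same individual).
#' For a 15-set trial there are 105 rows; five such trials give 525.
#'
#' @param trials Tibble with `trial_id`, `set_id`, `individual_id` (e.g.
#'   from [sim_trials()]).
#' @return A tibble with `trial_id`, `comparison_id`, `set_a`, `set_b`,
#'   `truth`, in deterministic sorted order.
#' @examples
#' trials <- tibble::tibble(trial_id = "t1", set_id = c("a", "b", "c"),
#'                          individual_id = c("x", "x", "y"))
#' build_comparison_table(trials)
#' @export
build_comparison_table <- function(trials) {
  stopifnot(all(c("trial_id", "set_id", "individual_id") %in% names(trials)))
  dup <- trials |>
    group_by(.data$trial_id, .data$set_id) |>
    summarise(n = n(), .groups = "drop") |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate set within a trial: ",
         paste(dup$trial_id, dup$set_id, collapse = ", "))
  }
  one <- function(df) {
    df <- arrange(df, .data$set_id)
    if (nrow(df) < 2) stop("trial ", df$trial_id[1], " has fewer than 2 sets")
    idx <- combn(nrow(df), 2)
    tibble(
      trial_id = df$trial_id[1],
      set_a = df$set_id[idx[1, ]],
      set_b = df$set_id[idx[2, ]],
      truth = ifelse(df$individual_id[idx[1, ]] == df$individual_id[idx[2, ]],
                     "same", "different")
    )
  }
  out <- trials |>
    group_by(.data$trial_id) |>
    dplyr::group_split() |>
    map(one) |>
    bind_rows() |>
    arrange(.data$trial_id, .data$set_a, .data$set_b)
  out |>
    group_by(.data$trial_id) |>
    mutate(comparison_id = sprintf("%s_c%03d", .data$trial_id,
                                   row_number())) |>
    ungroup() |>
    select("trial_id", "comparison_id", "set_a", "set_b", "truth")
}

#' Classify ratings into confusion cells and outcomes
#'
#' Joins per-observer ratings onto a comparison table and assigns each
#' (comparison, observer) cell exactly one of TP/TN/FP/FN, plus the binary
#' `outcome` (0 = rating correct, 1 = incorrect).
#'
#' @param comparisons A [build_comparison_table()] tibble.
#' @param ratings Long tibble with `comparison_id`, `observer_id`,
#'   `rating` in `{"S", "D"}` covering every comparison.
#' @return A tibble with `trial_id`, `comparison_id`, `observer_id`,
#'   `truth`, `rating`, `cell`, `outcome`.
#' @export
classify_outcomes <- function(comparisons, ratings) {
  bad <- ratings$rating[!ratings$rating %in% c("S", "D")]
  if (length(bad)) {
    at <- which(!ratings$rating %in% c("S", "D"))[1]
    stop(sprintf("invalid rating %s at comparison %s, observer %s",
                 ratings$rating[at], ratings$comparison_id[at],
                 ratings$observer_id[at]))
  }
  missing_cmp <- setdiff(comparisons$comparison_id, ratings$comparison_id)
  if (length(missing_cmp)) {
    stop("ratings missing for comparison(s): ",
         paste(head(missing_cmp, 5), collapse = ", "))
  }
  out <- left_join(ratings, comparisons, by = "comparison_id") |>
    mutate(
      cell = case_when(
        .data$truth == "same" & .data$rating == "S" ~ "TP",
        .data$truth == "same" & .data$rating == "D" ~ "FN",
        .data$truth == "different" & .data$rating == "D" ~ "TN",
        .data$truth == "different" & .data$rating == "S" ~ "FP"
      ),
      outcome = as.integer(.data$cell %in% c("FN", "FP"))
    )
  if (anyNA(out$truth)) {
    stop("ratings refer to unknown comparison id(s): ",
         paste(head(unique(out$comparison_id[is.na(out$truth)]), 5),
               collapse = ", "))
  }
  out |>
    select(dplyr::any_of(c("trial_id", "comparison_id", "observer_id",
                           "truth", "rating", "cell", "outcome")))
}

#' Euclidean error rate
#'
#' `ER = sqrt(FPR^2 + FNR^2)`, the distance of the error pair from the
#' origin of the modified ROC plot. Bounded by
#' `max(FPR, FNR) <= ER <= FPR + FNR` and at most `sqrt(2)`.
#'
#' @param fpr,fnr False positive / false negative rates (vectorized).
#' @return Numeric vector of error rates; `NA` where either rate is `NA`.
#' @examples
#' error_rate(0.303, 0.493) # 0.579 to 3 decimals
#' @export
error_rate <- function(fpr, fnr) {
  sqrt(fpr^2 + fnr^2)
}

#' Pooled confusion rates over classified outcomes
#'
#' Counts TP/TN/FP/FN over all cells (pooled across trials and observers,
#' matching the summation form of the rate definitions) and computes FNR,
#' FPR and ER. An absent similarity class leaves the corresponding rate --
#' and ER -- as `NA`.
#'
#' @param outcomes A [classify_outcomes()] tibble (column `cell`), or any
#'   tibble with a `cell` column.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `n`, `fpr`, `fnr`,
#'   `er`.
#' @export
confusion_rates <- function(outcomes) {
  stopifnot("cell" %in% names(outcomes))
  tp <- sum(outcomes$cell == "TP"); tn <- sum(outcomes$cell == "TN")
  fp <- sum(outcomes$cell == "FP"); fn <- sum(outcomes$cell == "FN")
  fnr <- if (tp + fn > 0) fn / (tp + fn) else NA_real_
  fpr <- if (tn + fp > 0) fp / (tn + fp) else NA_real_
  tibble(tp = tp, tn = tn, fp = fp, fn = fn, n = nrow(outcomes),
         fpr = fpr, fnr = fnr, er = error_rate(fpr, fnr))
}

#' Proportion of unanimously rated comparisons
#'
#' The fraction of comparisons on which every observer gave the identical
#' rating (all `"S"` or all `"D"`).
#'
#' @param ratings Long tibble with `comparison_id`, `observer_id`,
#'   `rating`; every comparison must be rated by every observer.
#' @return A single proportion.
#' @export
unanimity_proportion <- function(ratings) {
  n_obs <- length(unique(ratings$observer_id))
  if (n_obs < 2) stop("unanimity requires at least 2 observers")
  counts <- ratings |>
    group_by(.data$comparison_id) |>
    summarise(k = n(), unanimous = length(unique(.data$rating)) == 1,
              .groups = "drop")
  short <- counts$comparison_id[counts$k != n_obs]
  if (length(short)) {
    stop("missing rating cells for comparison(s): ",
         paste(head(short, 5), collapse = ", "))
  }
  mean(counts$unanimous)
}

#' Summarise set quality labels
#'
#' Counts and proportions of `high` / `low` / `unsuitable` quality labels
#' over set slots (a set presented in several trials counts once per
#' slot).
#'
#' @param sets Tibble with a `quality` column.
#' @return A tibble with `quality`, `n`, `proportion`.
#' @export
summarise_quality <- function(sets) {
  stopifnot("quality" %in% names(sets))
  sets |>
    group_by(quality = factor(.data$quality,
                              c("high", "low", "unsuitable"))) |>
    summarise(n = n(), .groups = "drop") |>
    tidyr::complete(.data$quality, fill = list(n = 0L)) |>
    mutate(proportion = .data$n / sum(.data$n))
}
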