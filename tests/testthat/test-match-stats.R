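make_design <- function(n_trials = 5, seed = 1) {
  sets <- tibble::tibble(
    individual_id = rep(sprintf("b%02d", 1:15), c(rep(3, 14), 1)))
  sets$set_id <- paste0(sets$individual_id, "_",
                        stats::ave(seq_len(nrow(sets)), sets$individual_id,
                                   FUN = seq_along))
  sim_trials(sets, n_trials = n_trials, seed = seed)
}

test_that("five 15-set trials give exactly 525 unique comparisons", {
  cmp <- build_comparison_table(make_design())
  expect_equal(nrow(cmp), 525)
  expect_equal(anyDuplicated(cmp$comparison_id), 0L)
  expect_equal(as.integer(table(cmp$trial_id)), rep(105L, 5))
  expect_true(all(cmp$set_a != cmp$set_b))
  # each unordered pair appears once per trial
  key <- paste(cmp$trial_id, pmin(cmp$set_a, cmp$set_b),
               pmax(cmp$set_a, cmp$set_b))
  expect_equal(anyDuplicated(key), 0L)
})

test_that("truth classes come from individual identity", {
  trials <- tibble::tibble(trial_id = "t1",
                           set_id = c("s1", "s2", "s3", "s4"),
                           individual_id = c("A", "A", "B", "C"))
  cmp <- build_comparison_table(trials)
  expect_equal(nrow(cmp), 6)
  expect_equal(sum(cmp$truth == "same"), 1)
  expect_equal(cmp$truth[cmp$set_a == "s1" & cmp$set_b == "s2"], "same")
  two <- build_comparison_table(
    tibble::tibble(trial_id = "t1", set_id = c("x", "y"),
                   individual_id = c("A", "A")))
  expect_equal(nrow(two), 1)
  expect_equal(two$truth, "same")
})

test_that("duplicate sets within a trial are rejected", {
  trials <- tibble::tibble(trial_id = "t1", set_id = c("s1", "s1", "s2"),
                           individual_id = c("A", "A", "B"))
  expect_error(build_comparison_table(trials), "duplicate")
})

test_that("outcome coding follows the confusion definitions", {
  cmp <- tibble::tibble(trial_id = "t1",
                        comparison_id = c("c1", "c2", "c3", "c4"),
                        set_a = "a", set_b = "b",
                        truth = c("same", "same", "different", "different"))
  ratings <- tibble::tibble(observer_id = "o1",
                            comparison_id = c("c1", "c2", "c3", "c4"),
                            rating = c("S", "D", "S", "D"))
  out <- classify_outcomes(cmp, ratings)
  expect_equal(out$cell, c("TP", "FN", "FP", "TN"))
  expect_equal(out$outcome, c(0L, 1L, 1L, 0L))
})

test_that("invalid or missing ratings fail naming the cell", {
  cmp <- tibble::tibble(trial_id = "t1", comparison_id = c("c1", "c2"),
                        set_a = "a", set_b = "b",
                        truth = c("same", "different"))
  bad <- tibble::tibble(observer_id = "o1", comparison_id = c("c1", "c2"),
                        rating = c("S", "X"))
  expect_error(classify_outcomes(cmp, bad), "invalid rating X.*c2")
  expect_error(classify_outcomes(cmp, bad[1, ]), "missing.*c2")
})

test_that("confusion rates reproduce the published worked examples", {
  # construct cell tallies whose pooled rates equal the printed ones
  outcomes <- tibble::tibble(cell = c(rep("FN", 493), rep("TP", 507),
                                      rep("FP", 303), rep("TN", 697)))
  cr <- confusion_rates(outcomes)
  expect_equal(cr$fnr, 0.493)
  expect_equal(cr$fpr, 0.303)
  expect_equal(round(cr$er, 3), 0.579)
  expect_equal(round(error_rate(0.200, 0.061), 3), 0.209)
  expect_equal(cr$tp + cr$tn + cr$fp + cr$fn, cr$n)
})

test_that("all-correct ratings give zero error rates", {
  outcomes <- tibble::tibble(cell = c("TP", "TN", "TP", "TN"))
  cr <- confusion_rates(outcomes)
  expect_equal(c(cr$fpr, cr$fnr, cr$er), c(0, 0, 0))
})

test_that("rates for an absent similarity class are undefined, not zero", {
  only_diff <- tibble::tibble(cell = c("TN", "FP", "TN"))
  cr <- confusion_rates(only_diff)
  expect_true(is.na(cr$fnr))
  expect_true(is.na(cr$er))
  expect_equal(cr$fpr, 1 / 3)
})

test_that("ER is bounded by max(FPR,FNR) and FPR+FNR", {
  set.seed(9)
  for (i in 1:200) {
    fpr <- runif(1); fnr <- runif(1)
    er <- error_rate(fpr, fnr)
    expect_gte(er, max(fpr, fnr))
    expect_lte(er, fpr + fnr + 1e-12)
    expect_lte(er, sqrt(2))
  }
})

test_that("simulated observers are recovered within 3 binomial SEs", {
  cmp <- build_comparison_table(make_design(n_trials = 5, seed = 8))
  obs <- sim_observers()
  ratings <- sim_ratings(cmp, obs, seed = 2026)
  # >= 10^4 cells: 525 comparisons x 10 observers
  expect_equal(nrow(ratings), 5250)
  out <- classify_outcomes(cmp, ratings)
  rec <- build_rating_records(out, obs)
  for (grp in c(0, 1)) {
    sub <- rec[rec$experience == grp, ]
    cr <- confusion_rates(sub)
    true_fnr <- if (grp == 0) 0.130 else 0.719
    true_fpr <- if (grp == 0) 0.003 else 0.009
    n_same <- cr$tp + cr$fn; n_diff <- cr$tn + cr$fp
    expect_lt(abs(cr$fnr - true_fnr),
              3 * sqrt(true_fnr * (1 - true_fnr) / n_same))
    expect_lt(abs(cr$fpr - true_fpr),
              3 * sqrt(true_fpr * (1 - true_fpr) / n_diff))
  }
})

test_that("unanimity proportion counts fully agreeing comparisons", {
  r <- tibble::tibble(
    comparison_id = rep(c("c1", "c2"), each = 3),
    observer_id = rep(c("o1", "o2", "o3"), 2),
    rating = c("S", "S", "S", "S", "D", "S"))
  expect_equal(unanimity_proportion(r), 0.5)
  r1 <- r[r$comparison_id == "c1", ]
  expect_equal(unanimity_proportion(r1), 1.0)
  expect_error(unanimity_proportion(r[-4, ]), "missing.*c2")
  expect_error(unanimity_proportion(r[r$observer_id == "o1", ]),
               "at least 2")
})

test_that("error-free simulated observers are unanimous", {
  cmp <- build_comparison_table(make_design(n_trials = 1, seed = 5))
  obs <- sim_observers(rates_experienced = c(fpr = 0, fnr = 0),
                       rates_inexperienced = c(fpr = 0, fnr = 0))
  ratings <- sim_ratings(cmp, obs, seed = 1)
  expect_equal(unanimity_proportion(ratings), 1.0)
})

test_that("quality summary reports the 19-of-75 proportion as 0.253", {
  sets <- tibble::tibble(quality = c(rep("high", 19), rep("low", 31),
                                     rep("unsuitable", 25)))
  qs <- summarise_quality(sets)
  expect_equal(qs$n[qs$quality == "high"], 19L)
  expect_equal(sum(qs$n), 75L)
  expect_equal(round(qs$proportion[qs$quality == "high"], 3), 0.253)
})
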