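test_that("spot patterns respect count range, region and separation", {
  grid <- small_grid()
  cfg <- small_spot_config()
  region <- bearid:::default_spot_region(grid, cfg)
  for (seed in c(1, 7, 42)) {
    p <- sim_spot_pattern("left", seed, cfg, grid)
    n <- nrow(p$spots)
    expect_gte(n, cfg$n_spots_range[1])
    expect_lte(n, cfg$n_spots_range[2])
    expect_true(all(p$spots[, 1] >= region[["x0"]] &
                      p$spots[, 1] <= region[["x1"]]))
    expect_true(all(p$spots[, 2] >= region[["y0"]] &
                      p$spots[, 2] <= region[["y1"]]))
    d <- as.matrix(dist(p$spots))
    diag(d) <- Inf
    expect_gte(min(d), cfg$min_separation)
  }
})

test_that("generators are pure functions of their seed", {
  g <- small_grid(); cfg <- small_spot_config()
  expect_identical(sim_spot_pattern("left", 3, cfg, g),
                   sim_spot_pattern("left", 3, cfg, g))
  expect_identical(sim_individuals(4, seed = 9, cfg, g),
                   sim_individuals(4, seed = 9, cfg, g))
  p1 <- render_photo(sim_spot_pattern("left", 3, cfg, g), quality = "low",
                     seed = 5, grid = g)
  p2 <- render_photo(sim_spot_pattern("left", 3, cfg, g), quality = "low",
                     seed = 5, grid = g)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$landmarks, p2$landmarks)
})

test_that("patterns differ across individuals (seeds 1..100)", {
  g <- small_grid(); cfg <- small_spot_config()
  pats <- lapply(1:100, function(s) sim_spot_pattern("left", s, cfg, g)$spots)
  keys <- vapply(pats, function(m) paste(sprintf("%.6f", m), collapse = ","),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("left and right patterns of one individual are independent draws", {
  ind <- sim_individuals(5, seed = 2, small_spot_config(), small_grid())
  for (i in seq_len(nrow(ind))) {
    l <- ind$pattern_left[[i]]$spots
    r <- ind$pattern_right[[i]]$spots
    expect_false(nrow(l) == nrow(r) && isTRUE(all.equal(l, r)))
  }
})

test_that("region too small for the requested spots fails explicitly", {
  cfg <- spot_config(n_spots_range = c(200, 200), spot_radius = 3,
                     min_separation = 8, max_attempts = 500)
  expect_error(sim_spot_pattern("left", 1, cfg, small_grid()),
               "could not place")
})

test_that("the default pool is 43 sets (14 x 3 + 1) and trials validate", {
  inds <- sim_individuals(15, seed = 1, small_spot_config(), small_grid())
  sets <- sim_photo_sets(inds, seed = 1)
  expect_equal(nrow(sets), 43)
  expect_equal(max(table(sets$individual_id)), 3)
  trials <- sim_trials(sets, n_trials = 5, seed = 1)
  per_trial <- split(trials, trials$trial_id)
  expect_length(per_trial, 5)
  for (tr in per_trial) {
    expect_equal(nrow(tr), 15)
    expect_true(length(unique(tr$individual_id)) %in% c(10, 11))
    expect_lte(max(table(tr$individual_id)), 3)
  }
  expect_identical(trials, sim_trials(sets, n_trials = 5, seed = 1))
})

test_that("trial composition keeps distinct individuals in {10, 11}", {
  inds <- tibble::tibble(individual_id = sprintf("b%02d", 1:15))
  sets <- tibble::tibble(
    individual_id = rep(inds$individual_id, c(rep(3, 14), 1)))
  sets$set_id <- paste0(sets$individual_id, "_",
                        stats::ave(seq_len(nrow(sets)), sets$individual_id,
                                   FUN = seq_along))
  trials <- sim_trials(sets, n_trials = 200, seed = 11)
  counts <- tapply(trials$individual_id, trials$trial_id,
                   function(x) length(unique(x)))
  expect_true(all(counts %in% c(10, 11)))
})

test_that("same-pair count equals sum over individuals of C(m, 2)", {
  inds <- tibble::tibble(individual_id = sprintf("b%02d", 1:15))
  sets <- tibble::tibble(
    individual_id = rep(inds$individual_id, c(rep(3, 14), 1)))
  sets$set_id <- paste0(sets$individual_id, "_",
                        stats::ave(seq_len(nrow(sets)), sets$individual_id,
                                   FUN = seq_along))
  trials <- sim_trials(sets, n_trials = 20, seed = 3)
  cmp <- build_comparison_table(trials)
  for (tid in unique(trials$trial_id)) {
    m <- table(trials$individual_id[trials$trial_id == tid])
    expected_same <- sum(choose(m, 2))
    observed <- sum(cmp$truth[cmp$trial_id == tid] == "same")
    expect_equal(observed, expected_same)
  }
})

test_that("an unsatisfiable trial constraint fails after max rejections", {
  sets <- tibble::tibble(individual_id = rep(sprintf("b%d", 1:5), each = 3))
  sets$set_id <- paste0(sets$individual_id, "_",
                        stats::ave(seq_len(nrow(sets)), sets$individual_id,
                                   FUN = seq_along))
  expect_error(sim_trials(sets, n_trials = 1, seed = 1, n_sets = 15,
                          max_rejections = 50),
               "no draw")
})

test_that("simulated observers obey their error probabilities exactly at 0/1", {
  trials <- tibble::tibble(trial_id = "t1",
                           set_id = c("a", "b", "c", "d"),
                           individual_id = c("x", "x", "y", "z"))
  cmp <- build_comparison_table(trials)
  perfect <- tibble::tibble(observer_id = "o1",
                            experience_photogrammetry = TRUE,
                            experience_bears = TRUE,
                            true_fpr = 0, true_fnr = 0)
  r <- sim_ratings(cmp, perfect, seed = 1)
  expect_true(all(r$rating[cmp$truth == "same"] == "S"))
  expect_true(all(r$rating[cmp$truth == "different"] == "D"))
  wrong <- perfect; wrong$true_fpr <- 1; wrong$true_fnr <- 1
  r2 <- sim_ratings(cmp, wrong, seed = 1)
  expect_true(all(r2$rating[cmp$truth == "same"] == "D"))
  expect_true(all(r2$rating[cmp$truth == "different"] == "S"))
})

test_that("observer error rates are recovered across seeds (binomial SE)", {
  # 525 comparisons x 200 seeds; recovered FNR within 3 Monte-Carlo SEs
  inds <- tibble::tibble(individual_id = sprintf("b%02d", 1:15))
  sets <- tibble::tibble(
    individual_id = rep(inds$individual_id, c(rep(3, 14), 1)))
  sets$set_id <- paste0(sets$individual_id, "_",
                        stats::ave(seq_len(nrow(sets)), sets$individual_id,
                                   FUN = seq_along))
  trials <- sim_trials(sets, n_trials = 5, seed = 21)
  cmp <- build_comparison_table(trials)
  obs <- tibble::tibble(observer_id = "o1",
                        experience_photogrammetry = TRUE,
                        experience_bears = FALSE,
                        true_fpr = 0.003, true_fnr = 0.13)
  n_same_total <- 0; fn_total <- 0
  n_diff_total <- 0; fp_total <- 0
  for (s in 1:200) {
    r <- sim_ratings(cmp, obs, seed = s)
    same <- cmp$truth == "same"
    n_same_total <- n_same_total + sum(same)
    fn_total <- fn_total + sum(r$rating[same] == "D")
    n_diff_total <- n_diff_total + sum(!same)
    fp_total <- fp_total + sum(r$rating[!same] == "S")
  }
  fnr_hat <- fn_total / n_same_total
  se_fnr <- sqrt(0.13 * 0.87 / n_same_total)
  expect_lt(abs(fnr_hat - 0.13), 3 * se_fnr)
  fpr_hat <- fp_total / n_diff_total
  se_fpr <- sqrt(0.003 * 0.997 / n_diff_total)
  expect_lt(abs(fpr_hat - 0.003), 3 * se_fpr)
})

test_that("render quality degrades monotonically (blur and jitter)", {
  g <- small_grid(); cfg <- small_spot_config()
  pat <- sim_spot_pattern("left", 77, cfg, g)
  mk_cfg <- function(blur, jitter, noise) {
    render_config(
      affine = list(rotate_deg = 4, log_scale = 0.04, shear = 0.02,
                    translate_px = 4),
      quality = list(high = list(blur_sigma = blur, noise_sd = noise,
                                 jitter_sd = jitter),
                     low = list(blur_sigma = blur, noise_sd = noise,
                                jitter_sd = jitter),
                     unsuitable = list(blur_sigma = blur, noise_sd = noise,
                                       jitter_sd = jitter)))
  }
  within_diss <- function(rc, seeds) {
    vapply(seeds, function(s) {
      p1 <- render_photo(pat, quality = "high", seed = s, config = rc,
                         grid = g)
      p2 <- render_photo(pat, quality = "high", seed = s + 5000,
                         config = rc, grid = g)
      b1 <- process_photo(p1$image, p1$landmarks, g)
      b2 <- process_photo(p2$image, p2$landmarks, g)
      chamfer_dissimilarity(b1, b2)
    }, numeric(1))
  }
  seeds <- 1:50
  d_sharp <- within_diss(mk_cfg(0.5, 0.5, 4), seeds)
  d_blur <- within_diss(mk_cfg(2.5, 0.5, 4), seeds)
  d_jitter <- within_diss(mk_cfg(0.5, 2.5, 4), seeds)
  expect_gte(median(d_blur, na.rm = TRUE), median(d_sharp, na.rm = TRUE))
  expect_gte(median(d_jitter, na.rm = TRUE), median(d_sharp, na.rm = TRUE))
})

test_that("low quality renders are harder to match than high quality", {
  g <- small_grid(); cfg <- small_spot_config()
  pat <- sim_spot_pattern("right", 13, cfg, g)
  rc <- render_config()
  d <- function(quality, seeds) {
    vapply(seeds, function(s) {
      p1 <- render_photo(pat, quality = quality, seed = s, config = rc,
                         grid = g)
      p2 <- render_photo(pat, quality = quality, seed = s + 9000,
                         config = rc, grid = g)
      chamfer_dissimilarity(process_photo(p1$image, p1$landmarks, g),
                            process_photo(p2$image, p2$landmarks, g))
    }, numeric(1))
  }
  seeds <- 1:50
  expect_gt(mean(d("low", seeds), na.rm = TRUE),
            mean(d("high", seeds), na.rm = TRUE))
})
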