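test_that("identical images have zero dissimilarity; singletons match hand value", {
  a <- matrix(FALSE, 4, 4); a[1, 1] <- TRUE
  expect_equal(chamfer_dissimilarity(a, a), 0)
  b <- matrix(FALSE, 4, 4); b[1, 3] <- TRUE # (x=0,y=0) vs (x=2,y=0)
  expect_equal(chamfer_dissimilarity(a, b), 2.0)
  set.seed(3)
  m <- matrix(runif(15 * 12) < 0.2, 12, 15)
  if (!any(m)) m[3, 3] <- TRUE
  expect_equal(chamfer_dissimilarity(m, m), 0)
})

test_that("chamfer equals the brute-force nearest-neighbour oracle", {
  set.seed(11)
  for (i in 1:20) {
    a <- matrix(runif(16 * 16) < 0.12, 16, 16)
    b <- matrix(runif(16 * 16) < 0.12, 16, 16)
    if (!any(a)) a[2, 2] <- TRUE
    if (!any(b)) b[5, 9] <- TRUE
    expect_equal(chamfer_dissimilarity(a, b), brute_chamfer(a, b),
                 tolerance = 1e-9)
  }
})

test_that("chamfer is exactly symmetric and non-negative", {
  set.seed(23)
  for (i in 1:10) {
    a <- matrix(runif(14 * 14) < 0.15, 14, 14)
    b <- matrix(runif(14 * 14) < 0.15, 14, 14)
    if (!any(a)) a[1, 1] <- TRUE
    if (!any(b)) b[1, 2] <- TRUE
    dab <- chamfer_dissimilarity(a, b)
    expect_identical(dab, chamfer_dissimilarity(b, a))
    expect_gte(dab, 0)
    if (!identical(which(a), which(b))) expect_gt(dab, 0)
  }
})

test_that("translating one image moves each directed term by at most |t|", {
  set.seed(5)
  for (i in 1:10) {
    a <- matrix(runif(20 * 20) < 0.1, 20, 20)
    b0 <- matrix(FALSE, 20, 20)
    b0[4:14, 4:14] <- matrix(runif(11 * 11) < 0.15, 11, 11)
    if (!any(a)) a[3, 3] <- TRUE
    if (!any(b0)) b0[6, 6] <- TRUE
    dx <- sample(-3:3, 1); dy <- sample(-3:3, 1)
    bt <- matrix(FALSE, 20, 20)
    idx <- which(b0, arr.ind = TRUE)
    bt[cbind(idx[, 1] + dy, idx[, 2] + dx)] <- TRUE
    t_norm <- sqrt(dx^2 + dy^2)
    d_ab0 <- bearid:::directed_chamfer(a, bearid:::distance_to_black(b0))
    d_abt <- bearid:::directed_chamfer(a, bearid:::distance_to_black(bt))
    expect_lte(abs(d_abt - d_ab0), t_norm + 1e-9)
  }
})

test_that("empty images give the incomparable sentinel, not 0 or Inf", {
  a <- matrix(FALSE, 6, 6)
  b <- matrix(FALSE, 6, 6); b[2, 2] <- TRUE
  expect_identical(chamfer_dissimilarity(a, b), NA_real_)
  expect_identical(chamfer_dissimilarity(b, a), NA_real_)
  expect_identical(chamfer_dissimilarity(a, a), NA_real_)
  expect_error(chamfer_dissimilarity(b, matrix(FALSE, 5, 5)), "dimensions")
})

test_that("pairwise table records the lower of the two side dissimilarities", {
  g <- small_grid()
  mk_bin <- function(px, id, side, q) {
    tibble::tibble(photo_id = id, set_id = sub("_[lr]$", "", id),
                   individual_id = "x", side = side, quality = q,
                   usable = TRUE,
                   bin = list(bearid:::new_binary_spot_image(px, g, id, side)))
  }
  dims <- bearid:::crop_dims(g)
  base <- matrix(FALSE, dims[["height"]], dims[["width"]])
  pxA_l <- base; pxA_l[10, 10] <- TRUE
  pxB_l <- base; pxB_l[10, 14] <- TRUE  # left-left distance 4
  pxA_r <- base; pxA_r[20, 20] <- TRUE
  pxB_r <- base; pxB_r[20, 21] <- TRUE  # right-right distance 1
  bins <- dplyr::bind_rows(
    mk_bin(pxA_l, "s1_l", "left", "high"), mk_bin(pxA_r, "s1_r", "right", "high"),
    mk_bin(pxB_l, "s2_l", "left", "high"), mk_bin(pxB_r, "s2_r", "right", "high"))
  out <- quiet(pairwise_dissimilarity(bins))
  expect_equal(nrow(out), 1)
  expect_equal(out$dissimilarity, 1)
  expect_equal(out$side_used, "right")
  expect_equal(out$quality_group, "high")
  # drop one side: the remaining left-left value is used
  out2 <- quiet(pairwise_dissimilarity(bins[-4, ]))
  expect_equal(out2$dissimilarity, 4)
  expect_equal(out2$side_used, "left")
})

test_that("pair quality group is high only when both sets are high quality", {
  g <- small_grid()
  dims <- bearid:::crop_dims(g)
  px <- matrix(FALSE, dims[["height"]], dims[["width"]]); px[5, 5] <- TRUE
  mk <- function(set, q) {
    tibble::tibble(photo_id = paste0(set, "_l"), set_id = set,
                   individual_id = set, side = "left", quality = q,
                   usable = TRUE,
                   bin = list(bearid:::new_binary_spot_image(px, g)))
  }
  bins <- dplyr::bind_rows(mk("s1", "high"), mk("s2", "low"),
                           mk("s3", "high"))
  out <- quiet(pairwise_dissimilarity(bins))
  grp <- setNames(out$quality_group, paste(out$set_a, out$set_b))
  expect_equal(unname(grp[c("s1 s2", "s2 s3", "s1 s3")]),
               c("low", "low", "high"))
})

test_that("sets with no shared side are incomparable; unusable sets excluded", {
  g <- small_grid()
  dims <- bearid:::crop_dims(g)
  px <- matrix(FALSE, dims[["height"]], dims[["width"]]); px[5, 5] <- TRUE
  bins <- tibble::tibble(
    photo_id = c("s1_l", "s2_r", "s3_l"),
    set_id = c("s1", "s2", "s3"),
    individual_id = c("x", "y", "z"),
    side = c("left", "right", "left"),
    quality = c("high", "high", "unsuitable"),
    usable = c(TRUE, TRUE, FALSE),
    bin = list(bearid:::new_binary_spot_image(px, g),
               bearid:::new_binary_spot_image(px, g),
               NULL))
  out <- quiet(pairwise_dissimilarity(bins))
  expect_equal(nrow(out), 1) # s3 excluded entirely
  expect_equal(out$status, "incomparable")
  expect_true(is.na(out$dissimilarity))
  expect_equal(attr(out, "excluded_sets"), "s3")
})

test_that("within-individual dissimilarity is below between-individual", {
  g <- small_grid()
  inds <- sim_individuals(9, seed = 31, small_spot_config(), g)
  sets <- sim_photo_sets(inds, seed = 31, occasions = 2)
  photos <- render_study_photos(sets, inds, seed = 31,
                                quality_probs = c(high = 1, low = 0,
                                                  unsuitable = 0),
                                grid = g)
  bins <- process_photos(photos, g)
  d <- quiet(pairwise_dissimilarity(bins))
  ok <- d[d$status == "ok", ]
  expect_lt(median(ok$dissimilarity[ok$truth == "same"]),
            median(ok$dissimilarity[ok$truth == "different"]))
})
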