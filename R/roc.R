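# Modified ROC analysis of the dissimilarity index.
#
# A threshold splits pairs into "same" (dissimilarity below it) and
# "different" (at or above it). As the threshold rises FNR falls and FPR
# rises; the curve plots FNR against FPR at every observed threshold and
# the optimal threshold is the point nearest the origin (both error rates
# zero). Equality with the threshold is classified "different": the rule
# covers only "below" and "above", and sending ties to "different" keeps
# FPR conservative.

#' Classify dissimilarities by a threshold
#'
#' @param dissimilarities Numeric vector; `NA` marks incomparable pairs,
#'   which stay `NA` (their count is reported via a message).
#' @param threshold The decision threshold: values strictly below it are
#'   rated `"S"`, values at or above it `"D"`.
#' @return Character vector in `{"S", "D", NA}`.
#' @examples
#' classify_by_threshold(c(2.5, 5.0), 2.8)
#' @export
classify_by_threshold <- function(dissimilarities, threshold) {
  stopifnot(length(threshold) == 1)
  n_na <- sum(is.na(dissimilarities))
  if (n_na > 0) {
    message(n_na, " incomparable pair(s) left unclassified")
  }
  ifelse(is.na(dissimilarities), NA_character_,
         ifelse(dissimilarities < threshold, "S", "D"))
}

roc_points <- function(d_same, d_diff) {
  ths <- c(-Inf, sort(unique(c(d_same, d_diff))), Inf)
  tibble(
    threshold = ths,
    fpr = vapply(ths, function(t) mean(d_diff < t), numeric(1)),
    fnr = vapply(ths, function(t) mean(d_same >= t), numeric(1))
  ) |>
    mutate(distance = error_rate(.data$fpr, .data$fnr))
}

#' Build the modified ROC curve of a dissimilarity table
#'
#' Sweeps the threshold over every observed dissimilarity value (plus
#' `-Inf`/`Inf` sentinels for the degenerate ends), recording `(FPR, FNR)`
#' at each, and locates the optimal threshold. Incomparable pairs
#' (`NA` dissimilarity) are excluded with a reported count.
#'
#' @param data Tibble with a dissimilarity column and a truth column (e.g.
#'   from [pairwise_dissimilarity()]).
#' @param dissimilarity,truth Column names. `truth` must contain both
#'   `"same"` and `"different"`.
#' @param quality_group Optional label carried on the result.
#' @return An object of class `whisker_roc` with elements `points`
#'   (tibble: `threshold`, `fpr`, `fnr`, `distance`), `optimal` (one-row
#'   tibble), `n_same`, `n_different`, `n_excluded`, `quality_group`.
#'   [tidy()] returns the points, [glance()] the optimum, [autoplot()] the
#'   FNR-vs-FPR plot.
#' @export
roc_curve <- function(data, dissimilarity = "dissimilarity",
                      truth = "truth", quality_group = NA_character_) {
  d <- data[[dissimilarity]]
  tr <- data[[truth]]
  stopifnot(!is.null(d), !is.null(tr))
  keep <- !is.na(d)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded, " incomparable pair(s) excluded from the ROC input")
  }
  d <- d[keep]; tr <- tr[keep]
  if (!all(c("same", "different") %in% tr)) {
    stop("both truth classes are required to sweep a threshold")
  }
  pts <- roc_points(d[tr == "same"], d[tr == "different"])
  obj <- structure(
    list(points = pts, optimal = NULL, n_same = sum(tr == "same"),
         n_different = sum(tr == "different"), n_excluded = n_excluded,
         quality_group = quality_group),
    class = "whisker_roc")
  obj$optimal <- optimal_threshold(obj)
  obj
}

#' Locate the optimal threshold on a modified ROC curve
#'
#' The optimum minimises the Euclidean distance
#' `sqrt(FPR^2 + FNR^2)` from the curve to the bottom-left corner of the
#' plot; ties are broken by lower FPR, then lower threshold.
#'
#' @param curve A `whisker_roc` object or its points tibble (columns
#'   `threshold`, `fpr`, `fnr`).
#' @return A one-row tibble: `threshold`, `fpr`, `fnr`,
#'   `distance_to_origin`.
#' @export
optimal_threshold <- function(curve) {
  pts <- if (inherits(curve, "whisker_roc")) curve$points else as_tibble(curve)
  stopifnot(nrow(pts) > 0)
  dist <- error_rate(pts$fpr, pts$fnr)
  ord <- order(dist, pts$fpr, pts$threshold)
  best <- ord[1]
  tibble(threshold = pts$threshold[best], fpr = pts$fpr[best],
         fnr = pts$fnr[best], distance_to_origin = dist[best])
}

#' @export
print.whisker_roc <- function(x, ...) {
  cat(sprintf(
    "<whisker_roc>%s %d same + %d different pairs, %d thresholds\n",
    if (is.na(x$quality_group)) "" else paste0(" [", x$quality_group, "]"),
    x$n_same, x$n_different, nrow(x$points)))
  cat(sprintf("  optimal threshold %.3g: FPR %.3f, FNR %.3f, ER %.3f\n",
              x$optimal$threshold, x$optimal$fpr, x$optimal$fnr,
              x$optimal$distance_to_origin))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.whisker_roc <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.whisker_roc <- function(x, ...) {
  tibble(optimal_threshold = x$optimal$threshold, fpr = x$optimal$fpr,
         fnr = x$optimal$fnr, error_rate = x$optimal$distance_to_origin,
         n_same = x$n_same, n_different = x$n_different,
         n_excluded = x$n_excluded, quality_group = x$quality_group)
}

#' @exportS3Method ggplot2::autoplot
autoplot.whisker_roc <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$fnr)) +
    ggplot2::geom_abline(slope = -1, intercept = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = object$optimal, colour = "red", size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "False negative rate",
                  title = if (is.na(object$quality_group)) "Modified ROC"
                          else paste("Modified ROC,", object$quality_group,
                                     "quality")) +
    ggplot2::theme_minimal()
}

# FNR as a staircase function of allowed FPR: the smallest FNR achievable
# at FPR <= f. Always defined because the -Inf sentinel has FPR = 0.
fnr_at_fpr <- function(points, fpr_grid) {
  vapply(fpr_grid, function(f) {
    ok <- points$fpr <= f
    if (!any(ok)) 1 else min(points$fnr[ok])
  }, numeric(1))
}

#' Bootstrap confidence band of the modified ROC curve
#'
#' Resamples comparisons with replacement, stratified by truth class (so a
#' replicate can never lose a class), rebuilds the curve, and reports the
#' 2.5/97.5 percentile band of FNR on a fixed FPR grid. The observed curve
#' is included as one of the `n_replicates` curves, so the band always
#' contains the point estimate and collapses onto it at
#' `n_replicates = 1`.
#'
#' @inheritParams roc_curve
#' @param n_replicates Total number of curves (observed + resampled).
#' @param seed Integer seed; fixed seed gives an identical band.
#' @param fpr_grid FPR values at which the band is evaluated.
#' @return A tibble of class `roc_band`: `fpr`, `fnr` (point estimate),
#'   `lower`, `upper`; attributes `n_replicates`, `n_redrawn`.
#' @export
roc_band <- function(data, dissimilarity = "dissimilarity", truth = "truth",
                     n_replicates = 10000, seed = 1,
                     fpr_grid = seq(0, 1, by = 0.01)) {
  stopifnot(n_replicates >= 1)
  d <- data[[dissimilarity]]; tr <- data[[truth]]
  keep <- !is.na(d)
  d <- d[keep]; tr <- tr[keep]
  ds <- d[tr == "same"]; dd <- d[tr == "different"]
  if (length(ds) < 2 || length(dd) < 2) {
    stop("bootstrap requires at least 2 pairs in each truth class")
  }
  est <- fnr_at_fpr(roc_points(ds, dd), fpr_grid)
  reps <- matrix(NA_real_, n_replicates, length(fpr_grid))
  reps[1, ] <- est
  if (n_replicates > 1) {
    with_seed(child_seed(seed, "roc_band"), {
      for (r in 2:n_replicates) {
        rs <- sample(ds, length(ds), replace = TRUE)
        rd <- sample(dd, length(dd), replace = TRUE)
        reps[r, ] <- fnr_at_fpr(roc_points(rs, rd), fpr_grid)
      }
    })
  }
  out <- tibble(
    fpr = fpr_grid,
    fnr = est,
    lower = apply(reps, 2, quantile, 0.025, names = FALSE),
    upper = apply(reps, 2, quantile, 0.975, names = FALSE)
  )
  attr(out, "n_replicates") <- n_replicates
  attr(out, "n_redrawn") <- 0L # stratification precludes degenerate draws
  class(out) <- c("roc_band", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_band <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$fnr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "False negative rate") +
    ggplot2::theme_minimal()
}
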