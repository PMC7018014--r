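# Symmetric Chamfer dissimilarity between binary whisker-spot images.
#
# For every black pixel of image A the Euclidean distance to the nearest
# black pixel of image B is read off an exact distance transform of B; the
# directed dissimilarity is the mean of those distances, and the reported
# index is the average of the two directions. Units are pixels on the
# standard grid.

as_black_pixels <- function(x) {
  px <- if (inherits(x, "binary_spot_image")) x$pixels else x
  stopifnot(is.logical(px), is.matrix(px))
  px
}

# Exact Euclidean distance from every pixel to the nearest TRUE pixel.
distance_to_black <- function(px) {
  stopifnot(any(px))
  fg <- matrix(1, nrow(px), ncol(px))
  fg[px] <- 0
  unclass(EBImage::imageData(EBImage::distmap(fg, metric = "euclidean")))
}

directed_chamfer <- function(px_from, dist_to) {
  mean(dist_to[px_from])
}

#' Symmetric Chamfer dissimilarity between two binary spot images
#'
#' `d(A -> B)` is the mean, over black pixels of `A`, of the Euclidean
#' distance to the nearest black pixel of `B`; the dissimilarity index is
#' `(d(A -> B) + d(B -> A)) / 2`. It is symmetric, non-negative, and zero
#' exactly when the two black-pixel sets coincide.
#'
#' If either image has no black pixels the pair is incomparable: the
#' sentinel `NA_real_` is returned (and excluded downstream), never a
#' silent 0 or an infinite value.
#'
#' @param a,b `binary_spot_image` objects or logical matrices of equal
#'   dimensions (`TRUE` = black).
#' @return A single non-negative number in pixels, or `NA_real_` for an
#'   incomparable pair.
#' @examples
#' a <- matrix(FALSE, 4, 4); b <- a
#' a[1, 1] <- TRUE; b[1, 3] <- TRUE
#' chamfer_dissimilarity(a, b) # 2: the single pixels are 2 px apart
#' @export
chamfer_dissimilarity <- function(a, b) {
  pa <- as_black_pixels(a); pb <- as_black_pixels(b)
  if (!all(dim(pa) == dim(pb))) {
    stop("images must share grid dimensions")
  }
  if (!any(pa) || !any(pb)) {
    return(NA_real_)
  }
  (directed_chamfer(pa, distance_to_black(pb)) +
     directed_chamfer(pb, distance_to_black(pa))) / 2
}

# Select, per set and side, the best available processed photo: empty or
# missing binaries are unusable; high quality beats low; ties broken by
# photo_id for determinism.
select_set_photos <- function(bins) {
  usable <- bins |>
    filter(!map_lgl(.data$bin, is.null),
           !map_lgl(.data$bin, function(b) isTRUE(b$empty))) |>
    mutate(q_rank = match(.data$quality, c("high", "low"))) |>
    filter(!is.na(.data$q_rank)) |>
    arrange(.data$set_id, .data$side, .data$q_rank, .data$photo_id) |>
    group_by(.data$set_id, .data$side) |>
    slice(1) |>
    ungroup()
  usable
}

#' Pairwise Chamfer dissimilarity over photo sets
#'
#' From each set at most one left-side and one right-side binary spot image
#' is selected (highest quality available); sets in which no photograph is
#' usable are excluded. For every unordered pair of usable sets the
#' dissimilarity is computed side-to-side (left-left and/or right-right,
#' never across sides) and, when both sides are available, the lower of the
#' two values is recorded. A pair is grouped as `"high"` quality only when
#' the selected photographs of both sets are high quality, otherwise
#' `"low"`. Pairs of sets sharing no side are marked incomparable.
#'
#' @param bins Tibble from [process_photos()] (columns `photo_id`,
#'   `set_id`, `individual_id`, `side`, `quality`, list-column `bin`).
#' @return A tibble with one row per unordered set pair: `set_a`, `set_b`,
#'   `individual_a`, `individual_b`, `truth`, `side_used`,
#'   `dissimilarity`, `quality_group`, `status`. Excluded set ids are
#'   attached as attribute `"excluded_sets"`.
#' @export
pairwise_dissimilarity <- function(bins) {
  sel <- select_set_photos(bins)
  excluded <- setdiff(unique(bins$set_id), unique(sel$set_id))
  if (length(excluded)) {
    message(length(excluded), " set(s) excluded: no usable photograph")
  }
  sets <- sel |>
    group_by(.data$set_id) |>
    summarise(individual_id = .data$individual_id[1],
              set_quality = if (all(.data$quality == "high")) "high"
                            else "low") |>
    arrange(.data$set_id)
  if (nrow(sets) < 2) {
    stop("fewer than two usable sets; nothing to compare")
  }
  # cache black pixels and distance transforms per selected photo
  key <- paste(sel$set_id, sel$side)
  cache <- setNames(map(sel$bin, function(b) {
    list(px = b$pixels, dist = distance_to_black(b$pixels))
  }), key)
  pair_idx <- combn(nrow(sets), 2)
  rows <- map(seq_len(ncol(pair_idx)), function(k) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    sa <- sets$set_id[i]; sb <- sets$set_id[j]
    shared <- intersect(sel$side[sel$set_id == sa], sel$side[sel$set_id == sb])
    vals <- map_dbl(shared, function(s) {
      ca <- cache[[paste(sa, s)]]; cb <- cache[[paste(sb, s)]]
      (directed_chamfer(ca$px, cb$dist) + directed_chamfer(cb$px, ca$dist)) / 2
    })
    if (length(vals) == 0 || all(is.na(vals))) {
      d <- NA_real_; side_used <- NA_character_; status <- "incomparable"
    } else {
      w <- which.min(vals)
      d <- vals[w]; side_used <- shared[w]; status <- "ok"
    }
    tibble(set_a = sa, set_b = sb,
           individual_a = sets$individual_id[i],
           individual_b = sets$individual_id[j],
           truth = if (sets$individual_id[i] == sets$individual_id[j])
             "same" else "different",
           side_used = side_used, dissimilarity = d,
           quality_group = if (sets$set_quality[i] == "high" &&
                               sets$set_quality[j] == "high") "high"
                           else "low",
           status = status)
  })
  out <- bind_rows(rows)
  attr(out, "excluded_sets") <- excluded
  out
}
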