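# Whisker-spot image pipeline: crop + binarize the warped photograph, then
# remove sub-threshold specks so isolated noise pixels never enter the
# Chamfer comparison.

new_binary_spot_image <- function(pixels, grid, photo_id = NA_character_,
                                  side = NA_character_, empty = !any(pixels)) {
  structure(list(pixels = pixels, grid = grid, photo_id = photo_id,
                 side = side, empty = empty),
            class = "binary_spot_image")
}

#' @export
print.binary_spot_image <- function(x, ...) {
  cat(sprintf("<binary_spot_image> %s (%s), %d x %d px, %d black pixels%s\n",
              x$photo_id, x$side, ncol(x$pixels), nrow(x$pixels),
              sum(x$pixels), if (x$empty) " [empty]" else ""))
  invisible(x)
}

# Local mean over a w x w window, windows clipped at the borders, via
# integral images; exact, no padding artefacts.
local_mean <- function(m, w) {
  h <- nrow(m); wd <- ncol(m); r <- floor(w / 2)
  P <- matrix(0, h + 1, wd + 1)
  P[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  rows <- seq_len(h); cols <- seq_len(wd)
  r0 <- pmax(rows - r, 1); r1 <- pmin(rows + r, h)
  c0 <- pmax(cols - r, 1); c1 <- pmin(cols + r, wd)
  R0 <- matrix(r0, h, wd); R1 <- matrix(r1, h, wd)
  C0 <- matrix(c0, h, wd, byrow = TRUE); C1 <- matrix(c1, h, wd, byrow = TRUE)
  s <- P[cbind(c(R1 + 1), c(C1 + 1))] - P[cbind(c(R0), c(C1 + 1))] -
    P[cbind(c(R1 + 1), c(C0))] + P[cbind(c(R0), c(C0))]
  cnt <- (R1 - R0 + 1) * (C1 - C0 + 1)
  matrix(s, h, wd) / cnt
}

#' Binarize the whisker-spot region of a warped photograph
#'
#' Crops the standard grid's whisker window and thresholds it so that dark
#' pixels (spots) become `TRUE`. The default is a local adaptive mean
#' threshold, robust to illumination gradients; a global percentile
#' threshold is available as a fallback for flat lighting.
#'
#' @param warped Numeric matrix from [warp_to_grid()], grid dimensions.
#' @param grid The [standard_grid()] used for warping.
#' @param method `"adaptive"` (pixel black when darker than the local mean
#'   minus `offset`) or `"percentile"` (black when below the `percentile`
#'   quantile of the crop).
#' @param window Side length of the adaptive window, pixels.
#' @param offset Grey-level offset below the local mean.
#' @param percentile Quantile for the percentile method.
#' @param photo_id,side Carried through as provenance.
#' @return A `binary_spot_image` (pre-denoising). A zero-variance crop
#'   yields an empty image flagged via `$empty`, not an error.
#' @export
binarize_whisker_region <- function(warped, grid = standard_grid(),
                                    method = c("adaptive", "percentile"),
                                    window = 15, offset = 25,
                                    percentile = 0.05,
                                    photo_id = NA_character_,
                                    side = NA_character_) {
  method <- match.arg(method)
  stopifnot(nrow(warped) == grid$height, ncol(warped) == grid$width)
  cw <- grid$crop_window
  crop <- warped[(cw[["y0"]] + 1):(cw[["y1"]] + 1),
                 (cw[["x0"]] + 1):(cw[["x1"]] + 1), drop = FALSE]
  if (max(crop) - min(crop) < .Machine$double.eps^0.5) {
    return(new_binary_spot_image(matrix(FALSE, nrow(crop), ncol(crop)),
                                 grid, photo_id, side, empty = TRUE))
  }
  px <- if (method == "adaptive") {
    crop < local_mean(crop, window) - offset
  } else {
    crop < quantile(crop, percentile)
  }
  new_binary_spot_image(px, grid, photo_id, side)
}

# 8- (or 4-) connected components over the black pixels; returns integer
# labels per black pixel plus component sizes.
label_components <- function(px, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  idx <- which(px)
  if (length(idx) == 0) {
    return(list(index = integer(0), label = integer(0), sizes = integer(0)))
  }
  h <- nrow(px); w <- ncol(px)
  rr <- ((idx - 1) %% h) + 1
  cc <- ((idx - 1) %/% h) + 1
  offs <- list(c(-1, 0), c(0, -1))
  if (connectivity == 8) offs <- c(offs, list(c(-1, -1), c(-1, 1)))
  vid <- match(idx, idx)
  edges <- NULL
  black <- matrix(FALSE, h, w); black[idx] <- TRUE
  for (o in offs) {
    nr <- rr + o[1]; nc <- cc + o[2]
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
    nidx <- (nc - 1) * h + nr
    ok[ok] <- black[nidx[ok]]
    if (any(ok)) {
      edges <- rbind(edges, cbind(vid[ok], match(nidx[ok], idx)))
    }
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(0), ncol = 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(index = idx, label = comp$membership, sizes = unname(comp$csize))
}

#' Remove small connected components ("isolated black spots")
#'
#' Filters unwanted noise from a binarized whisker image by deleting every
#' connected component with fewer than `min_component_size` black pixels
#' (default 2, i.e. single isolated pixels are removed). Components are
#' 8-connected by default so a diagonal 2-pixel speck counts as one
#' component of size 2 and survives. Idempotent.
#'
#' @param binary A `binary_spot_image` or logical matrix.
#' @param min_component_size Components smaller than this are removed.
#' @param connectivity 8 (default) or 4.
#' @return Same type as the input, with small components removed.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[1, 1] <- TRUE; m[3, 3:4] <- TRUE
#' sum(denoise_spots(m)) # the isolated pixel is gone, the pair survives
#' @export
denoise_spots <- function(binary, min_component_size = 2, connectivity = 8) {
  is_bsi <- inherits(binary, "binary_spot_image")
  px <- if (is_bsi) binary$pixels else binary
  stopifnot(is.logical(px), is.matrix(px))
  lab <- label_components(px, connectivity)
  if (length(lab$index)) {
    drop <- lab$sizes[lab$label] < min_component_size
    px[lab$index[drop]] <- FALSE
  }
  if (is_bsi) {
    binary$pixels <- px
    binary$empty <- !any(px)
    binary
  } else {
    px
  }
}

#' Count whisker spots (connected components) in a binary image
#'
#' @param binary A `binary_spot_image` or logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer component count.
#' @export
count_spots <- function(binary, connectivity = 8) {
  px <- if (inherits(binary, "binary_spot_image")) binary$pixels else binary
  length(label_components(px, connectivity)$sizes)
}

#' Process one photograph to a binary spot image
#'
#' Convenience chain: [warp_to_grid()], [binarize_whisker_region()],
#' [denoise_spots()].
#'
#' @param image Grey-level matrix.
#' @param lm [landmarks()] of the photograph.
#' @param grid A [standard_grid()].
#' @param method,window,offset,percentile Passed to
#'   [binarize_whisker_region()].
#' @param min_component_size,connectivity Passed to [denoise_spots()].
#' @param photo_id,side Provenance.
#' @return A denoised `binary_spot_image`.
#' @export
process_photo <- function(image, lm, grid = standard_grid(),
                          method = "adaptive", window = 15, offset = 25,
                          percentile = 0.05, min_component_size = 2,
                          connectivity = 8, photo_id = NA_character_,
                          side = NA_character_) {
  warped <- warp_to_grid(image, lm, grid)
  bin <- binarize_whisker_region(warped, grid, method, window, offset,
                                 percentile, photo_id = photo_id, side = side)
  denoise_spots(bin, min_component_size, connectivity)
}

#' Process a photo table to binary spot images
#'
#' Applies [process_photo()] to every usable photograph of a
#' [render_study_photos()]-shaped tibble; unusable photographs (quality
#' `"unsuitable"`) get a `NULL` entry.
#'
#' @param photos Tibble with `photo_id`, `set_id`, `side`, `quality`,
#'   `usable`, list-columns `image`, `landmarks`.
#' @param ... Passed to [process_photo()].
#' @inheritParams process_photo
#' @return The input tibble with a `bin` list-column added.
#' @export
process_photos <- function(photos, grid = standard_grid(), ...) {
  photos$bin <- pmap(
    list(photos$image, photos$landmarks, photos$photo_id, photos$side,
         photos$usable),
    function(img, lm, id, side, usable) {
      if (!usable) return(NULL)
      process_photo(img, lm, grid, photo_id = id, side = side, ...)
    })
  photos
}
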