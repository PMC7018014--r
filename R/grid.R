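# Standard pixel grid and three-point affine registration.
#
# Photographs are registered by mapping three facial reference points --
# the corner of the eye, the notch of the nose and the trailing edge of the
# mouth -- onto fixed target positions in a standard grid, then cropping
# the whisker-spot region from the warped image.

#' Construct a landmark triple
#'
#' @param eye,nose_notch,mouth_trailing_edge Numeric `(x, y)` pairs in pixel
#'   coordinates (0-based, origin top-left).
#' @return A 3 x 2 numeric matrix with one row per landmark.
#' @examples
#' landmarks(c(176, 64), c(80, 120), c(144, 208))
#' @export
landmarks <- function(eye, nose_notch, mouth_trailing_edge) {
  lm <- rbind(eye = as.numeric(eye),
              nose_notch = as.numeric(nose_notch),
              mouth_trailing_edge = as.numeric(mouth_trailing_edge))
  colnames(lm) <- c("x", "y")
  stopifnot(ncol(lm) == 2, all(is.finite(lm)))
  lm
}

landmarks_collinear <- function(lm, tol = 1e-8) {
  v1 <- lm[2, ] - lm[1, ]
  v2 <- lm[3, ] - lm[1, ]
  abs(v1[1] * v2[2] - v1[2] * v2[1]) < tol * max(1, sum(abs(v1)), sum(abs(v2)))
}

#' Define the standard pixel grid
#'
#' The grid fixes the image dimensions every photograph is warped onto, the
#' target positions of the three facial landmarks, and the rectangular crop
#' window delimiting the whisker-spot region of the muzzle. The defaults
#' (256 x 256 grid) give a resolution comparable to a telephoto head crop;
#' all values are configurable.
#'
#' @param width,height Grid dimensions in pixels.
#' @param target_landmarks A [landmarks()] matrix inside the grid.
#' @param crop_window Integer vector `(x0, y0, x1, y1)`, inclusive 0-based
#'   pixel bounds of the whisker region within the grid.
#' @return An object of class `standard_grid`.
#' @examples
#' standard_grid()
#' @export
standard_grid <- function(width = 256, height = 256,
                          target_landmarks = landmarks(
                            eye = c(176, 64),
                            nose_notch = c(80, 120),
                            mouth_trailing_edge = c(144, 208)),
                          crop_window = c(x0 = 48, y0 = 112,
                                          x1 = 207, y1 = 211)) {
  stopifnot(width > 0, height > 0, length(crop_window) == 4)
  crop_window <- as.integer(crop_window)
  names(crop_window) <- c("x0", "y0", "x1", "y1")
  if (landmarks_collinear(target_landmarks)) {
    stop("target landmarks are collinear; the affine map is ill-posed")
  }
  inside <- all(target_landmarks[, 1] >= 0, target_landmarks[, 1] < width,
                target_landmarks[, 2] >= 0, target_landmarks[, 2] < height)
  if (!inside) stop("target landmarks must lie inside the grid")
  if (crop_window["x0"] < 0 || crop_window["y0"] < 0 ||
      crop_window["x1"] >= width || crop_window["y1"] >= height ||
      crop_window["x0"] > crop_window["x1"] ||
      crop_window["y0"] > crop_window["y1"]) {
    stop("crop_window must be a non-empty rectangle inside the grid")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 target_landmarks = target_landmarks,
                 crop_window = crop_window),
            class = "standard_grid")
}

#' @export
print.standard_grid <- function(x, ...) {
  cat(sprintf("<standard_grid> %d x %d px, crop [%d..%d] x [%d..%d]\n",
              x$width, x$height, x$crop_window["x0"], x$crop_window["x1"],
              x$crop_window["y0"], x$crop_window["y1"]))
  invisible(x)
}

crop_dims <- function(grid) {
  c(height = unname(grid$crop_window["y1"] - grid$crop_window["y0"] + 1L),
    width = unname(grid$crop_window["x1"] - grid$crop_window["x0"] + 1L))
}

#' Solve the affine map sending three source points to three targets
#'
#' @param src,dst 3 x 2 matrices of `(x, y)` points.
#' @return A 3 x 2 coefficient matrix `C` such that
#'   `cbind(x, y, 1) %*% C` maps source points to destination points.
#' @export
solve_affine <- function(src, dst) {
  src <- unname(as.matrix(src)); dst <- unname(as.matrix(dst))
  stopifnot(dim(src) == c(3, 2), dim(dst) == c(3, 2))
  if (landmarks_collinear(src)) {
    stop("source landmarks are collinear; the affine map is ill-posed")
  }
  solve(cbind(src, 1), dst)
}

#' Apply an affine coefficient matrix to points
#'
#' @param points An n x 2 matrix of `(x, y)` points.
#' @param coef A 3 x 2 coefficient matrix from [solve_affine()].
#' @return An n x 2 matrix of mapped points.
#' @export
apply_affine <- function(points, coef) {
  points <- matrix(as.numeric(points), ncol = 2)
  out <- cbind(points, 1) %*% coef
  colnames(out) <- c("x", "y")
  out
}

#' Warp a photograph onto the standard grid
#'
#' Solves the unique affine map taking the photograph's three landmarks to
#' the grid's target landmarks and resamples the image onto the grid by
#' inverse mapping. Pixels mapping outside the source image are filled with
#' `fill` (white background by default).
#'
#' @param image Numeric matrix, grey levels in `[0, 255]` (rows = y).
#' @param lm A [landmarks()] matrix giving the three reference points in
#'   the photograph.
#' @param grid A [standard_grid()].
#' @param interpolation `"bilinear"` (default, for grey-level photographs)
#'   or `"nearest"`.
#' @param fill Grey level used outside the source image.
#' @return A numeric `grid$height` x `grid$width` matrix.
#' @export
warp_to_grid <- function(image, lm, grid = standard_grid(),
                         interpolation = c("bilinear", "nearest"),
                         fill = 255) {
  interpolation <- match.arg(interpolation)
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0)
  if (landmarks_collinear(lm)) {
    stop("photo landmarks are collinear; the affine map is ill-posed")
  }
  h <- nrow(image); w <- ncol(image)
  if (any(lm[, 1] < 0 | lm[, 1] > w - 1 | lm[, 2] < 0 | lm[, 2] > h - 1)) {
    warning("landmarks fall outside the image bounds; proceeding")
  }
  inv <- solve_affine(grid$target_landmarks, lm)
  gx <- rep(seq_len(grid$width) - 1, each = grid$height)
  gy <- rep(seq_len(grid$height) - 1, times = grid$width)
  src <- apply_affine(cbind(gx, gy), inv)
  sx <- src[, 1]; sy <- src[, 2]
  out <- rep(as.numeric(fill), length(sx))
  if (interpolation == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix <= w - 1 & iy >= 0 & iy <= h - 1
    out[ok] <- image[cbind(iy[ok] + 1, ix[ok] + 1)]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- x0 >= 0 & x0 <= w - 1 & y0 >= 0 & y0 <= h - 1
    # clamp all four neighbour indices into the image; non-ok pixels are
    # masked afterwards, and the +1 neighbour interpolates flat at the border
    x0c <- pmin(pmax(x0, 0), w - 1); y0c <- pmin(pmax(y0, 0), h - 1)
    x1c <- pmin(x0c + 1, w - 1); y1c <- pmin(y0c + 1, h - 1)
    v <- (1 - fx) * (1 - fy) * image[cbind(y0c + 1, x0c + 1)] +
      fx * (1 - fy) * image[cbind(y0c + 1, x1c + 1)] +
      (1 - fx) * fy * image[cbind(y1c + 1, x0c + 1)] +
      fx * fy * image[cbind(y1c + 1, x1c + 1)]
    out[ok] <- v[ok]
  }
  matrix(out, nrow = grid$height, ncol = grid$width)
}
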