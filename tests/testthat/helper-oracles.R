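# Independent brute-force oracles; deliberately naive, never shared with
# the implementation code paths they check.

# mean nearest-neighbour distance A -> B by a double loop over black pixels
brute_directed_chamfer <- function(a, b) {
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  total <- 0
  for (i in seq_len(nrow(pa))) {
    best <- Inf
    for (j in seq_len(nrow(pb))) {
      d <- sqrt((pa[i, 1] - pb[j, 1])^2 + (pa[i, 2] - pb[j, 2])^2)
      if (d < best) best <- d
    }
    total <- total + best
  }
  unname(total / nrow(pa))
}

brute_chamfer <- function(a, b) {
  (brute_directed_chamfer(a, b) + brute_directed_chamfer(b, a)) / 2
}

# exhaustive threshold sweep: confusion rates at every candidate threshold
brute_roc <- function(d, truth) {
  ths <- c(-Inf, sort(unique(d)), Inf)
  data.frame(
    threshold = ths,
    fpr = sapply(ths, function(t) {
      dd <- d[truth == "different"]; sum(dd < t) / length(dd)
    }),
    fnr = sapply(ths, function(t) {
      ds <- d[truth == "same"]; sum(ds >= t) / length(ds)
    })
  )
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}

# exact expected FPR/FNR of the permutation null by full enumeration
enum_null <- function(individual_ids) {
  k <- length(individual_ids)
  m <- outer(individual_ids, individual_ids, `==`)
  ut <- upper.tri(m)
  fpr <- c(); fnr <- c()
  for (p in all_perms(k)) {
    mp <- m[p, p]
    t_same <- m[ut]; r_same <- mp[ut]
    fp <- sum(!t_same & r_same); tn <- sum(!t_same & !r_same)
    fn <- sum(t_same & !r_same); tp <- sum(t_same & r_same)
    fpr <- c(fpr, if (fp + tn > 0) fp / (fp + tn) else NA)
    fnr <- c(fnr, if (tp + fn > 0) fn / (tp + fn) else NA)
  }
  c(fpr = mean(fpr, na.rm = TRUE), fnr = mean(fnr, na.rm = TRUE))
}

# small grid + fast configs for image tests
small_grid <- function() {
  standard_grid(width = 128, height = 128,
                target_landmarks = landmarks(c(88, 32), c(40, 60),
                                             c(72, 104)),
                crop_window = c(24, 56, 103, 105))
}

small_spot_config <- function(...) {
  spot_config(n_spots_range = c(10, 18), spot_radius = 3,
              min_separation = 8, ...)
}

# exact rendering: no pose, no degradation; binarization must round-trip
noiseless_render_config <- function() {
  render_config(
    affine = list(rotate_deg = 0, log_scale = 0, shear = 0,
                  translate_px = 0),
    quality = list(high = list(blur_sigma = 0, noise_sd = 0, jitter_sd = 0),
                   low = list(blur_sigma = 0, noise_sd = 0, jitter_sd = 0),
                   unsuitable = list(blur_sigma = 0, noise_sd = 0,
                                     jitter_sd = 0)),
    gradient = 0)
}

# pixel set of ideal disks for a pattern, within the crop window
ideal_disk_pixels <- function(pattern, grid) {
  cw <- grid$crop_window
  h <- cw[["y1"]] - cw[["y0"]] + 1; w <- cw[["x1"]] - cw[["x0"]] + 1
  px <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(pattern$spots))) {
    cx <- pattern$spots[i, 1]; cy <- pattern$spots[i, 2]
    for (x in floor(cx - 4):ceiling(cx + 4)) {
      for (y in floor(cy - 4):ceiling(cy + 4)) {
        if ((x - cx)^2 + (y - cy)^2 <= pattern$spot_radius^2 &&
            x >= cw[["x0"]] && x <= cw[["x1"]] &&
            y >= cw[["y0"]] && y <= cw[["y1"]]) {
          px[y - cw[["y0"]] + 1, x - cw[["x0"]] + 1] <- TRUE
        }
      }
    }
  }
  px
}

quiet <- function(expr) suppressMessages(expr)
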