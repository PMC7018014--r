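# Synthetic study generator.
#
# Emulates the inputs of a captive-bear identification experiment: 15
# individuals photographed on up to three occasions (43 photo sets), five
# trials of 15 sets drawn without replacement with 10-11 distinct
# individuals each, muzzle photographs of controlled quality, and test
# observers with group-specific error probabilities. Every generator is a
# pure function of its inputs and a seed; per-entity child seeds are derived
# with child_seed() so adding an entity never perturbs the others.

#' Spot-pattern generator configuration
#'
#' @param n_spots_range Integer range for the number of whisker spots per
#'   side. Not a measured quantity; the default keeps patterns individually
#'   distinctive while dense enough that Chamfer matching is nontrivial.
#' @param spot_radius Disk radius of a rendered spot, pixels.
#' @param min_separation Minimum centre-to-centre distance between spots,
#'   pixels; must be at least `2 * spot_radius` so disks never merge.
#' @param region Placement rectangle `(x0, y0, x1, y1)` in standard-grid
#'   coordinates, or `NULL` to inset the grid's crop window by
#'   `spot_radius + 2`.
#' @param max_attempts Rejection-sampling budget per pattern.
#' @return A list of class `spot_config`.
#' @export
spot_config <- function(n_spots_range = c(15, 40), spot_radius = 3,
                        min_separation = 8, region = NULL,
                        max_attempts = 10000) {
  stopifnot(length(n_spots_range) == 2, n_spots_range[1] >= 1,
            n_spots_range[1] <= n_spots_range[2],
            spot_radius > 0, min_separation >= 2 * spot_radius)
  structure(list(n_spots_range = as.integer(n_spots_range),
                 spot_radius = spot_radius,
                 min_separation = min_separation,
                 region = region, max_attempts = max_attempts),
            class = "spot_config")
}

default_spot_region <- function(grid, config) {
  if (!is.null(config$region)) return(config$region)
  m <- ceiling(config$spot_radius) + 2
  cw <- grid$crop_window
  c(x0 = cw[["x0"]] + m, y0 = cw[["y0"]] + m,
    x1 = cw[["x1"]] - m, y1 = cw[["y1"]] - m)
}

#' Generate one whisker-spot pattern
#'
#' Places spot centres by uniform rejection sampling inside the whisker
#' region with a minimum-separation constraint.
#'
#' @param side `"left"` or `"right"`.
#' @param seed Integer seed; the pattern is a pure function of
#'   `(side, seed, config, grid)`.
#' @param config A [spot_config()].
#' @param grid A [standard_grid()].
#' @return A `spot_pattern`: list with `side`, `spots` (n x 2 matrix of
#'   `(x, y)` centres) and `spot_radius`.
#' @export
sim_spot_pattern <- function(side = c("left", "right"), seed = 1,
                             config = spot_config(), grid = standard_grid()) {
  side <- match.arg(side)
  region <- default_spot_region(grid, config)
  if (region[["x1"]] - region[["x0"]] < config$min_separation ||
      region[["y1"]] - region[["y0"]] < config$min_separation) {
    stop("spot region is too small for the requested minimum separation")
  }
  with_seed(seed, {
    n <- sample(seq(config$n_spots_range[1], config$n_spots_range[2]), 1)
    pts <- matrix(numeric(0), ncol = 2)
    attempts <- 0
    while (nrow(pts) < n) {
      attempts <- attempts + 1
      if (attempts > config$max_attempts) {
        stop(sprintf(
          "could not place %d spots with separation %.1f in the region (%d placed)",
          n, config$min_separation, nrow(pts)))
      }
      p <- c(runif(1, region[["x0"]], region[["x1"]]),
             runif(1, region[["y0"]], region[["y1"]]))
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >=
          config$min_separation) {
        pts <- rbind(pts, p)
      }
    }
    dimnames(pts) <- list(NULL, c("x", "y"))
    structure(list(side = side, spots = pts,
                   spot_radius = config$spot_radius),
              class = "spot_pattern")
  })
}

#' @export
print.spot_pattern <- function(x, ...) {
  cat(sprintf("<spot_pattern> %s side, %d spots, radius %.1f px\n",
              x$side, nrow(x$spots), x$spot_radius))
  invisible(x)
}

#' Generate a population of individuals
#'
#' Each individual carries an independent left and right whisker-spot
#' pattern drawn from per-individual child seeds.
#'
#' @param n_individuals Number of individuals (study default 15).
#' @param seed Study seed.
#' @param config A [spot_config()].
#' @param grid A [standard_grid()].
#' @return A tibble with columns `individual_id`, `sex`, `pattern_left`,
#'   `pattern_right` (list-columns of `spot_pattern`).
#' @examples
#' bears <- sim_individuals(3, seed = 1)
#' bears$pattern_left[[1]]
#' @export
sim_individuals <- function(n_individuals = 15, seed = 1,
                            config = spot_config(), grid = standard_grid()) {
  stopifnot(n_individuals >= 1)
  ids <- sprintf("bear%02d", seq_len(n_individuals))
  sex <- with_seed(child_seed(seed, "sex"),
                   sample(c("male", "female"), n_individuals, replace = TRUE))
  tibble(
    individual_id = ids,
    sex = sex,
    pattern_left = map(ids, function(id) {
      sim_spot_pattern("left", child_seed(seed, id, "left"), config, grid)
    }),
    pattern_right = map(ids, function(id) {
      sim_spot_pattern("right", child_seed(seed, id, "right"), config, grid)
    })
  )
}

#' Generate the pool of photo sets (occasions)
#'
#' A set is all photographs of one bear from one photography occasion. The
#' default gives three occasions for all but the last individual and one
#' for the last, i.e. 43 sets for 15 individuals. Occasion dates are
#' generated as metadata with a mean spacing of 25 days; no computation
#' uses them.
#'
#' @param individuals Tibble from [sim_individuals()].
#' @param seed Study seed.
#' @param occasions Integer vector of occasions per individual, recycled.
#' @param mean_spacing_days Mean gap between successive occasions.
#' @return A tibble with `set_id`, `individual_id`, `occasion`, `date`.
#' @export
sim_photo_sets <- function(individuals, seed = 1,
                           occasions = c(rep(3, nrow(individuals) - 1), 1),
                           mean_spacing_days = 25) {
  occasions <- rep_len(occasions, nrow(individuals))
  stopifnot(all(occasions >= 1))
  sets <- tibble(
    individual_id = rep(individuals$individual_id, occasions),
    occasion = unlist(lapply(occasions, seq_len))
  )
  sets$set_id <- sprintf("%s_s%d", sets$individual_id, sets$occasion)
  gaps <- with_seed(child_seed(seed, "dates"),
                    stats::rexp(nrow(sets), rate = 1 / mean_spacing_days))
  start <- as.Date("2026-01-01")
  sets <- sets |>
    group_by(.data$individual_id) |>
    mutate(date = start + round(cumsum(gaps[dplyr::cur_group_rows()]))) |>
    ungroup()
  sets[, c("set_id", "individual_id", "occasion", "date")]
}

#' Compose trials from a pool of sets
#'
#' Each trial presents `n_sets` sets drawn randomly without replacement
#' from the pool; a draw is rejected unless the number of distinct
#' individuals falls in `distinct_range` (the experimental design held it
#' at 10 or 11). Trials are independent, so the same set may appear in
#' several trials.
#'
#' @param sets Pool tibble with `set_id` and `individual_id` (at most 3
#'   sets per individual).
#' @param n_trials Number of trials.
#' @param seed Study seed.
#' @param n_sets Sets per trial.
#' @param distinct_range Admissible range for distinct individuals per
#'   trial.
#' @param max_rejections Rejection budget per trial.
#' @return A tibble with `trial_id`, `set_id`, `individual_id`.
#' @export
sim_trials <- function(sets, n_trials = 5, seed = 1, n_sets = 15,
                       distinct_range = c(10, 11), max_rejections = 1000) {
  stopifnot(nrow(sets) >= n_sets)
  per_ind <- table(sets$individual_id)
  if (any(per_ind > 3)) {
    stop("pool violates the design: more than 3 sets for ",
         paste(names(per_ind)[per_ind > 3], collapse = ", "))
  }
  one_trial <- function(trial_id) {
    with_seed(child_seed(seed, trial_id), {
      for (i in seq_len(max_rejections)) {
        idx <- sample(nrow(sets), n_sets)
        k <- length(unique(sets$individual_id[idx]))
        if (k >= distinct_range[1] && k <= distinct_range[2]) {
          return(tibble(trial_id = trial_id,
                        set_id = sets$set_id[sort(idx)],
                        individual_id = sets$individual_id[sort(idx)]))
        }
      }
      stop(sprintf(
        "trial %s: no draw with %d-%d distinct individuals in %d attempts",
        trial_id, distinct_range[1], distinct_range[2], max_rejections))
    })
  }
  bind_rows(lapply(sprintf("trial%d", seq_len(n_trials)), one_trial))
}

#' Rendering configuration
#'
#' Maps each quality label to a degradation triple (Gaussian blur sigma,
#' additive pixel noise SD on the 8-bit scale, landmark/spot jitter SD in
#' pixels), monotone in degradation, and sets the range of the random
#' affine pose perturbation. Poor light in the source material produced
#' blurry or grainy photographs; the `low` and `unsuitable` triples emulate
#' that.
#'
#' @param affine List with `rotate_deg`, `log_scale`, `shear`,
#'   `translate_px`: half-widths of the uniform pose perturbation.
#' @param quality Named list of `high`, `low`, `unsuitable` triples, each a
#'   list with `blur_sigma`, `noise_sd`, `jitter_sd`.
#' @param background,spot_value Grey levels of fur background and spot
#'   disks. The default contrast is moderate (dark grey pigment on pale
#'   fur), so blurring genuinely erodes spot detectability.
#' @param gradient Amplitude of a random linear illumination gradient.
#' @return A list of class `render_config`.
#' @export
render_config <- function(
    affine = list(rotate_deg = 8, log_scale = 0.08, shear = 0.05,
                  translate_px = 8),
    quality = list(
      high = list(blur_sigma = 0.8, noise_sd = 4, jitter_sd = 0.5),
      low = list(blur_sigma = 2.0, noise_sd = 12, jitter_sd = 1.5),
      unsuitable = list(blur_sigma = 3.0, noise_sd = 20, jitter_sd = 3.0)),
    background = 210, spot_value = 120, gradient = 12) {
  stopifnot(all(c("high", "low", "unsuitable") %in% names(quality)))
  for (p in c("blur_sigma", "noise_sd", "jitter_sd")) {
    v <- vapply(quality[c("high", "low", "unsuitable")], `[[`, numeric(1), p)
    if (is.unsorted(v)) {
      stop(sprintf("quality parameter %s must be monotone in degradation", p))
    }
  }
  stopifnot(background > spot_value)
  structure(list(affine = affine, quality = quality, background = background,
                 spot_value = spot_value, gradient = gradient),
            class = "render_config")
}

draw_pose <- function(affine, centre) {
  theta <- runif(1, -affine$rotate_deg, affine$rotate_deg) * pi / 180
  s <- exp(runif(1, -affine$log_scale, affine$log_scale))
  k <- runif(1, -affine$shear, affine$shear)
  t <- runif(2, -affine$translate_px, affine$translate_px)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  lin <- s * rot %*% matrix(c(1, 0, k, 1), 2, 2)
  offset <- centre - as.numeric(lin %*% centre) + t
  # 3 x 2 coefficient matrix, same layout as solve_affine()
  rbind(t(lin), offset)
}

draw_disks <- function(image, centres, radius, value) {
  h <- nrow(image); w <- ncol(image)
  r <- ceiling(radius)
  for (i in seq_len(nrow(centres))) {
    cx <- centres[i, 1]; cy <- centres[i, 2]
    xs <- max(0, floor(cx) - r):min(w - 1, ceiling(cx) + r)
    ys <- max(0, floor(cy) - r):min(h - 1, ceiling(cy) + r)
    if (length(xs) == 0 || length(ys) == 0) next
    gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
    hit <- (gx - cx)^2 + (gy - cy)^2 <= radius^2
    image[cbind(gy[hit] + 1, gx[hit] + 1)] <- value
  }
  image
}

gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  # isotropic, so the [y, x] layout is immaterial to EBImage's [x, y]
  EBImage::imageData(EBImage::gblur(EBImage::Image(image / 255),
                                    sigma = sigma)) * 255
}

#' Render a synthetic muzzle photograph
#'
#' Draws the individual's whisker spots as dark disks on a light background
#' after a random affine pose perturbation, adds an illumination gradient,
#' Gaussian blur and pixel noise according to the quality level, and
#' returns the photograph together with its annotated landmarks (the true
#' facial landmarks under the same pose, plus annotation jitter).
#'
#' @param individual One row of [sim_individuals()], or a `spot_pattern`.
#' @param side `"left"` or `"right"` (ignored when a `spot_pattern` is
#'   given).
#' @param quality `"high"`, `"low"` or `"unsuitable"`. Quality is a label
#'   assigned by the generator, mirroring subjective photo grading; it is
#'   an input to downstream grouping, never re-derived from pixels.
#' @param seed Integer seed.
#' @param config A [render_config()].
#' @param grid A [standard_grid()].
#' @return A `synthetic_photo`: list with `image` (matrix, grey `[0,255]`),
#'   `landmarks` (annotated), `landmarks_true`, `spots_true` (spot centres
#'   in photo coordinates), `side`, `quality`, `usable`.
#' @export
render_photo <- function(individual, side = c("left", "right"),
                         quality = c("high", "low", "unsuitable"), seed = 1,
                         config = render_config(), grid = standard_grid()) {
  side <- match.arg(side)
  quality <- match.arg(quality)
  if (inherits(individual, "spot_pattern")) {
    pattern <- individual
    side <- pattern$side
  } else {
    stopifnot(nrow(individual) == 1)
    pattern <- individual[[paste0("pattern_", side)]][[1]]
  }
  qp <- config$quality[[quality]]
  with_seed(seed, {
    centre <- c((grid$width - 1) / 2, (grid$height - 1) / 2)
    pose <- draw_pose(config$affine, centre)
    jit <- matrix(rnorm(length(pattern$spots), 0, qp$jitter_sd),
                  ncol = 2)
    spots_photo <- apply_affine(pattern$spots + jit, pose)
    img <- matrix(config$background, grid$height, grid$width)
    if (config$gradient > 0) {
      ang <- runif(1, 0, 2 * pi)
      gx <- rep(seq_len(grid$width) - 1, each = grid$height)
      gy <- rep(seq_len(grid$height) - 1, times = grid$width)
      proj <- (gx * cos(ang) + gy * sin(ang)) /
        sqrt(grid$width^2 + grid$height^2)
      img <- img + matrix(config$gradient * (proj - mean(proj)) * 2,
                          grid$height, grid$width)
    }
    img <- draw_disks(img, spots_photo, pattern$spot_radius,
                      config$spot_value)
    img <- gaussian_blur(img, qp$blur_sigma)
    if (qp$noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), 0, qp$noise_sd),
                          nrow(img), ncol(img))
    }
    img <- pmin(pmax(img, 0), 255)
    lm_true <- apply_affine(grid$target_landmarks, pose)
    rownames(lm_true) <- rownames(grid$target_landmarks)
    lm_ann <- lm_true + matrix(rnorm(6, 0, qp$jitter_sd), 3, 2)
    rownames(lm_ann) <- rownames(lm_true)
    structure(list(image = img, landmarks = lm_ann,
                   landmarks_true = lm_true, spots_true = spots_photo,
                   side = side, quality = quality,
                   usable = quality != "unsuitable"),
              class = "synthetic_photo")
  })
}

#' @export
print.synthetic_photo <- function(x, ...) {
  cat(sprintf("<synthetic_photo> %s side, %s quality, %d x %d px%s\n",
              x$side, x$quality, ncol(x$image), nrow(x$image),
              if (x$usable) "" else " (landmarks unusable)"))
  invisible(x)
}

#' Render photographs for every set in a pool
#'
#' Assigns each set a quality label (both sides share it) with the study's
#' observed proportions by default, then renders one left and one right
#' photograph per set.
#'
#' @param sets Tibble from [sim_photo_sets()] or [sim_trials()] (one row
#'   per set; duplicates are collapsed).
#' @param individuals Tibble from [sim_individuals()].
#' @param seed Study seed.
#' @param quality_probs Named probabilities for `high`, `low`,
#'   `unsuitable`.
#' @param config A [render_config()].
#' @param grid A [standard_grid()].
#' @return A tibble with `photo_id`, `set_id`, `individual_id`, `side`,
#'   `quality`, `usable`, and list-columns `image`, `landmarks`.
#' @export
render_study_photos <- function(sets, individuals, seed = 1,
                                quality_probs = c(high = 0.253, low = 0.414,
                                                  unsuitable = 0.333),
                                config = render_config(),
                                grid = standard_grid()) {
  sets <- distinct(sets, .data$set_id, .data$individual_id)
  stopifnot(all(sets$individual_id %in% individuals$individual_id))
  qual <- with_seed(child_seed(seed, "set_quality"),
                    sample(c("high", "low", "unsuitable"), nrow(sets),
                           replace = TRUE, prob = quality_probs))
  rows <- pmap(list(sets$set_id, sets$individual_id, qual),
               function(set_id, ind_id, q) {
    ind <- individuals[individuals$individual_id == ind_id, ]
    map(c("left", "right"), function(side) {
      ph <- render_photo(ind, side, q,
                         seed = child_seed(seed, set_id, side), config, grid)
      tibble(photo_id = sprintf("%s_%s", set_id, side), set_id = set_id,
             individual_id = ind_id, side = side, quality = q,
             usable = ph$usable, image = list(ph$image),
             landmarks = list(ph$landmarks))
    })
  })
  bind_rows(unlist(rows, recursive = FALSE))
}

#' Define observer profiles
#'
#' Four observer types combine previous experience with polar bears and
#' training in photogrammetric techniques (study sizes 2/2/2/4). True error
#' probabilities depend on photogrammetric experience; defaults are the
#' fitted group rates of the identification experiment.
#'
#' @param n_bears_photo,n_photo_only,n_bears_only,n_none Observers per
#'   type.
#' @param rates_experienced,rates_inexperienced Named vectors
#'   `c(fpr = , fnr = )` of true error probabilities by photogrammetric
#'   experience.
#' @return A tibble with `observer_id`, `experience_photogrammetry`,
#'   `experience_bears`, `true_fpr`, `true_fnr`.
#' @export
sim_observers <- function(n_bears_photo = 2, n_photo_only = 2,
                          n_bears_only = 2, n_none = 4,
                          rates_experienced = c(fpr = 0.003, fnr = 0.130),
                          rates_inexperienced = c(fpr = 0.009, fnr = 0.719)) {
  photo <- c(rep(TRUE, n_bears_photo + n_photo_only),
             rep(FALSE, n_bears_only + n_none))
  bears <- c(rep(TRUE, n_bears_photo), rep(FALSE, n_photo_only),
             rep(TRUE, n_bears_only), rep(FALSE, n_none))
  tibble(
    observer_id = sprintf("obs%02d", seq_along(photo)),
    experience_photogrammetry = photo,
    experience_bears = bears,
    true_fpr = ifelse(photo, rates_experienced[["fpr"]],
                      rates_inexperienced[["fpr"]]),
    true_fnr = ifelse(photo, rates_experienced[["fnr"]],
                      rates_inexperienced[["fnr"]])
  )
}

#' Simulate observer ratings over a comparison table
#'
#' Each observer rates every comparison independently: a truth-`same` pair
#' is rated `"D"` with probability `true_fnr`, a truth-`different` pair is
#' rated `"S"` with probability `true_fpr`.
#'
#' @param comparisons A [build_comparison_table()] tibble.
#' @param observers A [sim_observers()] tibble (valid probabilities).
#' @param seed Study seed; each observer gets a child seed.
#' @return A long tibble with `observer_id`, `comparison_id`, `rating`.
#' @export
sim_ratings <- function(comparisons, observers, seed = 1) {
  stopifnot(all(observers$true_fpr >= 0 & observers$true_fpr <= 1),
            all(observers$true_fnr >= 0 & observers$true_fnr <= 1))
  bind_rows(pmap(
    list(observers$observer_id, observers$true_fpr, observers$true_fnr),
    function(obs, fpr, fnr) {
      with_seed(child_seed(seed, "ratings", obs), {
        err <- rbinom(nrow(comparisons), 1,
                      ifelse(comparisons$truth == "same", fnr, fpr)) == 1
        correct <- ifelse(comparisons$truth == "same", "S", "D")
        wrong <- ifelse(comparisons$truth == "same", "D", "S")
        tibble(observer_id = obs, comparison_id = comparisons$comparison_id,
               rating = ifelse(err, wrong, correct))
      })
    }))
}
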