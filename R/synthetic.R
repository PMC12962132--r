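#' Configuration for a synthetic territorial singing population
#'
#' The generator realizes the two locality assumptions by construction:
#' group centres are kept at least `min_center_spacing` apart (minimal
#' inter-individual distance) and a group's calls on any one day scatter
#' within `daily_site_radius` of that day's singing site (maximal
#' intra-individual distance). Daily sites wander within `homerange_radius`
#' of the group centre, emulating movement through a territory across days.
#'
#' Defaults emulate a small montane gibbon population: 6 family groups,
#' centres >= 1,600 m apart (the mean recorder spacing of a typical array)
#' in a 6 x 6 km arena, 500 m home-range radius, 100 m daily scatter, 30
#' days with on average 3 localized calls per group and day, and a 20
#' station grid.
#'
#' @param n_groups number of singing groups (>= 2).
#' @param arena `c(xmin, xmax, ymin, ymax)` in metres.
#' @param min_center_spacing minimal distance between group centres
#'   (metres).
#' @param homerange_radius radius of daily-site wander around the centre.
#' @param daily_site_radius within-day call scatter radius.
#' @param n_days number of days.
#' @param calls_per_group_day Poisson mean of calls per group and day.
#' @param overlap_fraction in \[0, 1\); relaxes the enforced centre spacing
#'   to `(1 - overlap_fraction) * min_center_spacing`, letting home-range
#'   polygons overlap.
#' @param prediction_q,prediction_p corruption parameters applied by
#'   [attach_predictions()].
#' @param timing_noise_sd arrival-time jitter (seconds) for
#'   [generate_tdoa()]; default 0.001 (millisecond-accurate GPS sync).
#' @param speed_of_sound metres per second for the TDOA forward model.
#' @param n_stations recorder stations laid out on a grid over the arena.
#' @param seed integer seed.
#' @return a list of class `population_config`.
#' @export
population_config <- function(n_groups = 6, arena = c(0, 6000, 0, 6000),
                              min_center_spacing = 1600,
                              homerange_radius = 500,
                              daily_site_radius = 100,
                              n_days = 30, calls_per_group_day = 3,
                              overlap_fraction = 0,
                              prediction_q = 0, prediction_p = 0,
                              timing_noise_sd = 0.001,
                              speed_of_sound = 343,
                              n_stations = 20, seed = 1L) {
  stopifnot(n_groups >= 2, length(arena) == 4, arena[2] > arena[1],
            arena[4] > arena[3], min_center_spacing > 0,
            homerange_radius > 0, daily_site_radius > 0, n_days >= 1,
            calls_per_group_day > 0, overlap_fraction >= 0,
            overlap_fraction < 1, prediction_q >= 0, prediction_q <= 1,
            prediction_p >= 0, prediction_p <= 1, timing_noise_sd >= 0,
            n_stations >= 3)
  structure(as.list(environment()), class = "population_config")
}

# Uniform draw in a disc of radius r around (cx, cy).
runif_disc <- function(n, cx, cy, r) {
  th <- stats::runif(n, 0, 2 * pi)
  rr <- r * sqrt(stats::runif(n))
  cbind(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

#' Generate a synthetic territorial singing population
#'
#' Rejection-samples group centres respecting the centre spacing, then for
#' each group and day draws a daily singing site uniformly within
#' `homerange_radius` of the centre and a Poisson number of calls scattered
#' uniformly within `daily_site_radius` of the site. Emission times are
#' uniform within a morning window (05:00-09:00). Home ranges are emitted
#' as regular 32-gons of radius `homerange_radius + daily_site_radius`
#' around each centre (so every call of a group lies inside its polygon),
#' and recorder stations are laid out on a grid across the arena.
#'
#' Centres are inset from the arena edge by the polygon radius, so all
#' calls and polygons stay inside the arena.
#'
#' @param config a [population_config()].
#' @return a `synthetic_dataset` list: `calls` (call table with `true_id`
#'   and emission `time` in seconds of day), `homeranges`, `stations`,
#'   `config`. `predicted_id` is absent until [attach_predictions()].
#' @export
generate_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  rng <- local_rng(config$seed)
  on.exit(rng$restore())
  r_poly <- config$homerange_radius + config$daily_site_radius
  lo <- c(config$arena[1] + r_poly, config$arena[3] + r_poly)
  hi <- c(config$arena[2] - r_poly, config$arena[4] - r_poly)
  if (any(hi <= lo)) stop("arena too small for the home-range radius")
  spacing <- (1 - config$overlap_fraction) * config$min_center_spacing

  centers <- matrix(NA_real_, config$n_groups, 2)
  placed <- 0L
  for (attempt in seq_len(20000L)) {
    cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
    ok <- placed == 0L ||
      all(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                        cand)^2)) >= spacing)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == config$n_groups) break
    }
  }
  if (placed < config$n_groups)
    stop("could not place group centres at the requested spacing; ",
         "enlarge the arena or allow overlap")

  groups <- sprintf("G%d", seq_len(config$n_groups))
  rows <- list()
  for (g in seq_len(config$n_groups)) {
    for (d in seq_len(config$n_days)) {
      site <- runif_disc(1, centers[g, 1], centers[g, 2],
                         config$homerange_radius)
      n_calls <- stats::rpois(1, config$calls_per_group_day)
      if (n_calls == 0L) next
      pts <- runif_disc(n_calls, site[1], site[2], config$daily_site_radius)
      rows[[length(rows) + 1L]] <-
        data.frame(x = pts[, 1], y = pts[, 2], day = d,
                   time = sort(stats::runif(n_calls, 5 * 3600, 9 * 3600)),
                   true_id = groups[g])
    }
  }
  calls <- do.call(rbind, rows)
  calls <- cbind(call_id = sprintf("c%05d", seq_len(nrow(calls))), calls)
  rownames(calls) <- NULL

  theta <- seq(0, 2 * pi, length.out = 33L)[-33L]
  polys <- lapply(seq_len(config$n_groups), function(g)
    homerange_polygon(groups[g],
                      cbind(centers[g, 1] + r_poly * cos(theta),
                            centers[g, 2] + r_poly * sin(theta))))
  names(polys) <- groups

  ng <- ceiling(sqrt(config$n_stations))
  gx <- seq(config$arena[1], config$arena[2], length.out = ng + 2L)[-c(1, ng + 2L)]
  gy <- seq(config$arena[3], config$arena[4], length.out = ng + 2L)[-c(1, ng + 2L)]
  grid <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[seq_len(min(config$n_stations, nrow(grid))), ]
  stations <- data.frame(station_id = sprintf("S%02d", seq_len(nrow(grid))),
                         x = grid$x, y = grid$y)

  structure(list(calls = calls,
                 homeranges = structure(polys, class = "aiid_homeranges"),
                 stations = stations, centers = centers, config = config),
            class = "synthetic_dataset")
}

#' Attach corrupted ID predictions to a synthetic dataset
#'
#' Maps the true group labels to integer classes, corrupts them with the
#' systematic/isolated error model of [corrupt_labels()], and maps back.
#' Corrupted classes above the number of true groups become spurious
#' `"novel_<i>"` labels (an overestimated population).
#'
#' @param dataset a `synthetic_dataset` from [generate_population()].
#' @param q,p corruption probabilities; default to the dataset config's
#'   `prediction_q` and `prediction_p`.
#' @param seed integer seed (default: dataset seed + 1).
#' @return the dataset with `predicted_id` and `confidence` columns added
#'   to `calls` and a recorded `true_accuracy`.
#' @export
attach_predictions <- function(dataset, q = NULL, p = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  cfg <- dataset$config
  if (is.null(q)) q <- cfg$prediction_q
  if (is.null(p)) p <- cfg$prediction_p
  if (is.null(seed)) seed <- cfg$seed + 1L
  groups <- sort(unique(dataset$calls$true_id))
  n <- length(groups)
  truth <- match(dataset$calls$true_id, groups)
  rng <- local_rng(seed)
  pred <- corrupt_labels(truth, simulation_config(length(truth), n, q, p))$predictions
  rng$restore()
  labels <- ifelse(pred <= n, groups[pmin(pred, n)],
                   sprintf("novel_%d", pred - n))
  dataset$calls$predicted_id <- labels
  dataset$calls$confidence <- 1
  dataset$true_accuracy <- mean(pred == truth)
  dataset
}

#' Forward-model TDOA observations for a synthetic dataset
#'
#' For each call, computes the arrival time at the nearest recorder
#' stations as emission time + distance / speed of sound + Gaussian
#' synchronization noise.
#'
#' @param dataset a `synthetic_dataset` (calls need `time`).
#' @param timing_noise_sd noise sd in seconds; defaults to the config's.
#' @param n_receivers stations reporting each call (default 3, the
#'   nearest); more stations are added when the nearest ones are collinear,
#'   so every observation is localizable.
#' @param seed integer seed (default: dataset seed + 2).
#' @return `data.frame` with `call_id`, `station_id`, `time` (seconds,
#'   day-relative).
#' @export
generate_tdoa <- function(dataset, timing_noise_sd = NULL, n_receivers = 3L,
                          seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  cfg <- dataset$config
  if (is.null(timing_noise_sd)) timing_noise_sd <- cfg$timing_noise_sd
  if (is.null(seed)) seed <- cfg$seed + 2L
  st <- dataset$stations
  stopifnot(nrow(st) >= n_receivers, n_receivers >= 3L)
  rng <- local_rng(seed)
  rows <- lapply(seq_len(nrow(dataset$calls)), function(i) {
    cl <- dataset$calls[i, ]
    d <- sqrt((st$x - cl$x)^2 + (st$y - cl$y)^2)
    ord <- order(d)
    take <- n_receivers
    while (take < nrow(st) &&
           stations_collinear(st$x[ord[seq_len(take)]],
                              st$y[ord[seq_len(take)]]))
      take <- take + 1L
    near <- ord[seq_len(take)]
    data.frame(call_id = cl$call_id,
               station_id = st$station_id[near],
               time = cl$time + d[near] / cfg$speed_of_sound +
                 stats::rnorm(length(near), 0, timing_noise_sd))
  })
  rng$restore()
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic territorial population: %d groups, %d calls over %d days\n",
              x$config$n_groups, nrow(x$calls), x$config$n_days))
  if (!is.null(x$true_accuracy))
    cat(sprintf("  predictions attached, true accuracy %.3f\n",
                x$true_accuracy))
  invisible(x)
}
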