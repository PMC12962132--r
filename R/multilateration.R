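#' Configuration for TDOA source localization
#'
#' @param speed_of_sound metres per second (default 343, dry air at 20 C).
#' @param tol convergence tolerance passed to the optimiser.
#' @param max_iter maximum optimiser iterations per start.
#' @return a list of class `multilateration_config`.
#' @export
multilateration_config <- function(speed_of_sound = 343, tol = 1e-10,
                                   max_iter = 500L) {
  stopifnot(speed_of_sound > 0)
  structure(list(speed_of_sound = speed_of_sound, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "multilateration_config")
}

#' Localize a sound source from arrival-time differences
#'
#' Estimates the planar position of a vocalizing animal from the times its
#' call reached at least three synchronized recorders, by least squares on
#' the time differences of arrival (TDOA): the position minimizing the sum
#' of squared differences between observed and geometric arrival-time
#' differences relative to the first station. The optimiser is multistarted
#' from the station centroid and from each station to escape local minima.
#'
#' @param obs `data.frame` with `station_id` and `time` (seconds), one row
#'   per receiving station, at least three distinct non-collinear stations.
#' @param stations station table (`station_id`, `x`, `y`).
#' @param config a [multilateration_config()].
#' @return list with `x`, `y`, `residual` (root mean square TDOA residual in
#'   seconds), `converged`.
#' @export
tdoa_localize <- function(obs, stations, config = multilateration_config()) {
  stopifnot(inherits(config, "multilateration_config"))
  if (anyDuplicated(obs$station_id)) stop("duplicate station in observation")
  idx <- match(obs$station_id, stations$station_id)
  if (any(is.na(idx))) stop("observation references unknown station")
  if (length(idx) < 3L) stop("need at least 3 stations")
  sx <- stations$x[idx]; sy <- stations$y[idx]
  if (stations_collinear(sx, sy))
    stop("collinear stations: position is ambiguous")
  if (any(!is.finite(obs$time))) stop("non-finite arrival time")

  c0 <- config$speed_of_sound
  dt_obs <- obs$time[-1] - obs$time[1]
  objective <- function(par) {
    d <- sqrt((sx - par[1])^2 + (sy - par[2])^2)
    sum((dt_obs - (d[-1] - d[1]) / c0)^2)
  }
  starts <- rbind(c(mean(sx), mean(sy)), cbind(sx, sy))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], objective, method = "Nelder-Mead",
                        control = list(maxit = config$max_iter,
                                       reltol = config$tol))
    fit <- stats::optim(fit$par, objective, method = "BFGS",
                        control = list(maxit = config$max_iter,
                                       reltol = config$tol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(x = best$par[1], y = best$par[2],
       residual = sqrt(best$value / length(dt_obs)),
       converged = best$convergence == 0L)
}

stations_collinear <- function(x, y, tol = 1e-9) {
  m <- cbind(x - mean(x), y - mean(y))
  s <- svd(m, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

#' Localize a table of TDOA observations
#'
#' Convenience wrapper applying [tdoa_localize()] per call and flagging
#' whether each estimate falls inside the recorders' convex hull.
#'
#' @param tdoa `data.frame` with `call_id`, `station_id`, `time`.
#' @param stations station table.
#' @param config a [multilateration_config()].
#' @return call table with `call_id`, `x`, `y`, `residual`, `in_hull`.
#' @export
localize_calls <- function(tdoa, stations,
                           config = multilateration_config()) {
  per_call <- split(tdoa, tdoa$call_id)
  rows <- lapply(names(per_call), function(id) {
    fit <- tdoa_localize(per_call[[id]], stations, config)
    data.frame(call_id = id, x = fit$x, y = fit$y, residual = fit$residual)
  })
  out <- do.call(rbind, rows)
  out$in_hull <- convex_hull_flags(out[, c("x", "y")], stations)
  rownames(out) <- NULL
  out
}

#' Flag positions inside the recorders' convex hull
#'
#' Localizations outside the convex hull of the recorder array are
#' geometrically poorly constrained and conventionally discarded. Boundary
#' points count as inside.
#'
#' @param positions two-column matrix or data.frame of positions.
#' @param stations station table (`x`, `y`; at least 3 non-collinear).
#' @return logical vector, `TRUE` when inside or on the hull.
#' @export
convex_hull_flags <- function(positions, stations) {
  if (nrow(stations) < 3L) stop("need at least 3 stations")
  if (stations_collinear(stations$x, stations$y))
    stop("degenerate (collinear) station hull")
  hull <- grDevices::chull(stations$x, stations$y)
  v <- cbind(stations$x[hull], stations$y[hull])
  pos <- as.matrix(positions)
  point_in_polygon(pos[, 1], pos[, 2], v)
}

#' Group detection times into song sequences
#'
#' Detections closer than `gap` seconds to their predecessor belong to the
#' same sequence; the input is split wherever an inter-detection gap reaches
#' `gap`. Candidate sequences shorter than `min_len` detections are flagged
#' as dropped but remain in the partition.
#'
#' @param times sorted ascending detection times (seconds).
#' @param gap split threshold in seconds (default 60, i.e. "less than one
#'   minute apart" stays together).
#' @param min_len minimum detections for a retained sequence (default 3).
#' @return list with `assignment` (candidate sequence id per detection) and
#'   `sequences` (`data.frame`: `sequence`, `n`, `start`, `end`, `duration`,
#'   `kept`).
#' @export
group_sequences <- function(times, gap = 60, min_len = 3L) {
  if (is.unsorted(times)) stop("times must be sorted ascending")
  if (length(times) == 0L)
    return(list(assignment = integer(0),
                sequences = data.frame(sequence = integer(0), n = integer(0),
                                       start = numeric(0), end = numeric(0),
                                       duration = numeric(0),
                                       kept = logical(0))))
  assignment <- cumsum(c(1L, as.integer(diff(times) >= gap)))
  seqs <- do.call(rbind, lapply(split(times, assignment), function(t)
    data.frame(n = length(t), start = t[1], end = t[length(t)],
               duration = t[length(t)] - t[1])))
  seqs <- cbind(sequence = as.integer(rownames(seqs)), seqs)
  rownames(seqs) <- NULL
  seqs$kept <- seqs$n >= min_len
  list(assignment = assignment, sequences = seqs)
}

#' Remove song build-up detections
#'
#' Gibbon song sequences open with a progressively intensifying build-up
#' phase whose notes are poorly stereotyped and unsuitable for individual
#' identification. This filter removes, within every retained sequence, the
#' detections falling in the first `buildup_duration` seconds after the
#' sequence start (strictly before `start + buildup_duration`); detections
#' in dropped (too-short) sequences are removed as well.
#'
#' @param times detection times, as passed to [group_sequences()].
#' @param groups result of [group_sequences()] on `times`.
#' @param buildup_duration seconds trimmed from each sequence start
#'   (default 480, i.e. eight minutes); 0 keeps everything in retained
#'   sequences.
#' @return logical vector, `TRUE` for retained detections.
#' @export
filter_buildup <- function(times, groups, buildup_duration = 480) {
  stopifnot(buildup_duration >= 0)
  seqs <- groups$sequences
  keep <- logical(length(times))
  for (i in seq_len(nrow(seqs))) {
    in_seq <- groups$assignment == seqs$sequence[i]
    keep[in_seq] <- seqs$kept[i] &
      times[in_seq] >= seqs$start[i] + buildup_duration
  }
  keep
}

#' Flag clusters violating the travel-speed plausibility heuristic
#'
#' A cluster of detections attributed to one individual is implausible when
#' it contains two detections at stations farther apart than `max_dist`
#' within less than `max_dt` of each other: no single animal can account
#' for both. The defaults (2 km, 30 min) reflect ape travel speeds of a few
#' hundred metres per hour.
#'
#' @param detections `data.frame` with `station_id`, `time` (seconds) and
#'   `cluster_id`.
#' @param stations station table.
#' @param max_dist metres (default 2000).
#' @param max_dt seconds (default 1800).
#' @return character vector of implausible cluster ids.
#' @export
cluster_plausibility <- function(detections, stations, max_dist = 2000,
                                 max_dt = 1800) {
  idx <- match(detections$station_id, stations$station_id)
  if (any(is.na(idx))) stop("detection references unknown station")
  sx <- stations$x[idx]; sy <- stations$y[idx]
  bad <- vapply(split(seq_len(nrow(detections)), detections$cluster_id),
                function(rows) {
                  if (length(rows) < 2L) return(FALSE)
                  d <- as.matrix(stats::dist(cbind(sx[rows], sy[rows])))
                  dt <- abs(outer(detections$time[rows],
                                  detections$time[rows], "-"))
                  any(d > max_dist & dt < max_dt)
                }, logical(1))
  names(bad)[bad]
}
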