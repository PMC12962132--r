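#' Configuration for one corrupted-label simulation run
#'
#' A run draws `N` ground-truth labels uniformly from `n` ID classes and
#' corrupts them with two error processes mimicking an AIID classifier:
#' systematic confusions (each class is wholly reassigned to another class
#' with probability `q`; merging classes underestimates the population) and
#' isolated mistakes (each point's prediction is independently replaced
#' with probability `p` by another label drawn from `ceiling(n/2)` to
#' `floor(3*n/2)`; labels above `n` model spurious "new" individuals, an
#' overestimated population).
#'
#' @param N number of points (>= 1).
#' @param n number of ID classes (>= 2).
#' @param q per-class systematic-confusion probability in \[0, 1\].
#' @param p per-point isolated-error probability in \[0, 1\].
#' @param seed optional integer seed recorded with the run.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(N, n, q, p, seed = NULL) {
  stopifnot(N >= 1, n >= 2, q >= 0, q <= 1, p >= 0, p <= 1)
  structure(list(N = as.integer(N), n = as.integer(n), q = q, p = p,
                 seed = seed),
            class = "simulation_config")
}

#' Sample uniform ground-truth labels
#'
#' @param config a [simulation_config()].
#' @return integer vector of `N` labels drawn i.i.d. uniform from `1:n`.
#' @export
sample_ground_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  sample.int(config$n, config$N, replace = TRUE)
}

#' Corrupt ground-truth labels with systematic and isolated errors
#'
#' Stage 1 (systematic confusions): classes are visited in order `1:n`;
#' with probability `q` a class `c` picks a target `c' != c` uniformly from
#' `1:n` and every prediction currently equal to `c` is reassigned to `c'`.
#' Targets are drawn independently, so two classes may merge into one.
#' Stage 2 (isolated mistakes): each point independently, with probability
#' `p`, has its prediction replaced by a uniform draw from the integers in
#' `ceiling(n/2):floor(3*n/2)` excluding its current value, so an isolated
#' error always changes the prediction.
#'
#' @param truth integer labels in `1:n`.
#' @param config a [simulation_config()].
#' @param order apply `"systematic_first"` (default) or `"isolated_first"`.
#' @return list with `predictions` (integer labels, possibly above `n`) and
#'   `changed` (logical, prediction differs from truth).
#' @export
corrupt_labels <- function(truth, config, order = c("systematic_first",
                                                    "isolated_first")) {
  stopifnot(inherits(config, "simulation_config"))
  order <- match.arg(order)
  stopifnot(all(truth >= 1L), all(truth <= config$n))
  pred <- as.integer(truth)
  stages <- if (order == "systematic_first") c("sys", "iso") else c("iso", "sys")
  for (stage in stages) {
    pred <- if (stage == "sys") corrupt_systematic(pred, config)
            else corrupt_isolated(pred, config)
  }
  list(predictions = pred, changed = pred != truth)
}

corrupt_systematic <- function(pred, config) {
  n <- config$n
  for (c in seq_len(n)) {
    if (stats::runif(1) < config$q) {
      target <- sample.int(n - 1L, 1L)
      if (target >= c) target <- target + 1L   # uniform over 1:n minus c
      pred[pred == c] <- target
    }
  }
  pred
}

corrupt_isolated <- function(pred, config) {
  n <- config$n
  lo <- as.integer(ceiling(n / 2)); hi <- as.integer(floor(3 * n / 2))
  hit <- which(stats::runif(length(pred)) < config$p)
  if (length(hit) == 0L) return(pred)
  span <- hi - lo + 1L
  draw <- lo + sample.int(span, length(hit), replace = TRUE) - 1L
  # redraw collisions with the current value so the replacement differs
  clash <- draw == pred[hit]
  while (any(clash)) {
    draw[clash] <- lo + sample.int(span, sum(clash), replace = TRUE) - 1L
    clash <- draw == pred[hit]
  }
  pred[hit] <- draw
  pred
}

#' True accuracy of predictions against ground truth
#'
#' @param truth,predictions equal-length label vectors.
#' @return fraction of positions where they agree.
#' @export
true_accuracy <- function(truth, predictions) {
  if (length(truth) == 0L) stop("empty input")
  if (length(truth) != length(predictions)) stop("length mismatch")
  mean(truth == predictions)
}

#' Locality metrics under the abstract (non-spatial) neighbourhood
#'
#' In the simulation the spatial layout is abstracted away: points sharing a
#' ground-truth class stand for calls inside one close radius, and points of
#' different classes stand for far-apart calls. The Table-of-assumptions
#' rules then apply verbatim: a point is *consistent* when its prediction is
#' a modal prediction among the other points of its true class (points whose
#' class has a single member are not evaluable), and *specific* when
#' strictly more same-prediction points lie inside its class than outside.
#'
#' @param truth,predictions equal-length integer label vectors.
#' @param tie_rule `"lenient"` (consistent when among tied modes, default)
#'   or `"strict"`.
#' @return a `locality_result` list, as from [compute_locality_metrics()].
#' @export
abstract_locality_metrics <- function(truth, predictions,
                                      tie_rule = c("lenient", "strict")) {
  tie_rule <- match.arg(tie_rule)
  if (length(truth) != length(predictions)) stop("length mismatch")
  N <- length(truth)
  lev <- sort(unique(predictions))
  pc <- match(predictions, lev)
  L <- length(lev)
  tot <- tabulate(pc, L)
  consistent <- rep(NA, N)
  specific <- rep(NA, N)
  for (idx in split(seq_len(N), truth)) {
    m <- length(idx)
    tabc <- tabulate(pc[idx], L)
    own <- tabc[pc[idx]] - 1L           # same-prediction neighbours inside
    if (m >= 2L) {
      M1 <- max(tabc)
      nM1 <- sum(tabc == M1)
      M2 <- if (any(tabc < M1)) max(tabc[tabc < M1]) else 0L
      # modal count among the point's neighbours, excluding its own column
      othermax <- ifelse(tabc[pc[idx]] == M1 & nM1 == 1L, M2, M1)
      consistent[idx] <- if (tie_rule == "lenient") own >= othermax
                         else own > othermax
    }
    if (N - m >= 1L)
      specific[idx] <- own > (tot[pc[idx]] - tabc[pc[idx]])
  }
  summarise_locality(list(consistent = consistent, specific = specific))
}

#' Default sweep grid over simulation settings
#'
#' `N` from 100 to 1,000 (step 100), `n` in \{5, 8, 11, 14, 17, 20\}, `q`
#' from 0.1 to 0.5 (step 0.1), `p` from 0.1 to 1 (step 0.1): 3,000 cells.
#' The ranges are fixed by the study design; the subdivision within them is
#' a package choice (their product must match the intended run count).
#'
#' @return `data.frame` with columns `N`, `n`, `q`, `p`, one row per run.
#' @export
default_sweep_grid <- function() {
  expand.grid(N = seq(100L, 1000L, by = 100L),
              n = c(5L, 8L, 11L, 14L, 17L, 20L),
              q = seq(0.1, 0.5, by = 0.1),
              p = seq(0.1, 1, by = 0.1),
              KEEP.OUT.ATTRS = FALSE)
}

#' Run the corrupted-label simulation sweep
#'
#' One simulation run per grid row: sample a uniform ground truth, corrupt
#' it ([corrupt_labels()]), compute true accuracy and the abstract locality
#' metrics, then summarise how well the two locality-based estimators track
#' true accuracy. Each run consumes a fresh deterministic substream derived
#' from `seed`, so any single cell can be reproduced in isolation.
#'
#' @param grid a `data.frame` with columns `N`, `n`, `q`, `p`; defaults to
#'   [default_sweep_grid()].
#' @param seed integer master seed.
#' @param tie_rule passed to [abstract_locality_metrics()].
#' @return a `sweep_report` list: `runs` (per-run table with the settings,
#'   `true_accuracy`, `consistency`, `specificity`, `accuracy_avg`,
#'   `accuracy_count`), overall `rmse_avg` and `rmse_count`, the
#'   high-accuracy-restricted `rmse_avg_hi` and `rmse_count_hi` (runs with
#'   true accuracy > 0.7), and `r2_sample_size`, the R-squared of an OLS
#'   regression of the absolute error of the averaged estimator on `N`.
#' @export
run_sweep <- function(grid = default_sweep_grid(), seed = 1L,
                      tie_rule = "lenient") {
  if (nrow(grid) == 0L) stop("empty grid")
  stopifnot(all(c("N", "n", "q", "p") %in% names(grid)))
  rng <- local_rng(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    set.seed(cell_seeds[i])
    cfg <- simulation_config(grid$N[i], grid$n[i], grid$q[i], grid$p[i],
                             seed = cell_seeds[i])
    truth <- sample_ground_truth(cfg)
    pred <- corrupt_labels(truth, cfg)$predictions
    m <- abstract_locality_metrics(truth, pred, tie_rule = tie_rule)
    rows[[i]] <- data.frame(N = cfg$N, n = cfg$n, q = cfg$q, p = cfg$p,
                            true_accuracy = true_accuracy(truth, pred),
                            consistency = m$consistency,
                            specificity = m$specificity,
                            accuracy_avg = m$accuracy_avg,
                            accuracy_count = m$accuracy_count)
  }
  rng$restore()
  runs <- do.call(rbind, rows)
  hi <- runs$true_accuracy > 0.7
  abs_err <- abs(runs$accuracy_avg - runs$true_accuracy)
  structure(list(
    runs = runs,
    rmse_avg = rmse(runs$accuracy_avg, runs$true_accuracy),
    rmse_count = rmse(runs$accuracy_count, runs$true_accuracy),
    rmse_avg_hi = rmse(runs$accuracy_avg[hi], runs$true_accuracy[hi]),
    rmse_count_hi = rmse(runs$accuracy_count[hi], runs$true_accuracy[hi]),
    n_hi = sum(hi),
    r2_sample_size = summary(stats::lm(abs_err ~ runs$N))$r.squared
  ), class = "sweep_report")
}

rmse <- function(est, truth) {
  keep <- !is.na(est) & !is.na(truth)
  if (!any(keep)) return(NA_real_)
  sqrt(mean((est[keep] - truth[keep])^2))
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("Corrupted-label sweep: %d runs\n", nrow(x$runs)))
  cat(sprintf("  RMSE, averaged estimator    : %.3f (%.3f on true acc > 0.7, n = %d)\n",
              x$rmse_avg, x$rmse_avg_hi, x$n_hi))
  cat(sprintf("  RMSE, error-count estimator : %.3f (%.3f on true acc > 0.7)\n",
              x$rmse_count, x$rmse_count_hi))
  cat(sprintf("  R-squared of |error| vs N   : %.4f\n", x$r2_sample_size))
  invisible(x)
}
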