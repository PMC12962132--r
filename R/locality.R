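#' Configuration for locality-assumption metrics
#'
#' The locality framework assumes that, within one temporal window (a day by
#' default), an individual sings only within a small "close radius" of
#' itself and that no two individuals sing within that radius of one
#' another. The radius default of 100 m is an empirical choice for gibbon
#' song data; tune it to the species' intra- vs inter-individual singing
#' distances.
#'
#' @param radius close radius in metres; distances `<= radius` count as
#'   inside the neighbourhood.
#' @param tie_rule how to score a call whose predicted ID is one of several
#'   tied modal IDs in its neighbourhood: `"lenient"` (consistent when among
#'   the tied modes, the default) or `"strict"` (consistent only when it is
#'   the unique mode).
#' @return a list of class `locality_config`.
#' @export
locality_config <- function(radius = 100, tie_rule = c("lenient", "strict")) {
  tie_rule <- match.arg(tie_rule)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("radius must be a single positive number")
  structure(list(radius = radius, tie_rule = tie_rule),
            class = "locality_config")
}

# Per-call neighbourhood structure within day windows. Returns, for each
# call, the indices (into the call table) of same-window calls within the
# radius (nb) and beyond it (far). Positions and days only; independent of
# the predicted IDs, so random_baseline can reuse it across runs.
build_neighbourhoods <- function(calls, config) {
  if (any(is.na(calls$day)))
    stop("locality metrics need a day value for every call")
  n <- nrow(calls)
  nb <- vector("list", n)
  far <- vector("list", n)
  for (idx in split(seq_len(n), calls$day)) {
    m <- length(idx)
    if (m == 1L) { nb[[idx]] <- integer(0); far[[idx]] <- integer(0); next }
    d <- as.matrix(stats::dist(cbind(calls$x[idx], calls$y[idx])))
    inside <- d <= config$radius
    diag(inside) <- FALSE
    for (i in seq_len(m)) {
      nb[[idx[i]]] <- idx[inside[i, ]]
      far[[idx[i]]] <- idx[!inside[i, ] & seq_len(m) != i]
    }
  }
  list(nb = nb, far = far)
}

# Score consistency/specificity for a given ID vector against a fixed
# neighbourhood structure. Returns per-call logicals (NA = not evaluable).
score_locality <- function(ids, hoods, tie_rule) {
  n <- length(ids)
  consistent <- rep(NA, n)
  specific <- rep(NA, n)
  for (i in seq_len(n)) {
    nb_ids <- ids[hoods$nb[[i]]]
    far_ids <- ids[hoods$far[[i]]]
    if (length(nb_ids) > 0L) {
      cnt <- table(nb_ids)
      own <- if (ids[i] %in% names(cnt)) cnt[[ids[i]]] else 0L
      consistent[i] <- if (tie_rule == "lenient") own == max(cnt)
                       else own == max(cnt) && sum(cnt == max(cnt)) == 1L
    }
    if (length(far_ids) > 0L)
      specific[i] <- sum(nb_ids == ids[i]) > sum(far_ids == ids[i])
  }
  list(consistent = consistent, specific = specific)
}

# Fold per-call scores into the summary metrics shared with the abstract
# (simulation) variant.
summarise_locality <- function(scores) {
  consistent <- scores$consistent
  specific <- scores$specific
  n_con <- sum(!is.na(consistent))
  n_spe <- sum(!is.na(specific))
  consistency <- if (n_con > 0L) mean(consistent, na.rm = TRUE) else NA_real_
  specificity <- if (n_spe > 0L) mean(specific, na.rm = TRUE) else NA_real_
  evaluable <- !is.na(consistent) | !is.na(specific)
  fails <- (!is.na(consistent) & !consistent) | (!is.na(specific) & !specific)
  accuracy_count <- if (any(evaluable)) 1 - sum(fails) / sum(evaluable)
                    else NA_real_
  structure(list(consistency = consistency, n_consistency = n_con,
                 specificity = specificity, n_specificity = n_spe,
                 accuracy_avg = mean(c(consistency, specificity)),
                 accuracy_count = accuracy_count,
                 n_evaluable = sum(evaluable)),
            class = "locality_result")
}

#' Locality-assumption accuracy metrics for ID predictions
#'
#' Scores every localized call against two territoriality assumptions,
#' within its temporal window (day):
#' \describe{
#'   \item{consistency}{the call's predicted ID is a modal ID among the
#'     other same-day calls within the close radius. Only calls with at
#'     least one neighbour are evaluable.}
#'   \item{specificity}{the call has strictly more same-ID calls inside the
#'     close radius than outside it. Only calls with at least one same-day
#'     call beyond the radius are evaluable.}
#' }
#' Two accuracy estimates are derived: `accuracy_avg`, the mean of the two
#' proportions, and `accuracy_count`, one minus the fraction of calls
#' failing at least one evaluable criterion (among calls with at least one
#' evaluable criterion). The focal call is never part of its own
#' neighbourhood.
#'
#' @param calls call table with finite `x`, `y`, a `day` for every row, and
#'   `predicted_id`.
#' @param config a [locality_config()].
#' @return a `locality_result` list: `consistency`, `n_consistency`,
#'   `specificity`, `n_specificity`, `accuracy_avg`, `accuracy_count`,
#'   `n_evaluable`. A metric with no evaluable call is `NA`. Attribute
#'   `"per_call"` holds the per-call logical scores.
#' @examples
#' calls <- data.frame(call_id = as.character(1:4),
#'                     x = c(0, 10, 5, 1000), y = 0, day = 1,
#'                     predicted_id = c("A", "A", "A", "B"))
#' compute_locality_metrics(calls, locality_config(radius = 100))
#' @export
compute_locality_metrics <- function(calls, config = locality_config()) {
  stopifnot(inherits(config, "locality_config"))
  if (nrow(calls) == 0L) stop("empty call table")
  if (!all(is.finite(calls$x)) || !all(is.finite(calls$y)))
    stop("non-finite coordinates")
  hoods <- build_neighbourhoods(calls, config)
  scores <- score_locality(calls$predicted_id, hoods, config$tie_rule)
  out <- summarise_locality(scores)
  attr(out, "per_call") <- data.frame(call_id = calls$call_id,
                                      consistent = scores$consistent,
                                      specific = scores$specific)
  out
}

#' @export
print.locality_result <- function(x, ...) {
  cat("Locality-assumption validation\n")
  cat(sprintf("  consistency : %.3f (N = %d)\n", x$consistency,
              x$n_consistency))
  cat(sprintf("  specificity : %.3f (N = %d)\n", x$specificity,
              x$n_specificity))
  cat(sprintf("  accuracy (avg of metrics)  : %.3f\n", x$accuracy_avg))
  cat(sprintf("  accuracy (1 - error count) : %.3f\n", x$accuracy_count))
  invisible(x)
}

#' Random-prediction baseline for the locality metrics
#'
#' Replaces every predicted ID by a uniform draw from the set of distinct
#' observed IDs (keeping positions and days fixed), recomputes the locality
#' metrics, and repeats. The resulting means and standard deviations give
#' the chance-level reference against which the model's own metrics are
#' judged.
#'
#' @param calls call table (as for [compute_locality_metrics()]).
#' @param config a [locality_config()].
#' @param runs number of randomized runs (>= 2).
#' @param seed integer seed for the draws.
#' @return a `data.frame` with one row per metric (`consistency`,
#'   `specificity`, `accuracy_avg`, `accuracy_count`) and columns `mean`,
#'   `sd`.
#' @export
random_baseline <- function(calls, config = locality_config(), runs = 100,
                            seed = 1L) {
  stopifnot(runs >= 2)
  ids <- sort(unique(calls$predicted_id))
  if (length(ids) < 2L) stop("need at least 2 distinct observed IDs")
  hoods <- build_neighbourhoods(calls, config)
  n <- nrow(calls)
  res <- matrix(NA_real_, nrow = runs, ncol = 4,
                dimnames = list(NULL, c("consistency", "specificity",
                                        "accuracy_avg", "accuracy_count")))
  rng <- local_rng(seed)
  for (r in seq_len(runs)) {
    fake <- sample(ids, n, replace = TRUE)
    m <- summarise_locality(score_locality(fake, hoods, config$tie_rule))
    res[r, ] <- c(m$consistency, m$specificity, m$accuracy_avg,
                  m$accuracy_count)
  }
  rng$restore()
  data.frame(metric = colnames(res),
             mean = colMeans(res, na.rm = TRUE),
             sd = apply(res, 2, stats::sd, na.rm = TRUE),
             row.names = NULL)
}

# Seed the RNG locally and hand back a restorer, so package functions do not
# clobber the caller's random stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}
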