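#' Configuration for kernel density home-range rasters
#'
#' Group-wise call densities are estimated with an axis-aligned Gaussian
#' product kernel on a square raster spanning a common extent ("the whole
#' map"). The default bandwidth convention follows [MASS::kde2d()], where
#' the supplied bandwidth is four times the kernel standard deviation (so
#' the 1,000 m default smooths with sd = 250 m); set
#' `bandwidth_convention = "sd"` to pass the standard deviation directly.
#'
#' @param bandwidth kernel bandwidth in metres (> 0); default 1,000.
#' @param grid_n raster points per axis (>= 2); default 50.
#' @param extent numeric `c(xmin, xmax, ymin, ymax)`; must cover all points.
#'   If `NULL`, callers derive it from the data with [shared_extent()].
#' @param bandwidth_convention `"quarter"` (kde2d dialect, default) or
#'   `"sd"`.
#' @return a list of class `kde_config`.
#' @export
kde_config <- function(bandwidth = 1000, grid_n = 50, extent = NULL,
                       bandwidth_convention = c("quarter", "sd")) {
  bandwidth_convention <- match.arg(bandwidth_convention)
  stopifnot(bandwidth > 0, grid_n >= 2)
  if (!is.null(extent)) stopifnot(length(extent) == 4,
                                  extent[2] > extent[1], extent[4] > extent[3])
  structure(list(bandwidth = bandwidth, grid_n = as.integer(grid_n),
                 extent = extent,
                 bandwidth_convention = bandwidth_convention),
            class = "kde_config")
}

#' Bounding box covering a set of calls
#'
#' @param calls call table with `x`, `y`.
#' @param pad fraction of each axis span added on both sides (default 0).
#' @return numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
shared_extent <- function(calls, pad = 0) {
  rx <- range(calls$x); ry <- range(calls$y)
  if (diff(rx) == 0) rx <- rx + c(-0.5, 0.5)
  if (diff(ry) == 0) ry <- ry + c(-0.5, 0.5)
  c(rx[1] - pad * diff(rx), rx[2] + pad * diff(rx),
    ry[1] - pad * diff(ry), ry[2] + pad * diff(ry))
}

# Gaussian kernel sd implied by a config.
kde_sd <- function(config) {
  if (config$bandwidth_convention == "quarter") config$bandwidth / 4
  else config$bandwidth
}

#' Kernel density raster for one group's call locations
#'
#' Evaluates the Gaussian product-kernel density (via [MASS::kde2d()]) at
#' `grid_n` x `grid_n` cell centres over the extent and normalizes the cell
#' values to sum to one, giving the relative probability that the group
#' calls from each cell.
#'
#' @param points two-column matrix or data.frame of call coordinates
#'   (metres); at least one point, all inside the extent.
#' @param config a [kde_config()] with a non-`NULL` extent.
#' @return an `aiid_raster` list: `z` (`grid_n` x `grid_n` matrix summing to
#'   1, rows indexing x), `x`, `y` (cell-centre coordinates), `extent`,
#'   `config`.
#' @export
kde_raster <- function(points, config) {
  stopifnot(inherits(config, "kde_config"))
  pts <- as.matrix(points)
  if (nrow(pts) == 0L) stop("no points for kernel density estimate")
  extent <- config$extent
  if (is.null(extent)) stop("kde_config extent must be set")
  if (any(pts[, 1] < extent[1] | pts[, 1] > extent[2] |
          pts[, 2] < extent[3] | pts[, 2] > extent[4]))
    stop("points outside the extent")
  h <- if (config$bandwidth_convention == "quarter") config$bandwidth
       else 4 * config$bandwidth
  kd <- MASS::kde2d(pts[, 1], pts[, 2], h = c(h, h), n = config$grid_n,
                    lims = extent)
  z <- kd$z / sum(kd$z)
  structure(list(z = z, x = kd$x, y = kd$y, extent = extent,
                 config = config),
            class = "aiid_raster")
}

#' Filter calls by prediction confidence
#'
#' Retains calls whose classifier confidence is strictly greater than the
#' threshold (the conventional cut is 0.75).
#'
#' @param calls call table with a `confidence` column.
#' @param threshold confidence cut in \[0, 1\].
#' @return the retained rows of `calls`.
#' @export
filter_by_confidence <- function(calls, threshold = 0.75) {
  stopifnot(threshold >= 0, threshold <= 1)
  conf <- if (is.null(calls$confidence)) rep(1, nrow(calls))
          else calls$confidence
  calls[conf > threshold, , drop = FALSE]
}

#' Relative likelihood of each group within each home range
#'
#' For every home-range polygon, sums each group's normalized kernel raster
#' over the cells whose centres fall inside the polygon (boundary
#' inclusive), then normalizes each row to sum to one. A cell inside
#' overlapping polygons contributes to each of them. The resulting row `k`
#' is the relative likelihood of each group calling within home range `k`.
#'
#' @param rasters named list of [kde_raster()] outputs (one per group),
#'   sharing grid and extent.
#' @param polygons an `aiid_homeranges` list.
#' @return a `K x C` matrix (home ranges x groups), rows summing to 1;
#'   attribute `"undefined_rows"` names polygons covering no cell centre or
#'   no kernel mass (their rows are `NA`), attribute `"raw"` holds the
#'   unnormalized sums.
#' @export
homerange_group_likelihoods <- function(rasters, polygons) {
  stopifnot(length(rasters) >= 1, length(polygons) >= 1)
  g1 <- rasters[[1]]
  for (r in rasters)
    if (!identical(r$x, g1$x) || !identical(r$y, g1$y))
      stop("rasters do not share a grid")
  cells <- expand.grid(x = g1$x, y = g1$y, KEEP.OUT.ATTRS = FALSE)
  # z has rows indexing x, columns indexing y; as.vector matches expand.grid
  zmat <- vapply(rasters, function(r) as.vector(r$z),
                 numeric(nrow(cells)))
  raw <- t(vapply(polygons, function(p) {
    inside <- point_in_polygon(cells$x, cells$y, p$vertices)
    colSums(zmat[inside, , drop = FALSE])
  }, numeric(length(rasters))))
  dimnames(raw) <- list(vapply(polygons, `[[`, character(1), "range_id"),
                        names(rasters))
  rs <- rowSums(raw)
  lik <- raw / rs
  lik[rs == 0, ] <- NA_real_
  attr(lik, "undefined_rows") <- unname(rownames(raw)[rs == 0])
  attr(lik, "raw") <- raw
  lik
}

#' Rank power-law coefficient of a probability profile
#'
#' Measures the diversity of a set of relative likelihoods as the slope `k`
#' of `log(P_i)` against `log(i)`, where `P_i` are the probabilities ranked
#' in descending order: `k = 0` for a uniform profile, strongly negative
#' when a single group dominates. Zeros are dropped before ranking; at
#' least two positive entries are required. The slope is the ordinary
#' least-squares estimate and is invariant to rescaling the probabilities.
#'
#' @param p numeric vector of (relative) probabilities.
#' @return a `power_law_fit` list: `k` (slope), `p_ranked` (descending
#'   positive probabilities), `intercept`.
#' @export
power_law_coefficient <- function(p) {
  p <- p[!is.na(p) & p > 0]
  if (length(p) < 2L) stop("need at least 2 positive probabilities")
  p <- sort(p, decreasing = TRUE)
  lx <- log(seq_along(p)); ly <- log(p)
  k <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  structure(list(k = k, p_ranked = p,
                 intercept = mean(ly) - k * mean(lx)),
            class = "power_law_fit")
}

#' Contingency table of calls by home range and predicted group
#'
#' Counts calls by (containing polygon, predicted ID). Calls outside every
#' polygon are excluded and their count reported; a call inside several
#' overlapping polygons is counted once in each.
#'
#' @param calls call table with `x`, `y`, `predicted_id`.
#' @param polygons an `aiid_homeranges` list.
#' @return integer matrix `n_kc` (home ranges x groups) with attribute
#'   `"n_excluded"`, the number of calls outside all polygons.
#' @export
contingency_from_calls <- function(calls, polygons) {
  groups <- sort(unique(calls$predicted_id))
  ids <- vapply(polygons, `[[`, character(1), "range_id")
  tab <- matrix(0L, nrow = length(polygons), ncol = length(groups),
                dimnames = list(ids, groups))
  covered <- rep(FALSE, nrow(calls))
  for (k in seq_along(polygons)) {
    inside <- point_in_polygon(calls$x, calls$y, polygons[[k]]$vertices)
    covered <- covered | inside
    if (any(inside)) {
      cnt <- table(factor(calls$predicted_id[inside], levels = groups))
      tab[k, ] <- tab[k, ] + as.integer(cnt)
    }
  }
  attr(tab, "n_excluded") <- sum(!covered)
  tab
}

#' Normalised mutual information of a contingency table
#'
#' Quantifies the association between home-range membership and predicted
#' group identity from the call-count table `n_kc`:
#' \deqn{NMI = \frac{\sum_{k,c} n_{kc} \log\frac{N n_{kc}}{n_k n_c}}
#'   {\sqrt{(\sum_k n_k \log\frac{n_k}{N})(\sum_c n_c \log\frac{n_c}{N})}}}
#' with zero cells contributing nothing. Values range from 0 (independence)
#' to 1 (each home range maps to a single group and vice versa).
#'
#' @param tab numeric matrix of counts with at least two non-empty rows and
#'   two non-empty columns.
#' @return NMI in \[0, 1\]; `NA` with a warning when a margin is degenerate.
#' @export
nmi <- function(tab) {
  tab <- as.matrix(tab)
  N <- sum(tab)
  if (N <= 0) stop("empty contingency table")
  nk <- rowSums(tab); nc <- colSums(tab)
  if (sum(nk > 0) < 2L || sum(nc > 0) < 2L) {
    warning("degenerate margin: NMI undefined")
    return(NA_real_)
  }
  pos <- tab > 0
  num <- sum(tab[pos] * log(N * tab[pos] /
                            (outer(nk, nc)[pos])))
  den <- sqrt(sum(nk[nk > 0] * log(nk[nk > 0] / N)) *
              sum(nc[nc > 0] * log(nc[nc > 0] / N)))
  num / den
}

#' Dominant group per home range
#'
#' @param lik likelihood matrix from [homerange_group_likelihoods()].
#' @return named character vector mapping each defined home range to its
#'   highest-likelihood group; ties go to the first group in column order
#'   and are listed in the `"ties"` attribute.
#' @export
dominant_groups <- function(lik) {
  defined <- !apply(lik, 1, function(r) all(is.na(r)))
  lik <- lik[defined, , drop = FALSE]
  winners <- colnames(lik)[apply(lik, 1, which.max)]
  names(winners) <- rownames(lik)
  tied <- rownames(lik)[apply(lik, 1, function(r)
    sum(r == max(r, na.rm = TRUE), na.rm = TRUE) > 1L)]
  attr(winners, "ties") <- tied
  winners
}

# ---- the full home-range pipeline -----------------------------------------

# Precomputed machinery for repeated evaluation of the pipeline statistics
# under permutations: per-point kernel contributions to each raster cell,
# and cell-in-polygon masks. Labels permute; positions never do.
homerange_engine <- function(calls, polygons, config) {
  extent <- if (is.null(config$extent)) shared_extent(calls) else config$extent
  cfg <- kde_config(config$bandwidth, config$grid_n, extent,
                    config$bandwidth_convention)
  gx <- seq(extent[1], extent[2], length.out = cfg$grid_n)
  gy <- seq(extent[3], extent[4], length.out = cfg$grid_n)
  cells <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  sd <- kde_sd(cfg)
  # ncell x ncall matrix of kernel contributions
  K <- outer(cells$x, calls$x, function(a, b) stats::dnorm(a, b, sd)) *
       outer(cells$y, calls$y, function(a, b) stats::dnorm(a, b, sd))
  masks <- vapply(polygons, function(p)
    point_in_polygon(cells$x, cells$y, p$vertices),
    logical(nrow(cells)))
  B <- t(masks) * 1
  rownames(B) <- vapply(polygons, `[[`, character(1), "range_id")
  membership <- vapply(polygons, function(p)
    point_in_polygon(calls$x, calls$y, p$vertices), logical(nrow(calls)))
  list(K = K, B = B, membership = membership, config = cfg,
       groups = sort(unique(calls$predicted_id)))
}

# Likelihood matrix for a label assignment, via the precomputed engine.
engine_likelihoods <- function(eng, labels) {
  ind <- vapply(eng$groups, function(g) as.numeric(labels == g),
                numeric(length(labels)))
  S <- eng$K %*% ind                       # ncell x C unnormalized rasters
  tot <- colSums(S)
  keep <- tot > 0
  S[, keep] <- sweep(S[, keep, drop = FALSE], 2, tot[keep], "/")
  raw <- eng$B %*% S                       # K x C in-polygon mass
  rs <- rowSums(raw)
  lik <- raw / rs
  lik[rs == 0, ] <- NA_real_
  lik
}

engine_mean_k <- function(eng, labels) {
  lik <- engine_likelihoods(eng, labels)
  ks <- apply(lik, 1, function(row) {
    row <- row[!is.na(row) & row > 0]
    if (length(row) < 2L) return(NA_real_)
    power_law_coefficient(row)$k
  })
  mean(ks, na.rm = TRUE)
}

engine_nmi <- function(eng, labels) {
  ind <- vapply(eng$groups, function(g) as.integer(labels == g),
                integer(length(labels)))
  tab <- t(eng$membership * 1) %*% ind
  out <- tryCatch(suppressWarnings(nmi(tab)), error = function(e) NA_real_)
  out
}

#' Home-range agreement report for ID predictions
#'
#' Runs the full home-range validation pipeline: confidence filter,
#' per-group kernel density rasters over a common extent, in-polygon
#' relative likelihoods, per-range power-law diversity coefficients, the
#' dominant-group map, and the normalised mutual information of the
#' call-count contingency table.
#'
#' @param calls call table with `x`, `y`, `predicted_id` and (optionally)
#'   `confidence`.
#' @param polygons an `aiid_homeranges` list.
#' @param config a [kde_config()].
#' @param conf_threshold confidence cut applied first (default 0.75;
#'   strictly greater-than).
#' @return a `homerange_report` list: `likelihoods`, `k` (named per-range
#'   coefficients), `mean_k`, `nmi`, `dominant`, `contingency`, `n_calls`
#'   (after filtering).
#' @export
validate_homerange <- function(calls, polygons, config = kde_config(),
                               conf_threshold = 0.75) {
  calls <- filter_by_confidence(calls, conf_threshold)
  if (nrow(calls) == 0L) stop("no calls pass the confidence filter")
  eng <- homerange_engine(calls, polygons, config)
  lik <- engine_likelihoods(eng, calls$predicted_id)
  ks <- apply(lik, 1, function(row) {
    row <- row[!is.na(row) & row > 0]
    if (length(row) < 2L) return(NA_real_)
    power_law_coefficient(row)$k
  })
  tab <- contingency_from_calls(calls, polygons)
  structure(list(likelihoods = lik, k = ks, mean_k = mean(ks, na.rm = TRUE),
                 nmi = tryCatch(suppressWarnings(nmi(tab)),
                                error = function(e) NA_real_),
                 dominant = dominant_groups(lik), contingency = tab,
                 n_calls = nrow(calls)),
            class = "homerange_report")
}

#' @export
print.homerange_report <- function(x, ...) {
  cat(sprintf("Home-range agreement (%d calls)\n", x$n_calls))
  cat(sprintf("  mean power-law coefficient k : %.3f\n", x$mean_k))
  cat(sprintf("  NMI(home range, group)       : %.3f\n", x$nmi))
  cat("  dominant groups:\n")
  for (k in names(x$dominant))
    cat(sprintf("    %s -> %s\n", k, x$dominant[k]))
  invisible(x)
}

#' Permutation ("exact") test for a home-range agreement statistic
#'
#' Builds the null distribution of a pipeline statistic by randomising the
#' assignment of predicted IDs to localized points (positions fixed) and
#' recomputing the statistic each iteration. The test is one-sided in the
#' direction of territorial structure: smaller-than-null for `"mean_k"`
#' (dominance makes `k` more negative), larger-than-null for `"nmi"`.
#' The p-value uses add-one smoothing, `(1 + #extreme) / (1 + iterations)`,
#' so it is never zero.
#'
#' @param calls call table (already confidence-filtered if desired; the
#'   permutation happens on the calls as given).
#' @param polygons an `aiid_homeranges` list.
#' @param statistic `"mean_k"` or `"nmi"`.
#' @param config a [kde_config()] (used by `"mean_k"`).
#' @param iterations number of randomisations (default 10,000).
#' @param seed integer seed.
#' @return a `permutation_test_result` list: `observed`, `null_values`,
#'   `p_value`, `iterations`, `n_undefined` (iterations whose statistic was
#'   undefined, excluded from the tally), `statistic`, `seed`.
#' @export
permutation_test <- function(calls, polygons,
                             statistic = c("mean_k", "nmi"),
                             config = kde_config(), iterations = 10000,
                             seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(iterations >= 1)
  eng <- homerange_engine(calls, polygons, config)
  fn <- if (statistic == "mean_k") engine_mean_k else engine_nmi
  observed <- fn(eng, calls$predicted_id)
  rng <- local_rng(seed)
  null_values <- numeric(iterations)
  for (it in seq_len(iterations))
    null_values[it] <- fn(eng, sample(calls$predicted_id))
  rng$restore()
  ok <- !is.na(null_values)
  extreme <- if (statistic == "mean_k") null_values[ok] <= observed
             else null_values[ok] >= observed
  p <- (1 + sum(extreme)) / (1 + sum(ok))
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, iterations = iterations,
                 n_undefined = sum(!ok), statistic = statistic,
                 seed = seed),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("Permutation test of %s: observed %.3f, null mean %.3f, p = %.4g (%d iterations)\n",
              x$statistic, x$observed, mean(x$null_values, na.rm = TRUE),
              x$p_value, x$iterations))
  invisible(x)
}
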