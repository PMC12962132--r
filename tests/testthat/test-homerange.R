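test_that("confidence filter keeps strictly-greater confidences only", {
  calls <- data.frame(call_id = as.character(1:3), x = 0, y = 0, day = 1L,
                      predicted_id = "A",
                      confidence = c(0.5, 0.75, 0.76))
  expect_equal(nrow(filter_by_confidence(calls, 0.75)), 1L)
  expect_equal(filter_by_confidence(calls, 0.75)$confidence, 0.76)
  expect_equal(nrow(filter_by_confidence(calls, 0)), 3L)
  set.seed(3)
  unif <- data.frame(call_id = as.character(1:400), x = 0, y = 0, day = 1L,
                     predicted_id = "A", confidence = runif(400))
  expect_lt(abs(nrow(filter_by_confidence(unif, 0.75)) / 400 - 0.25), 0.07)
})

test_that("kde raster matches a direct sum-of-Gaussians evaluation", {
  set.seed(5)
  ext <- c(0, 4000, 0, 3000)
  pts <- cbind(runif(10, 500, 3500), runif(10, 500, 2500))
  for (conv in c("quarter", "sd")) {
    cfg <- kde_config(bandwidth = 1000, grid_n = 20, extent = ext,
                      bandwidth_convention = conv)
    r <- kde_raster(pts, cfg)
    expect_equal(sum(r$z), 1, tolerance = 1e-12)
    sd <- if (conv == "quarter") 250 else 1000
    gx <- seq(ext[1], ext[2], length.out = 20)
    gy <- seq(ext[3], ext[4], length.out = 20)
    direct <- matrix(0, 20, 20)
    for (i in 1:20) for (j in 1:20) for (k in 1:10)
      direct[i, j] <- direct[i, j] +
        dnorm(gx[i], pts[k, 1], sd) * dnorm(gy[j], pts[k, 2], sd)
    direct <- direct / sum(direct)
    expect_lt(max(abs(r$z - direct) / max(direct)), 1e-9)
  }
})

test_that("single central point gives a symmetric raster peaking centrally", {
  cfg <- kde_config(bandwidth = 400, grid_n = 21, extent = c(-1, 1, -1, 1) * 500)
  r <- kde_raster(cbind(0, 0), cfg)
  expect_equal(which(r$z == max(r$z)), (21 * 21 + 1) %/% 2)  # centre cell
  expect_equal(r$z, r$z[21:1, ], tolerance = 1e-12)
  expect_equal(r$z, t(r$z), tolerance = 1e-12)
  expect_error(kde_raster(cbind(2000, 0), cfg), "outside the extent")
})

test_that("likelihood rows normalize, conserve mass, and flag empty polygons", {
  set.seed(15)
  ext <- c(0, 100, 0, 100)
  cfg <- kde_config(bandwidth = 40, grid_n = 30, extent = ext)
  rasters <- list(A = kde_raster(cbind(runif(8, 10, 40), runif(8, 10, 40)), cfg),
                  B = kde_raster(cbind(runif(8, 60, 90), runif(8, 60, 90)), cfg))

  # one polygon covering the full extent: each group contributes its total
  # mass of 1, so the normalized row is uniform
  whole <- as_homeranges(square_polygon("all", -1, 101, -1, 101))
  lik <- homerange_group_likelihoods(rasters, whole)
  expect_equal(unname(lik["all", ]), c(0.5, 0.5), tolerance = 1e-12)

  # disjoint partition: unnormalized entries per group sum to total mass
  halves <- as_homeranges(square_polygon("left", -1, 50, -1, 101),
                          square_polygon("right", 50.0001, 101, -1, 101))
  lik2 <- homerange_group_likelihoods(rasters, halves)
  raw <- attr(lik2, "raw")
  expect_equal(unname(colSums(raw)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(rowSums(lik2)), c(1, 1), tolerance = 1e-12)

  # mass concentration: small-bandwidth group inside its own polygon
  expect_gt(lik2["left", "A"], 0.9)
  expect_gt(lik2["right", "B"], 0.9)

  # a polygon with no cell centres is flagged undefined
  empty <- as_homeranges(square_polygon("tiny", 200, 201, 200, 201))
  lik3 <- homerange_group_likelihoods(rasters, empty)
  expect_true(all(is.na(lik3)))
  expect_equal(attr(lik3, "undefined_rows"), "tiny")
})

test_that("power-law coefficient: exact cases, OLS oracle, scale invariance", {
  expect_equal(power_law_coefficient(rep(0.2, 5))$k, 0)
  p_inv <- (1 / (1:5)) / sum(1 / (1:5))
  expect_equal(power_law_coefficient(p_inv)$k, -1, tolerance = 1e-12)

  p <- c(0.6, 0.3, 0.1)
  oracle <- unname(coef(lm(log(p) ~ log(1:3)))[2])
  expect_equal(power_law_coefficient(p)$k, oracle, tolerance = 1e-12)

  scaled <- power_law_coefficient(p * 37.5)
  expect_equal(scaled$k, oracle, tolerance = 1e-12)

  # zeros are dropped before ranking; order of input is irrelevant
  expect_equal(power_law_coefficient(c(0.1, 0, 0.6, 0.3))$k, oracle,
               tolerance = 1e-12)
  expect_error(power_law_coefficient(c(0.4, 0)), "at least 2")
})

test_that("contingency counts match a brute-force point-in-polygon tally", {
  k1 <- square_polygon("k1", 0, 10, 0, 10)
  k2 <- square_polygon("k2", 20, 30, 0, 10)
  calls <- data.frame(call_id = as.character(1:4),
                      x = c(5, 6, 25, 99), y = c(5, 6, 5, 99), day = 1L,
                      predicted_id = c("A", "A", "B", "A"))
  tab <- contingency_from_calls(calls, as_homeranges(k1, k2))
  expect_equal(unname(tab), rbind(c(2L, 0L), c(0L, 1L)), ignore_attr = TRUE)
  expect_equal(attr(tab, "n_excluded"), 1L)

  set.seed(25)
  calls <- data.frame(call_id = as.character(1:200),
                      x = runif(200, 0, 40), y = runif(200, 0, 15), day = 1L,
                      predicted_id = sample(c("A", "B", "C"), 200, TRUE))
  polys <- as_homeranges(k1, k2, square_polygon("k3", 5, 25, 5, 15))
  tab <- contingency_from_calls(calls, polys)
  for (k in names(polys)) for (g in c("A", "B", "C")) {
    manual <- sum(calls$predicted_id == g &
                    point_in_polygon(calls$x, calls$y, polys[[k]]$vertices))
    expect_equal(tab[k, g], manual)
  }
})

test_that("NMI hits its closed-form anchors and invariances", {
  expect_equal(nmi(rbind(c(10, 0), c(0, 10))), 1)
  expect_equal(nmi(rbind(c(5, 5), c(5, 5))), 0)

  tab <- rbind(c(8, 2), c(2, 8))
  # independent oracle: entropy formulation NMI = MI / sqrt(H(K) H(C))
  N <- sum(tab); pk <- rowSums(tab) / N; pc <- colSums(tab) / N
  pkc <- tab / N
  mi <- sum(pkc[pkc > 0] * log(pkc[pkc > 0] / outer(pk, pc)[pkc > 0]))
  oracle <- mi / sqrt(-sum(pk * log(pk)) * -sum(pc * log(pc)))
  expect_equal(nmi(tab), oracle, tolerance = 1e-12)
  expect_gte(nmi(tab), 0)
  expect_lte(nmi(tab), 1)

  # symmetric in the roles of rows and columns; invariant to permutation
  expect_equal(nmi(t(tab)), nmi(tab))
  expect_equal(nmi(tab[2:1, ]), nmi(tab))
  expect_equal(nmi(tab[, 2:1]), nmi(tab))

  expect_warning(out <- nmi(rbind(c(3, 4))), "degenerate")
  expect_true(is.na(out))
})

test_that("dominant groups take the row argmax with a reported tie policy", {
  lik <- rbind(r1 = c(0.7, 0.2, 0.1), r2 = c(0.5, 0.5, 0))
  colnames(lik) <- c("A", "B", "C")
  dom <- dominant_groups(lik)
  expect_equal(unname(dom["r1"]), "A")
  expect_equal(unname(dom["r2"]), "A")   # tie broken by column order
  expect_equal(attr(dom, "ties"), "r2")
})

test_that("pipeline recovers the generating territory map on clean synthetic data", {
  ds <- attach_predictions(generate_population(population_config(
    n_groups = 5, n_days = 12, seed = 101)), q = 0, p = 0)
  rep <- validate_homerange(ds$calls, ds$homeranges,
                            kde_config(bandwidth = 400), conf_threshold = 0)
  expect_equal(as.vector(rep$dominant), names(rep$dominant))
  expect_gt(rep$nmi, 0.99)
  expect_lt(rep$mean_k, -2)
})

test_that("permutation test: minimal p on territorial data, sane p under the null", {
  ds <- attach_predictions(generate_population(population_config(
    n_groups = 4, n_days = 10, seed = 55)), q = 0, p = 0)
  pt <- permutation_test(ds$calls, ds$homeranges, "nmi",
                         kde_config(bandwidth = 400), iterations = 199,
                         seed = 2)
  expect_equal(pt$p_value, 1 / 200)
  expect_true(all(pt$null_values <= pt$observed, na.rm = TRUE))

  pk <- permutation_test(ds$calls, ds$homeranges, "mean_k",
                         kde_config(bandwidth = 400), iterations = 199,
                         seed = 2)
  expect_equal(pk$p_value, 1 / 200)
  expect_lt(pk$observed, mean(pk$null_values, na.rm = TRUE))

  # identical seeds give identical null draws
  pk2 <- permutation_test(ds$calls, ds$homeranges, "mean_k",
                          kde_config(bandwidth = 400), iterations = 199,
                          seed = 2)
  expect_equal(pk$null_values, pk2$null_values)
})
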