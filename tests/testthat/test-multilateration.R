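equilateral_stations <- function(r = 1000) {
  th <- c(90, 210, 330) * pi / 180
  data.frame(station_id = c("S1", "S2", "S3"),
             x = r * cos(th), y = r * sin(th))
}

forward_times <- function(src, stations, c0 = 343, t0 = 0) {
  data.frame(station_id = stations$station_id,
             time = t0 + sqrt((stations$x - src[1])^2 +
                                (stations$y - src[2])^2) / c0)
}

test_that("zero TDOAs put the source at the array centroid", {
  st <- equilateral_stations()
  obs <- data.frame(station_id = st$station_id, time = 5)
  fit <- tdoa_localize(obs, st)
  expect_lt(sqrt(fit$x^2 + fit$y^2), 1e-3)
  expect_lt(fit$residual, 1e-9)
})

test_that("noiseless forward model is inverted to sub-metre accuracy", {
  set.seed(8)
  st <- data.frame(station_id = paste0("S", 1:4),
                   x = c(0, 2000, 2000, 0), y = c(0, 0, 2000, 2000))
  for (rep in 1:5) {
    src <- runif(2, 200, 1800)
    fit <- tdoa_localize(forward_times(src, st), st)
    expect_lt(sqrt((fit$x - src[1])^2 + (fit$y - src[2])^2), 1)
    expect_lt(fit$residual, 1e-8)
  }
})

test_that("perturbing the arrival times strictly raises the residual", {
  # four stations over-determine the position, so inconsistent TDOAs
  # cannot be absorbed by moving the estimate
  st <- data.frame(station_id = paste0("S", 1:4),
                   x = c(0, 2000, 2000, 0), y = c(0, 0, 2000, 2000))
  src <- c(700, 650)
  obs <- forward_times(src, st)
  clean <- tdoa_localize(obs, st)
  obs$time[2] <- obs$time[2] + 0.05
  noisy <- tdoa_localize(obs, st)
  expect_gt(noisy$residual, clean$residual + 1e-4)
})

test_that("solver agrees with a lattice grid search on noiseless toys", {
  set.seed(18)
  st <- data.frame(station_id = paste0("S", 1:4),
                   x = c(0, 2000, 2000, 0), y = c(0, 0, 2000, 2000))
  cell <- 25
  gx <- seq(0, 2000, by = cell)
  grid <- expand.grid(x = gx, y = gx)
  for (rep in 1:3) {
    src <- runif(2, 300, 1700)
    obs <- forward_times(src, st)
    dt <- obs$time[-1] - obs$time[1]
    sse <- apply(grid, 1, function(g) {
      d <- sqrt((st$x - g[1])^2 + (st$y - g[2])^2)
      sum((dt - (d[-1] - d[1]) / 343)^2)
    })
    best <- grid[which.min(sse), ]
    fit <- tdoa_localize(obs, st)
    expect_lt(max(abs(c(fit$x - best$x, fit$y - best$y))), cell)
  }
})

test_that("localization is equivariant under rigid motion of the scene", {
  st <- equilateral_stations()
  src <- c(220, 140)
  fit <- tdoa_localize(forward_times(src, st), st)
  th <- 1.1; shift <- c(3000, -500)
  rot <- function(p) c(cos(th) * p[1] - sin(th) * p[2] + shift[1],
                       sin(th) * p[1] + cos(th) * p[2] + shift[2])
  st2 <- st
  for (i in 1:3) { p <- rot(c(st$x[i], st$y[i])); st2$x[i] <- p[1]; st2$y[i] <- p[2] }
  fit2 <- tdoa_localize(forward_times(rot(src), st2), st2)
  expected <- rot(c(fit$x, fit$y))
  expect_lt(sqrt((fit2$x - expected[1])^2 + (fit2$y - expected[2])^2), 1)
})

test_that("collinear stations are rejected as ambiguous", {
  st <- data.frame(station_id = c("a", "b", "c"), x = c(0, 1000, 2000), y = 0)
  obs <- data.frame(station_id = st$station_id, time = c(1, 2, 3))
  expect_error(tdoa_localize(obs, st), "collinear")
  expect_error(convex_hull_flags(cbind(0, 0), st), "collinear|degenerate")
})

test_that("convex hull flags match a half-plane oracle and include the boundary", {
  st <- data.frame(station_id = paste0("S", 1:5),
                   x = c(0, 1000, 1000, 0, 500), y = c(0, 0, 1000, 1000, 500))
  expect_true(convex_hull_flags(cbind(500, 500), st))
  expect_true(convex_hull_flags(cbind(1000, 500), st))   # on an edge
  expect_true(convex_hull_flags(cbind(0, 0), st))        # at a vertex
  expect_false(convex_hull_flags(cbind(1000.001, 500), st))

  set.seed(28)
  pos <- cbind(runif(100, -300, 1300), runif(100, -300, 1300))
  flags <- convex_hull_flags(pos, st)
  # half-plane oracle on the hull, oriented by signed area
  hull <- grDevices::chull(st$x, st$y)
  hx <- st$x[hull]; hy <- st$y[hull]
  area2 <- sum(hx * hy[c(2:length(hy), 1)] - hx[c(2:length(hx), 1)] * hy)
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }
  oracle <- apply(pos, 1, function(p) {
    all(sapply(seq_along(hx), function(i) {
      j <- i %% length(hx) + 1
      (hx[j] - hx[i]) * (p[2] - hy[i]) - (hy[j] - hy[i]) * (p[1] - hx[i]) >= 0
    }))
  })
  expect_equal(flags, oracle)
})

test_that("sequence grouping splits at the gap and partitions the input", {
  g <- group_sequences(c(0, 30, 59, 200, 230, 260))
  expect_equal(g$assignment, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(g$sequences$n, c(3L, 3L))
  expect_true(all(g$sequences$kept))

  # a gap of exactly 60 s splits; singletons are dropped at min_len 3
  g2 <- group_sequences(c(0, 61))
  expect_equal(g2$assignment, c(1L, 2L))
  expect_false(any(g2$sequences$kept))

  set.seed(38)
  bouts <- sort(c(runif(20, 0, 500), runif(15, 2000, 2400),
                  runif(10, 9000, 9300)))
  g3 <- group_sequences(bouts, gap = 600)
  expect_equal(length(unique(g3$assignment)), 3L)
  expect_equal(tabulate(g3$assignment), c(20L, 15L, 10L))
  # every detection belongs to exactly one candidate sequence
  expect_equal(sum(g3$sequences$n), length(bouts))
})

test_that("build-up filtering trims the start of each sequence", {
  times <- seq(0, 20 * 60, by = 15)   # a 20-minute sequence every 15 s
  g <- group_sequences(times)
  keep <- filter_buildup(times, g, 480)
  expect_equal(sum(!keep), 32L)       # 0..465 s removed
  expect_true(all(times[keep] >= 480))

  short <- seq(0, 300, by = 15)       # shorter than the build-up window
  expect_false(any(filter_buildup(short, group_sequences(short), 480)))

  expect_equal(filter_buildup(times, g, 0), rep(TRUE, length(times)))
})

test_that("cluster plausibility flags fast far-apart co-occurrence only", {
  st <- data.frame(station_id = c("near", "far"), x = c(0, 2500), y = 0)
  det <- function(cluster, station, time)
    data.frame(cluster_id = cluster, station_id = station, time = time)

  single <- det("c1", c("near", "near"), c(0, 100))
  expect_equal(cluster_plausibility(single, st), character(0))

  fast <- rbind(det("c1", "near", 0), det("c1", "far", 600))
  expect_equal(cluster_plausibility(fast, st), "c1")

  slow <- rbind(det("c1", "near", 0), det("c1", "far", 7200))
  expect_equal(cluster_plausibility(slow, st), character(0))

  mixed <- rbind(det("ok", "near", 0), det("ok", "far", 7200),
                 det("bad", "near", 0), det("bad", "far", 60))
  expect_equal(cluster_plausibility(mixed, st), "bad")
})
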