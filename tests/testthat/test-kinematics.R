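# Kinematics: strain-rate decomposition, synchronisation, T1 detection,
# Voronoi deviation, event alignment and recoil regression.

test_that("rigid translation yields zero strain rates everywhere", {
  base <- hex44()
  mv <- replicate_frames(base, 5, function(v, s) {
    v$x <- v$x + 0.3 * s; v$y <- v$y + 0.1 * s; v
  })
  sr <- domain_strain_rates(mv, frames = 3)
  expect_gt(nrow(sr), 0)
  expect_lt(max(abs(as.matrix(sr[, grep("_(xx|xy|yy|ap|dv)$",
                                        names(sr))]))), 1e-9)
})

test_that("pure AP stretch is attributed to tissue and shape, not intercalation", {
  base <- hex44()
  k <- 0.6  # per hour
  g <- exp(k * 0.5 / 60)
  mv <- replicate_frames(base, 5, function(v, s) {
    v$x <- v$x * g^s; v
  })
  sr <- domain_strain_rates(mv, frames = 3)
  expect_equal(unique(round(sr$tissue_ap, 9)), k)
  expect_equal(unique(round(sr$tissue_dv, 9)), 0)
  expect_lt(max(abs(sr$intercalation_ap)), 1e-9)
  # decomposition identity holds to machine precision by construction
  expect_equal(sr$intercalation_xx, sr$tissue_xx - sr$shape_xx)
  expect_equal(sr$intercalation_xy, sr$tissue_xy - sr$shape_xy)
})

test_that("synchronisation finds the onset of AP extension", {
  base <- hex44()
  # constant sub-threshold growth: no onset
  slow <- replicate_frames(base, 10, function(v, s) {
    v$x <- v$x * (1 + 0.002)^s; v
  })
  expect_true(is.na(synchronize(slow)$offset))
  # step from 0 to 0.02/min at frame 6 (time 2.5): offset = frame 5's time
  step <- replicate_frames(base, 10, function(v, s) {
    f <- if (s >= 5) (1 + 0.02 * 0.5)^(s - 4) else 1
    v$x <- v$x * f; v
  })
  expect_equal(synchronize(step)$offset, 2.0)
  # ramped movie matches a brute-force scan of the rate series
  ramp <- replicate_frames(base, 20, function(v, s) {
    v$x <- v$x * prod(1 + 0.0015 * (0:s)); v
  })
  sy <- synchronize(ramp)
  first <- which(sy$rates$rate > 0.01)[1]
  expect_equal(sy$offset, sy$rates$time[first - 1])
})

test_that("T1 detection debounces flickers and ignores reversions", {
  expect_equal(nrow(detect_t1(make_scripted_t1_movie("clean"))), 1L)
  ev <- detect_t1(make_scripted_t1_movie("clean"))
  expect_equal(ev$time, 8)
  expect_equal(c(ev$losing_a, ev$losing_b) > 0, c(TRUE, TRUE))
  # losing pair 3|4, gaining pair 1|2 (track ids follow cell ids here)
  tr <- cell_tracks(make_scripted_t1_movie("clean"))
  id_of <- function(cid) tr$track[tr$frame == 1 & tr$id == cid]
  expect_setequal(c(ev$losing_a, ev$losing_b), c(id_of(3), id_of(4)))
  expect_setequal(c(ev$gaining_a, ev$gaining_b), c(id_of(1), id_of(2)))
  expect_equal(nrow(detect_t1(make_scripted_t1_movie("flicker"))), 1L)
  expect_equal(detect_t1(make_scripted_t1_movie("flicker"))$time, 10)
  expect_equal(nrow(detect_t1(make_scripted_t1_movie("revert"))), 0L)
  # static movie: no events
  static <- replicate_frames(hex44(), 4)
  expect_equal(nrow(detect_t1(static)), 0L)
})

test_that("T1 count is invariant under time shift and frame-rate doubling", {
  mv <- make_scripted_t1_movie("flicker")
  shifted <- mv
  shifted$times$time <- shifted$times$time + 13
  expect_equal(nrow(detect_t1(shifted)), 1L)
  fine <- make_scripted_t1_movie("flicker", frame_interval = 0.25)
  expect_equal(nrow(detect_t1(fine)), 1L)
})

test_that("Voronoi deviation vanishes on regular lattices and matches a sampling oracle", {
  tt <- make_hex_tissue(6, 6)
  vd <- voronoi_deviation(tt, 1)
  expect_gt(nrow(vd$interfaces), 10)
  expect_lt(max(abs(vd$interfaces$deviation)), 1e-9 * sqrt(1))
  expect_lt(max(abs(vd$cells$deviation)), 1e-9)
  # isotropic scaling: still zero
  big <- make_hex_tissue(6, 6, cell_area = 7)
  vdb <- voronoi_deviation(big, 1)
  expect_lt(max(abs(vdb$interfaces$deviation)), 1e-8)
  # duplicate centroids are rejected
  dup <- tt
  dup$cells$centroid_x[2] <- dup$cells$centroid_x[1]
  dup$cells$centroid_y[2] <- dup$cells$centroid_y[1]
  expect_error(voronoi_deviation(dup, 1), "duplicate")
})

test_that("Voronoi predictions agree with a nearest-two-generators sampling oracle", {
  set.seed(5)
  tt <- make_hex_tissue(6, 6)
  # perturb vertices and centroids jointly
  pert <- tt
  n <- nrow(pert$vertices)
  pert$vertices$x <- pert$vertices$x + rnorm(n, 0, 0.04)
  pert$vertices$y <- pert$vertices$y + rnorm(n, 0, 0.04)
  pert$cells$centroid_x <- vapply(seq_len(nrow(pert$cells)), function(k) {
    idx <- match(pert$cells$vertices[[k]], pert$vertices$vertex_id)
    gbex:::.poly_centroid(pert$vertices$x[idx], pert$vertices$y[idx])[1]
  }, numeric(1))
  pert$cells$centroid_y <- vapply(seq_len(nrow(pert$cells)), function(k) {
    idx <- match(pert$cells$vertices[[k]], pert$vertices$vertex_id)
    gbex:::.poly_centroid(pert$vertices$x[idx], pert$vertices$y[idx])[2]
  }, numeric(1))
  i1 <- match(pert$interfaces$v1, pert$vertices$vertex_id)
  i2 <- match(pert$interfaces$v2, pert$vertices$vertex_id)
  pert$interfaces$length <- sqrt(
    (pert$vertices$x[i2] - pert$vertices$x[i1])^2 +
      (pert$vertices$y[i2] - pert$vertices$y[i1])^2)
  vd <- voronoi_deviation(pert, 1)
  pts <- cbind(pert$cells$centroid_x, pert$cells$centroid_y)
  # oracle: walk the bisector of a pair and measure where the two cells are
  # the joint nearest generators
  bisector_length <- function(a, b) {
    pa <- pts[a, ]; pb <- pts[b, ]
    m <- (pa + pb) / 2
    d <- pb - pa
    t_dir <- c(-d[2], d[1]) / sqrt(sum(d^2))
    ts <- seq(-3, 3, by = 0.0015)
    onedge <- vapply(ts, function(t) {
      p <- m + t * t_dir
      dd <- sqrt(rowSums(sweep(pts, 2, p)^2))
      ord <- order(dd)
      all(sort(ord[1:2]) == sort(c(a, b)))
    }, logical(1))
    sum(onedge) * 0.0015
  }
  rows <- vd$interfaces[sample(nrow(vd$interfaces), 8), ]
  ia <- match(rows$cell_a, pert$cells$cell_id)
  ib <- match(rows$cell_b, pert$cells$cell_id)
  for (k in seq_len(nrow(rows))) {
    expect_equal(rows$predicted[k], bisector_length(ia[k], ib[k]),
                 tolerance = 0.01)
  }
})

test_that("event-aligned averages behave like the definition", {
  ev <- tibble::tibble(time = c(10, 20),
                       shrinking_interface = c(1L, 2L))
  ser <- dplyr::bind_rows(
    tibble::tibble(interface_id = 1L, time = seq(5, 15, 0.5), value = 2),
    tibble::tibble(interface_id = 2L, time = seq(15, 25, 0.5), value = 4))
  al <- align_to_t1(ser, ev)
  # constant series align to a flat curve; two events average pointwise
  expect_true(all(abs(al$value - 3) < 1e-12))
  expect_equal(sort(unique(al$rel_min)), -5:5)
  # single event: curve is the series itself
  al1 <- align_to_t1(ser[ser$interface_id == 1L, ], ev[1, ])
  expect_true(all(al1$value == 2))
  expect_equal(nrow(align_to_t1(ser, ev[0, ])), 0L)
})

test_that("recoil regression recovers slopes and compares groups", {
  tm <- seq(0.5, 5, by = 0.5)
  df <- dplyr::bind_rows(
    tibble::tibble(ablation_id = 1L, group = "PSB", time = tm,
                   distance = 1 + 0.2245 * tm),
    tibble::tibble(ablation_id = 2L, group = "plus1", time = tm,
                   distance = 1 + 0.1084 * tm))
  fit <- suppressWarnings(recoil_regression(df, n_post = 5))
  td <- tidy(fit)
  expect_equal(td$slope[td$group == "PSB"], 0.2245, tolerance = 1e-12)
  expect_equal(td$slope[td$group == "plus1"], 0.1084, tolerance = 1e-12)
  expect_equal(td$slope[td$group == "PSB"] / td$slope[td$group == "plus1"],
               2.07, tolerance = 0.01)
  # only the first n_post post-ablation points are used
  df2 <- df
  df2$distance[df2$time > 2.5] <- 99
  fit2 <- suppressWarnings(recoil_regression(df2, n_post = 5))
  expect_equal(tidy(fit2)$slope, td$slope)
  # noiseless groups with slopes s and 2s differ significantly
  df3 <- dplyr::bind_rows(
    tibble::tibble(ablation_id = 1L, group = "a", time = tm,
                   distance = 0.1 * tm + rnorm(10, 0, 1e-6)),
    tibble::tibble(ablation_id = 2L, group = "b", time = tm,
                   distance = 0.2 * tm + rnorm(10, 0, 1e-6)))
  fit3 <- suppressWarnings(recoil_regression(df3, n_post = 5))
  expect_lt(glance(fit3)$equal_slopes_p[1], 1e-6)
})

test_that("recoil slope confidence intervals achieve nominal coverage", {
  set.seed(17)
  tm <- seq(0.5, 2.5, by = 0.5)
  slope <- 0.25
  hits <- 0L
  nsim <- 400
  for (s in seq_len(nsim)) {
    d <- tibble::tibble(time = tm, distance = 1 + slope * tm +
                          rnorm(5, 0, 0.05))
    ci <- tidy(recoil_regression(d, n_post = 5))
    hits <- hits + (ci$conf.low <= slope && slope <= ci$conf.high)
  }
  expect_gte(hits / nsim, 0.9)
})
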