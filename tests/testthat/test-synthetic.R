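# Synthetic-data generators: perimeter signals, hex tissues, scripted T1
# movies and identity painting.

test_that("perimeter signals follow the generative double-Gaussian model", {
  # zero amplitudes, no noise: constant at baseline
  s <- make_perimeter_signal(signal_spec(baseline = 3))
  expect_equal(s$intensity, rep(3, 6))
  # equal amplitudes: symmetric under theta -> theta + 180
  s2 <- make_perimeter_signal(signal_spec(anterior_amplitude = 1,
                                          posterior_amplitude = 1))
  expect_equal(s2$intensity[1:3], s2$intensity[c(4:6)], tolerance = 1e-12)
  # side means match a numerical quadrature oracle of the generative model
  spec <- signal_spec(baseline = 1, anterior_amplitude = 1,
                      posterior_amplitude = 2, gaussian_sd = 30)
  s3 <- make_perimeter_signal(spec)
  w <- 60
  for (k in 1:6) {
    a <- (k - 1) * w - w / 2
    expected <- 1 +
      2 * gauss_arc_mean_quadrature(a, a + w, 0, 30) +
      1 * gauss_arc_mean_quadrature(a, a + w, 180, 30)
    expect_equal(s3$intensity[k], expected, tolerance = 1e-8)
  }
  # fixed seed gives bit-identical noisy output
  n1 <- make_perimeter_signal(signal_spec(noise_sd = 0.2, seed = 11))
  n2 <- make_perimeter_signal(signal_spec(noise_sd = 0.2, seed = 11))
  expect_identical(n1$intensity, n2$intensity)
})

test_that("stripe plans carry parasegments of width 4 and 3 with discontinuous S3/S4", {
  pl <- default_stripe_plan(20, 14)
  expect_equal(dim(pl$stripe), c(20, 14))
  expect_equal(as.vector(table(pl$parasegment[1, ])), c(4L, 3L, 4L, 3L))
  # first two columns of each parasegment are S1 then S2
  for (p in 1:4) {
    cc <- which(pl$parasegment[1, ] == p)
    expect_true(all(pl$stripe[, cc[1]] == 1L))
    expect_true(all(pl$stripe[, cc[2]] == 2L))
    # remaining columns mix identities 3 and 4 (discontinuous stripes)
    rest <- pl$stripe[, cc[-(1:2)], drop = FALSE]
    expect_setequal(unique(as.vector(rest)), c(3L, 4L))
  }
  expect_error(make_hex_tissue(3, 5, stripe_plan = default_stripe_plan(4, 5)),
               "rows x cols")
})

test_that("scripted T1 movies encode their ground truth", {
  for (p in c("clean", "flicker", "revert")) {
    mv <- make_scripted_t1_movie(p)
    expect_silent(validate_tissue(mv))
    truth <- attr(mv, "t1_truth")
    n_expected <- if (p == "revert") 0L else 1L
    expect_equal(nrow(truth), n_expected)
  }
  truth <- attr(make_scripted_t1_movie("flicker"), "t1_truth")
  expect_equal(truth$time, 10)  # the persisting swap, 2 min after the first
  # central interface swaps ownership 3|4 -> 1|2
  mv <- make_scripted_t1_movie("clean")
  pre <- mv$interfaces[mv$interfaces$frame == 1 &
                         mv$interfaces$interface_id == 100L, ]
  post <- mv$interfaces[mv$interfaces$frame == max(mv$interfaces$frame) &
                          mv$interfaces$interface_id == 101L, ]
  expect_equal(c(pre$cell_a, pre$cell_b), c(3L, 4L))
  expect_equal(c(post$cell_a, post$cell_b), c(1L, 2L))
})

test_that("painting assigns identity-dependent intensities with the 1:2:8 scheme", {
  tt <- make_hex_tissue(6, 8)
  painted <- paint_movie(tt, movie_paint_spec())
  cls <- classify_interfaces(painted)
  ifc <- dplyr::left_join(painted$interfaces, cls,
                          by = c("frame", "interface_id"))
  expect_true(all(ifc$intensity[ifc$class == "nonboundary"] == 1))
  expect_true(all(ifc$intensity[ifc$class %in%
                                  c("PSB", "S1/2B", "S2/3B", "S3/4B")] == 2))
  expect_true(all(ifc$intensity[ifc$class == "superboundary"] == 8))
  # uniform identities: everything at nonboundary level
  pl <- default_stripe_plan(3, 3)
  pl$stripe[] <- 1L
  flat <- paint_movie(make_hex_tissue(3, 3, stripe_plan = pl))
  expect_true(all(flat$interfaces$intensity == 1))
  # doming dims the corners relative to the centre
  dome <- paint_movie(tt, movie_paint_spec(doming_amplitude = 0.5))
  vs <- dome$vertices
  ctr <- c(mean(range(vs$x)), mean(range(vs$y)))
  i1 <- match(dome$interfaces$v1, vs$vertex_id)
  i2 <- match(dome$interfaces$v2, vs$vertex_id)
  mx <- (vs$x[i1] + vs$x[i2]) / 2
  my <- (vs$y[i1] + vs$y[i2]) / 2
  r <- sqrt((mx - ctr[1])^2 + (my - ctr[2])^2)
  nb <- cls$class == "nonboundary"
  expect_lt(cor(r[nb], dome$interfaces$intensity[nb]), -0.8)
})

test_that("plot functions return ggplot objects", {
  tt <- paint_movie(make_hex_tissue(3, 4))
  expect_s3_class(plot_tissue(tt, 1), "ggplot")
  pol <- tibble::tibble(time = rep(1:4, each = 10), centroid_x = runif(40),
                        v = rnorm(40))
  expect_s3_class(plot_polarity_map(polarity_maps(pol, "v", n_time_bins = 4,
                                                  n_ap_bins = 4)), "ggplot")
  co <- coalignment(tibble::tibble(class = "PSB", time = rep(1:5, 10),
                                   orientation = runif(50, 0, 180)))
  expect_s3_class(plot_coalignment(co), "ggplot")
  expect_s3_class(plot_score_histogram(search_patterns(1, "exhaustive")),
                  "ggplot")
})
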