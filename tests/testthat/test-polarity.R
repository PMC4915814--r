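# Polarity quantification: background subtraction, exact Fourier
# decomposition, constrained double-Gaussian fits, doming correction, maps.

test_that("modal background subtraction clips at zero", {
  expect_equal(subtract_background(rep(7, 100)), rep(0, 100))
  x <- c(rep(10, 90), rep(50, 10))
  expect_equal(subtract_background(x), c(rep(0, 90), rep(40, 10)))
  # matches a direct histogram-mode oracle on a synthetic integer field
  set.seed(3)
  field <- c(rpois(900, 4), rpois(100, 40))
  tab <- table(field)
  mode_val <- as.numeric(names(tab)[which.max(tab)])
  expect_equal(subtract_background(field), pmax(field - mode_val, 0))
})

test_that("Fourier polarity integrates the castellated signal exactly", {
  s0 <- make_perimeter_signal(signal_spec(baseline = 2))
  f0 <- fourier_polarity(s0)
  expect_equal(f0$period1_amplitude, 0, tolerance = 1e-12)
  expect_equal(f0$period2_amplitude, 0, tolerance = 1e-12)
  # continuous 1 + cos(2 theta), finely castellated: amplitude 1, phase 0
  th <- seq(0, 360, length.out = 1441)[-1441]
  sig <- tibble::tibble(arc_start = th, arc_end = th + 0.25,
                        intensity = 1 + cos(2 * th * pi / 180))
  f2 <- fourier_polarity(sig)
  expect_equal(f2$period2_amplitude, 1, tolerance = 1e-3)
  expect_lt(min(f2$period2_phase, 180 - f2$period2_phase), 0.5)
  # hexagon with one side elevated: period-2 present and in phase with
  # period-1, matching a dense-sampling DFT oracle
  s1 <- make_perimeter_signal(signal_spec(baseline = 1))
  s1$intensity[1] <- 2
  fp <- fourier_polarity(s1)
  expect_gt(fp$period2_amplitude, 0.05)
  dph <- abs(fp$period1_phase %% 180 - fp$period2_phase)
  expect_lt(min(dph, 180 - dph), 1)
  # dense-sampling DFT oracle
  thg <- seq(0, 360, length.out = 72001)[-72001]
  val <- s1$intensity[findInterval((thg + 30) %% 360, seq(0, 360, by = 60),
                                   rightmost.closed = TRUE)]
  a2 <- 2 * mean(val * cos(2 * thg * pi / 180))
  b2 <- 2 * mean(val * sin(2 * thg * pi / 180))
  expect_equal(fp$period2_amplitude, sqrt(a2^2 + b2^2), tolerance = 1e-3)
})

test_that("polarity measures are invariant to arc rotation and scale correctly", {
  spec <- signal_spec(baseline = 1, anterior_amplitude = 0.8,
                      posterior_amplitude = 1.5, gaussian_sd = 35)
  s <- make_perimeter_signal(spec)
  rot <- dplyr::bind_rows(s[3:6, ], s[1:2, ])
  expect_equal(fourier_polarity(rot)[, 1:4], fourier_polarity(s)[, 1:4],
               tolerance = 1e-10)
  g1 <- gaussian_polarity(s)
  g2 <- gaussian_polarity(rot)
  expect_equal(g2$unipolarity_pp, g1$unipolarity_pp, tolerance = 1e-6)
  # scaling by c scales amplitudes but not the normalised pp values
  s3 <- s; s3$intensity <- 3 * s3$intensity
  f1 <- fourier_polarity(s); f3 <- fourier_polarity(s3)
  expect_equal(f3$period2_amplitude, 3 * f1$period2_amplitude)
  g3 <- gaussian_polarity(s3)
  expect_equal(g3$bipolarity_pp, g1$bipolarity_pp, tolerance = 1e-6)
  expect_equal(g3$unipolarity_pp, g1$unipolarity_pp, tolerance = 1e-6)
})

test_that("the Gaussian fit separates uni- and bipolarity where Fourier cannot", {
  # pure bipolar castellated signal: Gaussian unipolarity ~ 0
  bi <- make_perimeter_signal(signal_spec(anterior_amplitude = 1,
                                          posterior_amplitude = 1,
                                          gaussian_sd = 30))
  gb <- gaussian_polarity(bi)
  expect_lt(abs(gb$unipolarity_pp), 1e-6)
  expect_gt(gb$bipolarity_pp, 0.05)
  # pure unipolar castellated signal: Fourier period-2 is contaminated
  # (strictly positive, in phase with period 1) while Gaussian bipolarity ~ 0
  uni <- make_perimeter_signal(signal_spec(posterior_amplitude = 2,
                                           gaussian_sd = 30))
  fu <- fourier_polarity(uni)
  gu <- gaussian_polarity(uni)
  expect_gt(fu$period2_amplitude, 0.05)
  dph <- abs(fu$period1_phase %% 180 - fu$period2_phase)
  expect_lt(min(dph, 180 - dph), 1)
  expect_lt(gu$bipolarity_pp, 1e-6)
  expect_gt(gu$unipolarity_pp, 0.1)
  # sign convention: posterior enrichment positive, anterior negative
  ant <- make_perimeter_signal(signal_spec(anterior_amplitude = 2,
                                           gaussian_sd = 30))
  expect_lt(gaussian_polarity(ant)$unipolarity_pp, 0)
})

test_that("the Gaussian fit recovers generator parameters", {
  spec <- signal_spec(baseline = 1, anterior_amplitude = 1,
                      posterior_amplitude = 2, gaussian_sd = 30)
  g <- gaussian_polarity(make_perimeter_signal(spec))
  expect_true(g$converged)
  expect_equal(g$anterior_amplitude, 1, tolerance = 0.05)
  expect_equal(g$posterior_amplitude, 2, tolerance = 0.05)
  expect_equal(g$shared_sd, 30, tolerance = 0.05)
  # degenerate inputs are rejected
  expect_error(gaussian_polarity(make_perimeter_signal(
    signal_spec(n_sides = 3))), "at least 4")
})

test_that("doming correction removes a linear ramp but preserves cell means", {
  tt <- paint_movie(make_hex_tissue(6, 8), movie_paint_spec())
  sig <- perimeter_signals(tt, 1)
  # spatially uniform field: unchanged
  flat <- sig; flat$intensity <- 2
  out <- correct_doming(flat)
  expect_equal(out$intensity, flat$intensity, tolerance = 1e-9)
  # pure linear ramp with flat true signal: corrected unipolarity ~ 0
  ramp <- sig
  ramp$intensity <- 1 + 0.3 * ramp$mid_x
  cor1 <- correct_doming(ramp)
  cid <- ramp$cell_id[which.max(table(ramp$cell_id))][1]
  per_cell <- cor1[cor1$cell_id == cid, ]
  expect_lt(fourier_polarity(per_cell)$period1_amplitude, 1e-6)
  # mean preservation for a random field
  set.seed(9)
  rnd <- sig
  rnd$intensity <- runif(nrow(rnd), 0.5, 2)
  cor2 <- correct_doming(rnd)
  m0 <- tapply((rnd$arc_end - rnd$arc_start) * rnd$intensity, rnd$cell_id, sum)
  m1 <- tapply((cor2$arc_end - cor2$arc_start) * cor2$intensity,
               cor2$cell_id, sum)
  expect_equal(unname(m1), unname(m0), tolerance = 1e-9)
})

test_that("polarity maps mask under-sampled and non-significant squares", {
  set.seed(2)
  df <- tibble::tibble(time = rep(1:10, each = 30),
                       centroid_x = runif(300, 0, 60),
                       v = 0)
  mp <- polarity_maps(df, "v", n_time_bins = 5, n_ap_bins = 4)
  expect_true(all(!mp$significant | is.na(mp$p)))
  # grid square with a single observation is masked
  df1 <- tibble::tibble(time = c(1, 10), centroid_x = c(0, 60), v = c(5, 5))
  mp1 <- polarity_maps(df1, "v", n_time_bins = 2, n_ap_bins = 2)
  expect_true(all(!mp1$significant))
  # strong consistent signal is flagged
  df2 <- tibble::tibble(time = rep(1, 50), centroid_x = rep(1, 50),
                        v = rnorm(50, 3, 0.1))
  mp2 <- polarity_maps(df2, "v", n_time_bins = 1, n_ap_bins = 1)
  expect_true(all(mp2$significant))
})
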