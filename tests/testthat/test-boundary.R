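# Boundary analysis: label propagation, coordinates, cells-per-parasegment,
# Myosin comparisons, co-alignment, interface fates, T1 profiles.

test_that("labels backtrack through static movies and scripted T1s", {
  mv <- replicate_frames(make_hex_tissue(3, 4), 4)
  last <- max(mv$times$frame)
  labs <- tibble::tibble(cell_id = mv$cells$cell_id[mv$cells$frame == last],
                         label = mv$cells$parasegment[mv$cells$frame == last])
  out <- backtrack_labels(mv, labs, ref_frame = last)
  joined <- dplyr::inner_join(out, mv$cells, by = c("frame", "cell_id"))
  expect_equal(joined$label, joined$parasegment)
  # labels survive a neighbour exchange
  t1 <- make_scripted_t1_movie("clean")
  labs2 <- tibble::tibble(cell_id = 1:4, label = c("a", "b", "c", "d"))
  out2 <- backtrack_labels(t1, labs2, ref_frame = max(t1$times$frame))
  expect_equal(out2$label[out2$frame == 1][order(out2$cell_id[out2$frame == 1])],
               c("a", "b", "c", "d"))
  # conflicting labels error with the cell named
  bad <- tibble::tibble(cell_id = c(1L, 1L), label = c("a", "b"))
  expect_error(backtrack_labels(t1, bad, 1), "conflicting")
})

test_that("within-parasegment coordinates are monotone cell-centre positions", {
  tt <- make_hex_tissue(1, 4,
                        stripe_plan = list(stripe = matrix(1:4, 1),
                                           parasegment = matrix(1L, 1, 4)))
  wc <- within_parasegment_coordinate(tt, 1)
  expect_equal(sort(wc$coordinate), c(0.125, 0.375, 0.625, 0.875))
  expect_equal(order(wc$centroid_x), order(wc$coordinate))
  # single-cell parasegment row sits at 0.5
  one <- make_hex_tissue(1, 1,
                         stripe_plan = list(stripe = matrix(1L, 1, 1),
                                            parasegment = matrix(1L, 1, 1)))
  expect_equal(within_parasegment_coordinate(one, 1)$coordinate, 0.5)
})

test_that("cells per parasegment counts AP columns", {
  # 4 identical cells of AP width w in one row -> ratio 4
  tt <- make_hex_tissue(1, 4,
                        stripe_plan = list(stripe = matrix(1:4, 1),
                                           parasegment = matrix(1L, 1, 4)))
  cpp <- cells_per_parasegment(tt, 1)
  expect_equal(cpp$average, 4, tolerance = 1e-9)
  # hex tissue with 4-column parasegments
  tt2 <- make_hex_tissue(6, 8)
  cpp2 <- cells_per_parasegment(tt2, 1)
  expect_equal(cpp2$per_parasegment$cells_per_parasegment, c(4, 4),
               tolerance = 0.15)
  # empty parasegment: explicit undefined result
  tt3 <- tt2
  tt3$cells$parasegment <- NA_character_
  expect_true(is.na(cells_per_parasegment(tt3, 1)$average))
})

test_that("interface classes follow stripe identities", {
  tt <- make_hex_tissue(6, 8)
  cls <- classify_interfaces(tt)
  expect_setequal(unique(cls$class),
                  c("PSB", "S1/2B", "S2/3B", "S3/4B", "superboundary",
                    "nonboundary", "other"))
  ifc <- dplyr::left_join(tt$interfaces, cls, by = c("frame", "interface_id"))
  expect_true(all(is.na(ifc$cell_b[ifc$class == "other"])))
  # PSB separates different parasegments
  ps <- setNames(tt$cells$parasegment, tt$cells$cell_id)
  psb <- ifc[ifc$class == "PSB", ]
  expect_true(all(ps[as.character(psb$cell_a)] !=
                    ps[as.character(psb$cell_b)]))
})

test_that("ribbon confidence intervals combine between- and within-embryo variance", {
  set.seed(21)
  df <- tidyr::expand_grid(embryo = c("e1", "e2", "e3"),
                           class = c("boundary", "plus1"),
                           time = seq(0.1, 4.9, by = 0.2),
                           rep = 1:4) |>
    dplyr::mutate(intensity = 1 + (class == "boundary") * 2 +
                    rnorm(dplyr::n(), 0, 0.3) +
                    rep(rnorm(3, 0, 0.2),
                        each = dplyr::n() / 3))
  res <- boundary_myosin_comparison(df, reference = "boundary")
  s <- res$summary
  expect_true(all(s$ribbon > 0))
  # ribbon formula: sqrt(var of embryo means + mean within-embryo variance)
  one <- df[df$class == "boundary" & df$time < 1 + 1e-9, ] |>
    dplyr::mutate(bin = 0)
  pe <- tapply(one$intensity, one$embryo, mean)
  wv <- tapply(one$intensity, one$embryo, var)
  expect_equal(s$ribbon[s$class == "boundary" & s$bin == 0],
               sqrt(var(pe) + mean(wv)))
  # a 2x intensity difference is flagged; identical classes are not
  expect_true(any(res$tests$significant))
  df2 <- df; df2$intensity <- 1
  res2 <- boundary_myosin_comparison(df2, reference = "boundary")
  expect_true(all(!res2$tests$significant | is.na(res2$tests$p)))
  # single embryo: ribbon reduces to the within-embryo term, tests NA
  df1 <- df[df$embryo == "e1", ]
  res1 <- boundary_myosin_comparison(df1, reference = "boundary")
  expect_true(all(is.na(res1$tests$p)))
})

test_that("co-alignment statistics behave analytically", {
  # all interfaces at 90 degrees: proportion 1, kappa large
  df <- tibble::tibble(class = "PSB", time = rep(1:5, each = 20),
                       orientation = 90)
  co <- coalignment(df)
  expect_true(all(co$proportion$prop == 1))
  expect_gt(min(co$kappa$kappa), 50)
  # uniform orientations: proportion ~ 1/3, kappa ~ 0
  set.seed(8)
  df2 <- tibble::tibble(class = "any", time = rep(1, 6000),
                        orientation = runif(6000, 0, 180))
  co2 <- coalignment(df2)
  expect_equal(co2$proportion$prop, 1 / 3, tolerance = 0.05)
  expect_lt(abs(co2$kappa$kappa), 0.1)
  # KS test separates distinct von Mises samples at reasonable power
  set.seed(9)
  rvm <- function(n, mu, kappa) {
    # acceptance sampling; fine for test-scale n
    out <- numeric(0)
    while (length(out) < n) {
      th <- runif(2 * n, -pi, pi)
      u <- runif(2 * n)
      keep <- u < exp(kappa * (cos(th) - 1))
      out <- c(out, th[keep])
    }
    (out[1:n] + mu) * 90 / pi
  }
  rejections <- 0L
  for (r in 1:10) {
    a <- abs(rvm(150, 0, 2))
    b <- abs(rvm(150, pi / 2, 2))
    df3 <- tibble::tibble(class = rep(c("a", "b"), each = 150), time = 1,
                          orientation = c(a, b))
    co3 <- coalignment(df3, at_time = 1)
    rejections <- rejections + (co3$ks_tests$p.value < 0.05)
  }
  expect_gte(rejections, 8)
})

test_that("interface fates partition S1/S2 interfaces into exclusive categories", {
  tt <- replicate_frames(make_hex_tissue(6, 8), 3)
  fates <- classify_interface_fates(tt, events = detect_t1(tt))
  expect_true(all(fates$category %in%
                    c("boundary_noT1", "boundary_T1_staysBoundary",
                      "boundary_T1_becomesNonboundary", "superboundary",
                      "nonboundary", "nonboundary_T1")))
  # static movie: no T1 categories
  expect_true(all(is.na(fates$t1_time)))
  expect_true(any(fates$category == "boundary_noT1"))
  expect_true(any(fates$category == "nonboundary"))
})

test_that("T1 position profiles histogram events by within-stripe coordinate", {
  tt <- replicate_frames(make_hex_tissue(6, 8), 3)
  # no events: all-zero histogram
  prof0 <- t1_position_profile(tt, detect_t1(tt))
  expect_true(all(prof0$count == 0))
  # synthetic events on stripe-edge cells produce edge-binned counts
  ev <- tibble::tibble(time = 1, losing_a = 1L, losing_b = 2L,
                       gaining_a = 3L, gaining_b = 4L,
                       shrinking_interface = NA_integer_,
                       growing_interface = NA_integer_)
  prof <- t1_position_profile(tt, ev)
  expect_equal(sum(prof$count) > 0, TRUE)
})

test_that("flanking classes mark the columns one cell from a boundary", {
  tt <- make_hex_tissue(6, 8)
  fl <- flanking_classes(tt, boundary = "PSB")
  cls <- classify_interfaces(tt)
  expect_equal(fl$class[cls$class == "PSB"],
               rep("boundary", sum(cls$class == "PSB")))
  # minus1 interfaces live inside the stripe anterior of the PSB (S4),
  # plus1 inside the posterior one (S1)
  st <- setNames(tt$cells$stripe, tt$cells$cell_id)
  ifc <- tt$interfaces
  m1 <- ifc[fl$class == "minus1", ]
  expect_true(all(st[as.character(m1$cell_a)] == "S4" &
                    st[as.character(m1$cell_b)] == "S4"))
  p1 <- ifc[fl$class == "plus1", ]
  expect_true(all(st[as.character(p1$cell_a)] == "S1" &
                    st[as.character(p1$cell_b)] == "S1"))
  expect_gt(nrow(m1), 0)
  expect_gt(nrow(p1), 0)
})

test_that("a boundary interface that swaps into a stripe becomes nonboundary in its fate", {
  mv <- make_scripted_t1_movie("clean")
  # label the quartet: losing pair 3|4 heterotypic (S1|S2), gaining pair
  # 1|2 homotypic (S1|S1), all in one parasegment
  mv$cells$parasegment <- "PS1"
  mv$cells$stripe <- c("S1", "S1", "S1", "S2")[mv$cells$cell_id]
  ev <- detect_t1(mv)
  expect_equal(nrow(ev), 1L)
  fates <- classify_interface_fates(mv, ev, stripes = c(1L, 2L))
  itr <- interface_tracks(mv)
  tr100 <- itr$track[itr$frame == 1 & itr$id == 100L]
  fate_central <- fates$category[fates$track == tr100]
  expect_equal(fate_central, "boundary_T1_becomesNonboundary")
  expect_equal(fates$t1_time[fates$track == tr100], 8)
})
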