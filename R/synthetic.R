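#' Specification of a synthetic castellated perimeter signal
#'
#' Generative counterpart of the double-Gaussian polarity model: a cell with
#' `n_sides` interfaces whose perimeter fluorescence is piecewise constant
#' ("castellated"), with a posterior Gaussian peak centred at 0 degrees and an
#' anterior peak at 180 degrees, both sharing one standard deviation.
#'
#' @param baseline Baseline intensity (a.u.).
#' @param anterior_amplitude,posterior_amplitude Peak heights (a.u., >= 0) of
#'   the Gaussians centred at 180 (anterior) and 0 (posterior) degrees.
#' @param gaussian_sd Shared standard deviation (degrees).
#' @param n_sides Number of interfaces (>= 3).
#' @param noise_sd Additive white noise on side means (a.u.).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return An object of class `signal_spec` (a list).
#' @export
signal_spec <- function(baseline = 1, anterior_amplitude = 0,
                        posterior_amplitude = 0, gaussian_sd = 30,
                        n_sides = 6L, noise_sd = 0, seed = 1L) {
  stopifnot(anterior_amplitude >= 0, posterior_amplitude >= 0,
            n_sides >= 3L, gaussian_sd > 0, noise_sd >= 0, baseline >= 0)
  structure(list(baseline = baseline,
                 anterior_amplitude = anterior_amplitude,
                 posterior_amplitude = posterior_amplitude,
                 gaussian_sd = gaussian_sd, n_sides = as.integer(n_sides),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "signal_spec")
}

# mean over [a, b] (degrees) of a unit-amplitude Gaussian centred at mu with
# sd s, wrapped on the circle (sum of +-360 and +-720 degree images)
.gauss_arc_mean <- function(a, b, mu, s) {
  stopifnot(all(b > a))
  tot <- 0
  for (k in -2:2) {
    m <- mu + 360 * k
    tot <- tot + s * sqrt(pi / 2) *
      (pracma::erf((b - m) / (s * sqrt(2))) -
         pracma::erf((a - m) / (s * sqrt(2))))
  }
  tot / (b - a)
}

#' Generate a castellated perimeter signal
#'
#' Produces the `n_sides` arc means of the generative model in
#' [signal_spec()]: each side's intensity is the baseline plus the arc
#' average of the two wrapped Gaussians, plus optional white noise. Sides are
#' equal arcs; the first side is centred on 0 degrees (East/posterior) and
#' sides proceed anticlockwise.
#'
#' @param spec A [signal_spec()].
#' @return A `perimeter_signal` tibble with columns `arc_start`, `arc_end`
#'   (degrees, `arc_end > arc_start`, covering 360 degrees in total) and
#'   `intensity`.
#' @export
make_perimeter_signal <- function(spec) {
  stopifnot(inherits(spec, "signal_spec"))
  w <- 360 / spec$n_sides
  start <- (seq_len(spec$n_sides) - 1) * w - w / 2
  end <- start + w
  base <- spec$baseline +
    spec$posterior_amplitude * .gauss_arc_mean(start, end, 0, spec$gaussian_sd) +
    spec$anterior_amplitude * .gauss_arc_mean(start, end, 180, spec$gaussian_sd)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    base <- base + rnorm(spec$n_sides, 0, spec$noise_sd)
  }
  sig <- tibble::tibble(arc_start = start %% 360,
                        arc_end = start %% 360 + w,
                        intensity = pmax(base, 0))
  class(sig) <- c("perimeter_signal", class(sig))
  sig
}

.default_hex_radius <- function(cell_area) sqrt(2 * cell_area / (3 * sqrt(3)))

#' Default stripe plan for a hexagonal tissue
#'
#' Splits `cols` anteroposterior columns into parasegments of alternating
#' width 4 and 3 (any remainder is absorbed into the last parasegment). In
#' each parasegment the first column is stripe S1 and the second S2; the
#' remaining one or two columns carry the discontinuous S3/S4 region, with
#' S3 and S4 interleaved between successive dorsoventral rows so that neither
#' forms a continuous column (their combined width averages 1.5 cells for a
#' 3.5-column parasegment).
#'
#' @param rows,cols Lattice dimensions (rows along DV, columns along AP).
#' @return A list with integer matrices `stripe` (identities 1--4) and
#'   `parasegment`, both `rows x cols`.
#' @export
default_stripe_plan <- function(rows, cols) {
  widths <- integer(0)
  left <- cols
  w <- 4L
  while (left > 0L) {
    if (left <= 6L) { widths <- c(widths, left); break }
    widths <- c(widths, w)
    left <- left - w
    w <- if (w == 4L) 3L else 4L
  }
  stripe <- matrix(0L, rows, cols)
  ps <- matrix(0L, rows, cols)
  col0 <- 0L
  for (p in seq_along(widths)) {
    wd <- widths[p]
    for (j in seq_len(wd)) {
      cc <- col0 + j
      ps[, cc] <- p
      if (j == 1L) {
        stripe[, cc] <- 1L
      } else if (j == 2L) {
        stripe[, cc] <- 2L
      } else if (j == 3L && wd == 3L) {
        stripe[, cc] <- ifelse(seq_len(rows) %% 2L == 1L, 3L, 4L)
      } else if (j == 3L) {
        stripe[, cc] <- ifelse(seq_len(rows) %% 2L == 1L, 3L, 4L)
      } else {
        stripe[, cc] <- ifelse(seq_len(rows) %% 2L == 1L, 4L, 3L)
      }
    }
    col0 <- col0 + wd
  }
  list(stripe = stripe, parasegment = ps)
}

#' Generate a regular hexagonal tissue frame
#'
#' Builds a `rows x cols` lattice of regular hexagons (flat left/right
#' columns along AP, so interfaces between AP-adjacent cells are DV-oriented
#' at 60--90 degrees), organised into parasegments with stripe identities per
#' the stripe plan.
#'
#' @param rows Number of cells along DV.
#' @param cols Number of cell columns along AP.
#' @param cell_area Area per cell (square micrometres).
#' @param stripe_plan A list as returned by [default_stripe_plan()], or
#'   `NULL` for the default; its matrices must be `rows x cols`.
#' @param time Frame time in minutes.
#' @return A single-frame [tracked_tissue()].
#' @export
make_hex_tissue <- function(rows, cols, cell_area = 1,
                            stripe_plan = default_stripe_plan(rows, cols),
                            time = 0) {
  stopifnot(rows >= 1, cols >= 1, cell_area > 0)
  if (!is.null(stripe_plan)) {
    if (!all(dim(stripe_plan$stripe) == c(rows, cols))) {
      stop("stripe_plan dimensions must be rows x cols", call. = FALSE)
    }
  }
  R <- .default_hex_radius(cell_area)
  ang <- (0:5) * 60 * pi / 180
  hx <- R * cos(ang); hy <- R * sin(ang)
  key <- function(x, y) paste(round(x / R * 1e6), round(y / R * 1e6))
  vx <- numeric(0); vy <- numeric(0)
  vid <- new.env(parent = emptyenv())
  nextv <- 0L
  cells <- vector("list", rows * cols)
  ci <- 0L
  for (cc in seq_len(cols)) {
    for (rr in seq_len(rows)) {
      cx <- (cc - 1) * 1.5 * R
      cy <- (rr - 1) * sqrt(3) * R + if (cc %% 2 == 0) sqrt(3) * R / 2 else 0
      ids <- integer(6)
      for (k in 1:6) {
        kk <- key(cx + hx[k], cy + hy[k])
        id <- vid[[kk]]
        if (is.null(id)) {
          nextv <- nextv + 1L
          id <- nextv
          assign(kk, id, envir = vid)
          vx[id] <- cx + hx[k]; vy[id] <- cy + hy[k]
        }
        ids[k] <- id
      }
      ci <- ci + 1L
      st <- if (is.null(stripe_plan)) NA_integer_ else stripe_plan$stripe[rr, cc]
      pg <- if (is.null(stripe_plan)) NA_integer_ else stripe_plan$parasegment[rr, cc]
      cells[[ci]] <- list(cell_id = ci, centroid_x = cx, centroid_y = cy,
                          stripe = st, parasegment = pg, vertices = ids)
    }
  }
  cells_tbl <- tibble::tibble(
    frame = 1L,
    cell_id = vapply(cells, `[[`, integer(1), "cell_id"),
    centroid_x = vapply(cells, `[[`, numeric(1), "centroid_x"),
    centroid_y = vapply(cells, `[[`, numeric(1), "centroid_y"),
    parasegment = ifelse(is.na(vapply(cells, `[[`, integer(1), "parasegment")),
                         NA_character_,
                         paste0("PS", vapply(cells, `[[`, integer(1),
                                             "parasegment"))),
    stripe = ifelse(is.na(vapply(cells, `[[`, integer(1), "stripe")),
                    NA_character_,
                    paste0("S", vapply(cells, `[[`, integer(1), "stripe"))),
    flag = "germband",
    vertices = lapply(cells, `[[`, "vertices"))
  vertices_tbl <- tibble::tibble(frame = 1L, vertex_id = seq_len(nextv),
                                 x = vx, y = vy)
  interfaces_tbl <- .interfaces_from_polygons(cells_tbl, vertices_tbl)
  tracked_tissue(cells_tbl, vertices_tbl, interfaces_tbl,
                 times = tibble::tibble(frame = 1L, time = time))
}

# derive the interface table from cell polygons (edges shared by two cells
# stored once with cell_a < cell_b; border edges get cell_b = NA)
.interfaces_from_polygons <- function(cells_tbl, vertices_tbl) {
  frames <- unique(cells_tbl$frame)
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cs <- cells_tbl[cells_tbl$frame == f, ]
    vs <- vertices_tbl[vertices_tbl$frame == f, ]
    ed <- list()
    for (k in seq_len(nrow(cs))) {
      vv <- cs$vertices[[k]]
      n <- length(vv)
      j <- c(2:n, 1L)
      ed[[k]] <- tibble::tibble(a = pmin(vv, vv[j]), b = pmax(vv, vv[j]),
                                cell = cs$cell_id[k])
    }
    ed <- dplyr::bind_rows(ed) |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(cell_a = min(.data$cell),
                       cell_b = if (dplyr::n() > 1L) max(.data$cell) else
                         NA_integer_,
                       n = dplyr::n(), .groups = "drop")
    if (any(ed$n > 2L)) stop("edge shared by more than two cells")
    i1 <- match(ed$a, vs$vertex_id); i2 <- match(ed$b, vs$vertex_id)
    out[[fi]] <- tibble::tibble(
      frame = f,
      interface_id = seq_len(nrow(ed)),
      v1 = ed$a, v2 = ed$b, cell_a = ed$cell_a, cell_b = ed$cell_b,
      length = sqrt((vs$x[i2] - vs$x[i1])^2 + (vs$y[i2] - vs$y[i1])^2),
      intensity = NA_real_)
  }
  dplyr::bind_rows(out)
}

#' Scripted four-cell T1 fixture movie
#'
#' Builds a quartet of cells around a central interface that swaps from the
#' horizontal pair (cells 3|4) to the vertical pair (cells 1|2) according to
#' a scripted pattern, with correct track links through the swap and ground
#' truth attached as attribute `"t1_truth"`.
#'
#' Patterns (`swap_time` defaults to 8 min, movies run 0--`duration`):
#' * `"clean"`: one swap that persists;
#' * `"flicker"`: swap, revert after 1 min, swap again 1 min later and
#'   persist -- one productive event under a 5-min debounce;
#' * `"revert"`: swap, then permanent reversion 1 min later -- no productive
#'   event.
#'
#' @param pattern One of `"clean"`, `"flicker"`, `"revert"`.
#' @param swap_time Time of the first scripted swap (minutes).
#' @param duration Movie length (minutes).
#' @param frame_interval Frame spacing (minutes).
#' @return A [tracked_tissue()] with attribute `t1_truth`, a tibble of the
#'   productive events by construction.
#' @export
make_scripted_t1_movie <- function(pattern = c("clean", "flicker", "revert"),
                                   swap_time = 8, duration = 20,
                                   frame_interval = 0.5) {
  pattern <- match.arg(pattern)
  times <- seq(0, duration, by = frame_interval)
  state <- function(t) {
    switch(pattern,
      clean = if (t >= swap_time) "swap" else "orig",
      flicker = if (t >= swap_time + 2) "swap"
                else if (t >= swap_time + 1) "orig"
                else if (t >= swap_time) "swap" else "orig",
      revert = if (t >= swap_time && t < swap_time + 1) "swap" else "orig")
  }
  # vertex ids: 1 a(-2,1.2) 2 b(-2,-1.2) 3 c(2,-1.2) 4 d(2,1.2)
  #             5 e(0,2) 6 f(0,-2) 7 u 8 v (central pair)
  base_xy <- rbind(c(-2, 1.2), c(-2, -1.2), c(2, -1.2), c(2, 1.2),
                   c(0, 2), c(0, -2))
  orig_uv <- rbind(c(0, 0.5), c(0, -0.5))
  swap_uv <- rbind(c(-0.5, 0), c(0.5, 0))
  polys_orig <- list(`1` = c(1L, 7L, 4L, 5L), `2` = c(2L, 6L, 3L, 8L),
                     `3` = c(1L, 2L, 8L, 7L), `4` = c(7L, 8L, 3L, 4L))
  polys_swap <- list(`1` = c(1L, 7L, 8L, 4L, 5L), `2` = c(2L, 6L, 3L, 8L, 7L),
                     `3` = c(1L, 2L, 7L), `4` = c(8L, 3L, 4L))
  if_orig <- tibble::tibble(
    interface_id = c(1L, 2L, 3L, 4L, 100L, 5L, 6L, 7L, 8L, 9L, 10L),
    v1 = c(1L, 7L, 2L, 8L, 7L, 4L, 5L, 2L, 6L, 1L, 3L),
    v2 = c(7L, 4L, 8L, 3L, 8L, 5L, 1L, 6L, 3L, 2L, 4L),
    cell_a = c(1L, 1L, 2L, 2L, 3L, 1L, 1L, 2L, 2L, 3L, 4L),
    cell_b = c(3L, 4L, 3L, 4L, 4L, NA, NA, NA, NA, NA, NA))
  if_swap <- tibble::tibble(
    interface_id = c(1L, 2L, 3L, 4L, 101L, 5L, 6L, 7L, 8L, 9L, 10L),
    v1 = c(1L, 8L, 2L, 8L, 7L, 4L, 5L, 2L, 6L, 1L, 3L),
    v2 = c(7L, 4L, 7L, 3L, 8L, 5L, 1L, 6L, 3L, 2L, 4L),
    cell_a = c(1L, 1L, 2L, 2L, 1L, 1L, 1L, 2L, 2L, 3L, 4L),
    cell_b = c(3L, 4L, 3L, 4L, 2L, NA, NA, NA, NA, NA, NA))
  cells <- list(); verts <- list(); ifs <- list(); links <- list()
  prev_state <- NULL
  for (fi in seq_along(times)) {
    st <- state(times[fi])
    uv <- if (st == "swap") swap_uv else orig_uv
    xy <- rbind(base_xy, uv)
    polys <- if (st == "swap") polys_swap else polys_orig
    itab <- if (st == "swap") if_swap else if_orig
    verts[[fi]] <- tibble::tibble(frame = fi, vertex_id = 1:8,
                                  x = xy[, 1], y = xy[, 2])
    cent <- t(vapply(polys, function(vv) .poly_centroid(xy[vv, 1], xy[vv, 2]),
                     numeric(2)))
    cells[[fi]] <- tibble::tibble(
      frame = fi, cell_id = 1:4,
      centroid_x = cent[, 1], centroid_y = cent[, 2],
      parasegment = NA_character_, stripe = NA_character_, flag = "germband",
      vertices = unname(polys))
    i1 <- itab$v1; i2 <- itab$v2
    ifs[[fi]] <- tibble::tibble(
      frame = fi, interface_id = itab$interface_id, v1 = i1, v2 = i2,
      cell_a = itab$cell_a, cell_b = itab$cell_b,
      length = sqrt((xy[i2, 1] - xy[i1, 1])^2 + (xy[i2, 2] - xy[i1, 2])^2),
      intensity = NA_real_)
    if (fi > 1L) {
      prev_if <- if (prev_state == "swap") if_swap else if_orig
      links[[fi]] <- dplyr::bind_rows(
        tibble::tibble(kind = "cell", frame = fi - 1L, id = 1:4,
                       frame_next = fi, id_next = 1:4),
        tibble::tibble(kind = "interface", frame = fi - 1L,
                       id = prev_if$interface_id, frame_next = fi,
                       id_next = itab$interface_id))
    }
    prev_state <- st
  }
  truth <- switch(pattern,
    clean = tibble::tibble(time = swap_time, losing = list(c(3L, 4L)),
                           gaining = list(c(1L, 2L))),
    flicker = tibble::tibble(time = swap_time + 2, losing = list(c(3L, 4L)),
                             gaining = list(c(1L, 2L))),
    revert = tibble::tibble(time = numeric(0), losing = list(),
                            gaining = list()))
  tt <- tracked_tissue(dplyr::bind_rows(cells), dplyr::bind_rows(verts),
                       dplyr::bind_rows(ifs), dplyr::bind_rows(links),
                       times = tibble::tibble(frame = seq_along(times),
                                              time = times),
                       frame_interval = frame_interval)
  attr(tt, "t1_truth") <- truth
  tt
}

#' Specification for painting Myosin on a synthetic movie
#'
#' Emulates the identity-boundary enrichment model: interfaces between cells
#' of different stripe identity carry boundary intensity, interfaces between
#' identities two apart in the 4-identity cycle carry super-boundary
#' intensity, and all other interfaces (same identity, tissue border, or
#' missing identity) carry the non-boundary level. The default 1:2:8
#' intensity ratios mirror the tension ratios used in the vertex model. An
#' optional radially symmetric multiplicative "doming" field emulates the
#' imaging artefact of dimmer image corners.
#'
#' @param nonboundary_intensity,boundary_intensity,superboundary_intensity
#'   Intensities (a.u., >= 0).
#' @param doming_amplitude Relative amplitude of the doming bump (0 = off).
#' @param doming_centre 2-vector or `NULL` (tissue bounding-box centre).
#' @param doming_sd Doming kernel sd in micrometres or `NULL` (1/4 of the
#'   tissue width).
#' @param noise_sd Additive white noise sd (a.u.).
#' @param multiplicative_noise If `TRUE`, noise is applied as
#'   `intensity * (1 + eps)` instead of `intensity + eps`.
#' @param seed Integer seed.
#' @return An object of class `movie_paint_spec`.
#' @export
movie_paint_spec <- function(nonboundary_intensity = 1,
                             boundary_intensity = 2,
                             superboundary_intensity = 8,
                             doming_amplitude = 0, doming_centre = NULL,
                             doming_sd = NULL, noise_sd = 0,
                             multiplicative_noise = FALSE, seed = 1L) {
  stopifnot(nonboundary_intensity >= 0, boundary_intensity >= 0,
            superboundary_intensity >= 0, noise_sd >= 0,
            doming_amplitude >= -1)
  structure(list(nonboundary_intensity = nonboundary_intensity,
                 boundary_intensity = boundary_intensity,
                 superboundary_intensity = superboundary_intensity,
                 doming_amplitude = doming_amplitude,
                 doming_centre = doming_centre, doming_sd = doming_sd,
                 noise_sd = noise_sd,
                 multiplicative_noise = multiplicative_noise,
                 seed = as.integer(seed)),
            class = "movie_paint_spec")
}

#' Paint identity-dependent Myosin intensities onto a tissue
#'
#' @param tissue A [tracked_tissue()] whose cells carry stripe identities.
#' @param spec A [movie_paint_spec()].
#' @return The tissue with interface `intensity` filled in.
#' @export
paint_movie <- function(tissue, spec = movie_paint_spec()) {
  stopifnot(inherits(tissue, "tracked_tissue"),
            inherits(spec, "movie_paint_spec"))
  set.seed(spec$seed)
  cid <- paste(tissue$cells$frame, tissue$cells$cell_id)
  ident <- setNames(suppressWarnings(
    as.integer(sub("^S", "", tissue$cells$stripe))), cid)
  ia <- ident[paste(tissue$interfaces$frame, tissue$interfaces$cell_a)]
  ib <- ident[paste(tissue$interfaces$frame, tissue$interfaces$cell_b)]
  d <- abs(ia - ib)
  d <- pmin(d, 4L - d)
  base <- rep(spec$nonboundary_intensity, nrow(tissue$interfaces))
  base[!is.na(d) & d == 1L] <- spec$boundary_intensity
  base[!is.na(d) & d == 2L] <- spec$superboundary_intensity
  if (spec$doming_amplitude != 0) {
    vs <- tissue$vertices
    keyv <- paste(vs$frame, vs$vertex_id)
    mx <- (vs$x[match(paste(tissue$interfaces$frame, tissue$interfaces$v1),
                      keyv)] +
           vs$x[match(paste(tissue$interfaces$frame, tissue$interfaces$v2),
                      keyv)]) / 2
    my <- (vs$y[match(paste(tissue$interfaces$frame, tissue$interfaces$v1),
                      keyv)] +
           vs$y[match(paste(tissue$interfaces$frame, tissue$interfaces$v2),
                      keyv)]) / 2
    ctr <- spec$doming_centre
    if (is.null(ctr)) ctr <- c(mean(range(vs$x)), mean(range(vs$y)))
    dsd <- spec$doming_sd
    if (is.null(dsd)) dsd <- diff(range(vs$x)) / 4
    base <- base * (1 + spec$doming_amplitude *
                      exp(-((mx - ctr[1])^2 + (my - ctr[2])^2) / (2 * dsd^2)))
  }
  if (spec$noise_sd > 0) {
    eps <- rnorm(length(base), 0, spec$noise_sd)
    base <- if (spec$multiplicative_noise) base * (1 + eps) else base + eps
  }
  tissue$interfaces$intensity <- pmax(base, 0)
  tissue
}
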