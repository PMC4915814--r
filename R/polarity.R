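#' Subtract the modal background intensity
#'
#' Histograms the intensities with fixed-width bins, takes the left edge of
#' the most populated bin as the background level, subtracts it, and clips
#' negatives to zero. With the default unit bin width on integer-valued data
#' this subtracts the exact modal value.
#'
#' @param intensities Numeric vector (pixel or interface intensities, a.u.).
#' @param binwidth Histogram bin width (a.u.).
#' @return Corrected intensities (same length, >= 0).
#' @export
subtract_background <- function(intensities, binwidth = 1) {
  stopifnot(binwidth > 0)
  x <- intensities[is.finite(intensities)]
  if (!length(x)) stop("no finite intensities", call. = FALSE)
  bins <- floor(x / binwidth)
  tab <- table(bins)
  mode_left <- as.numeric(names(tab)[which.max(tab)]) * binwidth
  pmax(intensities - mode_left, 0)
}

#' Extract castellated perimeter signals from a tissue frame
#'
#' For each cell, unwraps the perimeter from 0 to 360 degrees anticlockwise:
#' each interface becomes one arc whose width is proportional to its share
#' of the cell perimeter, and the layout is rotated so that arc centres best
#' align, in the circular least-squares sense, with the interfaces' true
#' midpoint directions from the centroid (on a regular hexagon each side
#' then sits exactly at its geometric angle, with the East/posterior side
#' centred on 0). Each arc carries the interface's mean fluorescence, giving
#' the castellated signal the polarity measures operate on. Perimeter
#' (arc-length) unwrapping stays well-defined for irregular, even
#' non-star-shaped cells.
#'
#' @param tissue A [tracked_tissue()] with painted interface intensities.
#' @param frame Frame number.
#' @param cell_id Optional cell ids (default: all germband cells).
#' @return Tibble with columns `cell_id`, `interface_id`, `arc_start`,
#'   `arc_end` (degrees; `arc_end > arc_start`, wrap-around arcs extend past
#'   360), `intensity`, `mid_x`, `mid_y`, `centroid_x`, `centroid_y`.
#' @export
perimeter_signals <- function(tissue, frame, cell_id = NULL) {
  cs <- tissue$cells[tissue$cells$frame == frame, ]
  if (is.null(cell_id)) cell_id <- cs$cell_id[cs$flag == "germband"]
  vs <- tissue$vertices[tissue$vertices$frame == frame, ]
  is <- tissue$interfaces[tissue$interfaces$frame == frame, ]
  ikey <- paste(pmin(is$v1, is$v2), pmax(is$v1, is$v2))
  out <- vector("list", length(cell_id))
  for (q in seq_along(cell_id)) {
    cid <- cell_id[q]
    row <- cs[cs$cell_id == cid, ]
    if (nrow(row) != 1L) stop("no such cell: ", cid, call. = FALSE)
    vv <- row$vertices[[1]]
    idx <- match(vv, vs$vertex_id)
    px <- vs$x[idx]; py <- vs$y[idx]
    ctr <- .poly_centroid(px, py)
    n <- length(vv)
    j <- c(2:n, 1L)
    lens <- sqrt((px[j] - px)^2 + (py[j] - py)^2)
    if (any(lens <= 0)) {
      stop("frame ", frame, ", cell ", cid, ": zero-length side",
           call. = FALSE)
    }
    mx <- (px + px[j]) / 2
    my <- (py + py[j]) / 2
    # anchor: lay the sides out CCW starting near East, then rotate the
    # whole layout so arc centres best align (circular least squares) with
    # the sides' true midpoint directions from the centroid
    mang <- .angle_deg(mx - ctr[1], my - ctr[2])
    east <- which.min(pmin(mang, 360 - mang))
    widths <- lens / sum(lens) * 360
    ord <- c(east:n, seq_len(east - 1L))  # CCW starting at the East side
    w_ord <- widths[ord]
    starts <- cumsum(c(0, w_ord[-n])) - w_ord[1] / 2
    centres <- starts + w_ord / 2
    delta <- (mang[ord] - centres) * pi / 180
    offset <- atan2(mean(sin(delta)), mean(cos(delta))) * 180 / pi
    starts <- starts + offset
    key <- paste(pmin(vv, vv[j]), pmax(vv, vv[j]))
    im <- match(key[ord], ikey)
    if (anyNA(im)) {
      stop("frame ", frame, ", cell ", cid, ": edge without interface record",
           call. = FALSE)
    }
    out[[q]] <- tibble::tibble(
      cell_id = cid,
      interface_id = is$interface_id[im],
      arc_start = starts %% 360,
      arc_end = starts %% 360 + w_ord,
      intensity = is$intensity[im],
      mid_x = mx[ord], mid_y = my[ord],
      centroid_x = ctr[1], centroid_y = ctr[2])
  }
  dplyr::bind_rows(out)
}

# normalise a signal (tibble with arc_start/arc_end/intensity) to a matrix of
# [start, end) in degrees with end > start; arcs must cover 360 in total
.check_arcs <- function(signal) {
  stopifnot(all(c("arc_start", "arc_end", "intensity") %in% names(signal)))
  w <- signal$arc_end - signal$arc_start
  if (any(w <= 0)) stop("arcs must have positive width", call. = FALSE)
  if (abs(sum(w) - 360) > 1e-6) {
    stop("arcs must partition [0, 360)", call. = FALSE)
  }
  signal
}

# length-weighted mean intensity around the perimeter (angular weighting)
.signal_mean <- function(signal) {
  w <- signal$arc_end - signal$arc_start
  sum(w * signal$intensity) / 360
}

#' Fourier polarity of a castellated perimeter signal
#'
#' Computes the period-1 (unidirectional) and period-2 (bidirectional)
#' components of the perimeter intensity signal by exact integration of the
#' piecewise-constant signal against `cos(k * theta)` and `sin(k * theta)`
#' (no discrete sampling). The period-1 phase is the direction of
#' unidirectional enrichment in `[0, 360)`; the period-2 phase is the axis of
#' bidirectional enrichment in `[0, 180)`.
#'
#' @param signal A perimeter-signal tibble (columns `arc_start`, `arc_end`,
#'   `intensity`; degrees and a.u.).
#' @return A one-row tibble with `period1_amplitude`, `period1_phase`,
#'   `period2_amplitude`, `period2_phase`, `mean_intensity`.
#' @export
fourier_polarity <- function(signal) {
  signal <- .check_arcs(signal)
  s <- signal$arc_start * pi / 180
  e <- signal$arc_end * pi / 180
  comp <- function(k) {
    a <- sum(signal$intensity * (sin(k * e) - sin(k * s)) / k) / pi
    b <- sum(signal$intensity * (cos(k * s) - cos(k * e)) / k) / pi
    c(a, b)
  }
  c1 <- comp(1); c2 <- comp(2)
  tibble::tibble(
    period1_amplitude = sqrt(sum(c1^2)),
    period1_phase = .angle_deg(c1[1], c1[2]),
    period2_amplitude = sqrt(sum(c2^2)),
    period2_phase = (.angle_deg(c2[1], c2[2]) / 2) %% 180,
    mean_intensity = .signal_mean(signal))
}

# objective pieces for the constrained double-Gaussian fit
.gauss_model_arc_means <- function(par, s, e) {
  # par = (baseline, post_amp, ant_amp, sd)
  par[1] +
    par[2] * .gauss_arc_mean(s, e, 0, par[4]) +
    par[3] * .gauss_arc_mean(s, e, 180, par[4])
}

#' Double-Gaussian polarity of a castellated perimeter signal
#'
#' Fits a baseline plus two Gaussians with means fixed at 0 (posterior) and
#' 180 (anterior) degrees, free amplitudes and one shared standard deviation,
#' to the arc means by least squares. The model is integrated over each arc
#' so the fit respects the castellated signal, and the squared error is
#' weighted by arc length. Bipolarity is twice the amplitude area of the
#' smaller Gaussian; the signed remainder is unipolarity (positive =
#' posterior enrichment). Both are normalised by the cell's mean perimeter
#' intensity ("pp" units): `area = amplitude * sd * sqrt(2*pi) / 360`.
#'
#' The optimiser restarts from three deterministic initialisations and keeps
#' the lowest objective; a fit that converges nowhere is returned with
#' `converged = FALSE` and should be excluded from averages.
#'
#' @param signal A perimeter-signal tibble (>= 4 arcs, positive mean).
#' @param sd_bounds Lower/upper bounds on the shared sd (degrees).
#' @return A one-row tibble with `anterior_amplitude`, `posterior_amplitude`,
#'   `shared_sd`, `baseline`, `bipolarity_pp`, `unipolarity_pp`,
#'   `mean_intensity`, `converged`.
#' @export
gaussian_polarity <- function(signal, sd_bounds = c(5, 120)) {
  signal <- .check_arcs(signal)
  if (nrow(signal) < 4L) stop("need at least 4 arcs", call. = FALSE)
  mbar <- .signal_mean(signal)
  if (!(mbar > 0)) stop("signal mean must be positive", call. = FALSE)
  s <- signal$arc_start; e <- signal$arc_end
  w <- (e - s) / 360
  y <- signal$intensity
  obj <- function(par) {
    m <- .gauss_model_arc_means(par, s, e)
    sum(w * (y - m)^2)
  }
  lower <- c(0, 0, 0, sd_bounds[1])
  upper <- c(Inf, Inf, Inf, sd_bounds[2])
  rng <- max(y) - min(y)
  near <- function(mu) {
    d <- pmin(abs((s + e) / 2 - mu) %% 360, 360 - abs((s + e) / 2 - mu) %% 360)
    mean(y[d <= 60]) - min(y)
  }
  starts <- list(
    c(min(y), max(near(0), 0.1 * rng, 1e-3),
      max(near(180), 0.1 * rng, 1e-3), 40),
    c(min(y), max(rng, 1e-3), max(rng, 1e-3), 20),
    c(mean(y) * 0.8, max(rng / 2, 1e-3), max(rng / 2, 1e-3), 70))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(p0, lower + 1e-9), c(Inf, Inf, Inf, upper[4])), obj,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(err) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(tibble::tibble(anterior_amplitude = NA_real_,
                          posterior_amplitude = NA_real_,
                          shared_sd = NA_real_, baseline = NA_real_,
                          bipolarity_pp = NA_real_, unipolarity_pp = NA_real_,
                          mean_intensity = mbar, converged = FALSE))
  }
  p <- best$par
  area <- function(amp) amp * p[4] * sqrt(2 * pi) / 360
  amin <- min(p[2], p[3])
  tibble::tibble(
    anterior_amplitude = p[3], posterior_amplitude = p[2],
    shared_sd = p[4], baseline = p[1],
    bipolarity_pp = 2 * area(amin) / mbar,
    unipolarity_pp = sign(p[2] - p[3]) * area(abs(p[2] - p[3])) / mbar,
    mean_intensity = mbar,
    converged = best$convergence == 0)
}

#' Polarity of every cell of a tissue frame
#'
#' Convenience wrapper: extracts perimeter signals and applies
#' [gaussian_polarity()] or [fourier_polarity()] per cell.
#'
#' @param tissue A painted [tracked_tissue()].
#' @param frame Frame numbers (default all).
#' @param method `"gaussian"` or `"fourier"`.
#' @param doming_correction Apply [correct_doming()] per frame first.
#' @return Tibble with one row per cell per frame, including `time`,
#'   centroid coordinates, and the method's outputs.
#' @export
cell_polarity <- function(tissue, frame = tissue$times$frame,
                          method = c("gaussian", "fourier"),
                          doming_correction = FALSE) {
  method <- match.arg(method)
  fun <- if (method == "gaussian") gaussian_polarity else fourier_polarity
  out <- vector("list", length(frame))
  for (q in seq_along(frame)) {
    f <- frame[q]
    sig <- perimeter_signals(tissue, f)
    if (doming_correction) sig <- correct_doming(sig)
    res <- sig |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::group_modify(function(d, g) {
        r <- if (method == "gaussian" &&
                 (nrow(d) < 4L || !(.signal_mean(d) > 0))) {
          # degenerate cell (triangle, or empty signal): flagged, no fit
          tibble::tibble(anterior_amplitude = NA_real_,
                         posterior_amplitude = NA_real_,
                         shared_sd = NA_real_, baseline = NA_real_,
                         bipolarity_pp = NA_real_, unipolarity_pp = NA_real_,
                         mean_intensity = .signal_mean(d), converged = FALSE)
        } else {
          fun(d)
        }
        r |> dplyr::mutate(centroid_x = d$centroid_x[1],
                           centroid_y = d$centroid_y[1])
      }) |>
      dplyr::ungroup()
    res$frame <- f
    res$time <- tissue$times$time[match(f, tissue$times$frame)]
    out[[q]] <- res
  }
  dplyr::bind_rows(out)
}

#' Correct a doming intensity gradient across the field of view
#'
#' Imaging introduces a smooth dome in intensity (corners dimmer than the
#' centre) that masquerades as unidirectional polarity. This fits a smooth
#' surface to the interface intensities (local-linear kernel regression with
#' a Gaussian kernel whose sd is `kernel_fraction` of the field width),
#' divides each cell's perimeter signal by the local trend of that smooth
#' across the cell, and rescales so the cell's mean perimeter intensity is
#' unchanged.
#'
#' @param signals A perimeter-signal table from [perimeter_signals()] (one
#'   frame; requires `mid_x`, `mid_y`, `centroid_x`, `centroid_y`).
#' @param kernel_fraction Kernel sd as a fraction of the field width.
#' @return `signals` with corrected `intensity`.
#' @export
correct_doming <- function(signals, kernel_fraction = 1 / 20) {
  need <- c("mid_x", "mid_y", "centroid_x", "centroid_y", "intensity",
            "cell_id")
  stopifnot(all(need %in% names(signals)))
  pts <- unique(signals[, c("mid_x", "mid_y")])
  if (nrow(pts) < 2L) stop("degenerate intensity field", call. = FALSE)
  width <- diff(range(signals$mid_x))
  if (width <= 0) width <- diff(range(signals$mid_y))
  h <- kernel_fraction * width
  X <- cbind(1, signals$mid_x, signals$mid_y)
  yv <- signals$intensity
  smooth_at <- function(x0, y0) {
    wk <- exp(-((signals$mid_x - x0)^2 + (signals$mid_y - y0)^2) / (2 * h^2))
    wk <- wk + 1e-12
    xc <- cbind(1, signals$mid_x - x0, signals$mid_y - y0)
    fit <- tryCatch(stats::lm.wfit(xc, yv, wk)$coefficients[1],
                    error = function(err) NA_real_)
    if (!is.finite(fit)) stats::weighted.mean(yv, wk) else fit
  }
  out <- signals
  for (cid in unique(signals$cell_id)) {
    sel <- signals$cell_id == cid
    sm_mid <- mapply(smooth_at, signals$mid_x[sel], signals$mid_y[sel])
    sm_c <- smooth_at(signals$centroid_x[sel][1], signals$centroid_y[sel][1])
    if (any(sm_mid <= 0) || sm_c <= 0) next  # cannot rebalance, leave as is
    corr <- signals$intensity[sel] * sm_c / sm_mid
    w <- (signals$arc_end[sel] - signals$arc_start[sel])
    m0 <- sum(w * signals$intensity[sel]) / sum(w)
    m1 <- sum(w * corr) / sum(w)
    if (m1 > 0) corr <- corr * m0 / m1
    out$intensity[sel] <- corr
  }
  out
}

#' Spatiotemporal polarity maps
#'
#' Bins per-cell polarity values into a time-by-AP grid (the DV dimension is
#' averaged out), with per-grid-square mean, count and a two-sided one-sample
#' t-test against zero at the requested confidence level. Squares with fewer
#' than two observations have undefined variance and are masked as
#' non-significant.
#'
#' @param polarity Tibble with columns `time`, an AP coordinate column, and
#'   the value column.
#' @param value Name of the value column (string), e.g. `"unipolarity_pp"`.
#' @param ap Name of the AP coordinate column (default `"centroid_x"`).
#' @param n_time_bins,n_ap_bins Grid size (defaults 80 x 60).
#' @param conf_level Confidence level for the significance mask (0.95 for
#'   unipolarity, 0.999 for bipolarity).
#' @return Tibble with `time_bin`, `ap_bin`, bin centres, `mean`, `n`, `p`
#'   and `significant`.
#' @export
polarity_maps <- function(polarity, value, ap = "centroid_x",
                          n_time_bins = 80, n_ap_bins = 60,
                          conf_level = 0.95) {
  stopifnot(value %in% names(polarity), ap %in% names(polarity),
            "time" %in% names(polarity))
  tb <- .bin_index(polarity$time, n_time_bins)
  ab <- .bin_index(polarity[[ap]], n_ap_bins)
  df <- tibble::tibble(time_bin = tb$index, ap_bin = ab$index,
                       v = polarity[[value]])
  out <- df |>
    dplyr::filter(is.finite(.data$v)) |>
    dplyr::group_by(.data$time_bin, .data$ap_bin) |>
    dplyr::summarise(mean = mean(.data$v), n = dplyr::n(),
                     sd = sd(.data$v), .groups = "drop") |>
    dplyr::mutate(
      se = .data$sd / sqrt(.data$n),
      p = ifelse(.data$n >= 2L & .data$se > 0,
                 2 * pt(abs(.data$mean) / .data$se, df = .data$n - 1L,
                        lower.tail = FALSE),
                 NA_real_),
      significant = !is.na(.data$p) & .data$p < (1 - conf_level),
      time_mid = tb$centres[.data$time_bin],
      ap_mid = ab$centres[.data$ap_bin])
  out
}

.bin_index <- function(x, n) {
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  br <- seq(r[1], r[2], length.out = n + 1)
  idx <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), n)
  list(index = idx, centres = (br[-1] + br[-length(br)]) / 2)
}
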