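# ---- label propagation ------------------------------------------------------

#' Backtrack labels through cell tracks
#'
#' Propagates labels assigned at a reference frame (typically the last, where
#' parasegment boundaries are identifiable from strong Myosin cables) to all
#' other frames through the cell track links, forwards and backwards.
#' Conflicting labels within one track raise an error naming the cell.
#'
#' @param tissue A [tracked_tissue()] with cell links.
#' @param labels Tibble with columns `cell_id` and `label`.
#' @param ref_frame Frame at which `labels` apply.
#' @return Tibble with `frame`, `cell_id`, `label` (NA where untracked).
#' @export
backtrack_labels <- function(tissue, labels, ref_frame) {
  stopifnot(all(c("cell_id", "label") %in% names(labels)))
  tr <- cell_tracks(tissue)
  ref <- tr[tr$frame == ref_frame, ]
  m <- match(labels$cell_id, ref$id)
  if (anyNA(m)) {
    stop("label refers to absent cell ", labels$cell_id[which(is.na(m))[1]],
         " at frame ", ref_frame, call. = FALSE)
  }
  lab_by_track <- tibble::tibble(track = ref$track[m], label = labels$label)
  conf <- lab_by_track |>
    dplyr::distinct() |>
    dplyr::count(.data$track) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conf)) {
    bad <- tr[tr$track == conf$track[1], ]
    stop("conflicting labels for cell track containing cell ", bad$id[1],
         " (frames ", paste(range(bad$frame), collapse = "-"), ")",
         call. = FALSE)
  }
  lab_by_track <- dplyr::distinct(lab_by_track)
  out <- tr |>
    dplyr::left_join(lab_by_track, by = "track") |>
    dplyr::select(frame = "frame", cell_id = "id", label = "label")
  out
}

# ---- within-group coordinates ----------------------------------------------

# assign DV row bins within a frame; row_height defaults to the median cell
# DV extent
.dv_rows <- function(cs, vs, row_height = NULL) {
  if (is.null(row_height)) {
    ext <- vapply(cs$vertices, function(vv) {
      idx <- match(vv, vs$vertex_id)
      diff(range(vs$y[idx]))
    }, numeric(1))
    row_height <- median(ext)
  }
  floor((cs$centroid_y - min(cs$centroid_y)) / row_height + 1e-9)
}

.within_coordinate <- function(tissue, frame, group_col, row_height = NULL) {
  cs <- tissue$cells[tissue$cells$frame == frame, ]
  vs <- tissue$vertices[tissue$vertices$frame == frame, ]
  cs$dv_row <- .dv_rows(cs, vs, row_height)
  cs$grp <- cs[[group_col]]
  cs |>
    dplyr::filter(!is.na(.data$grp), .data$flag == "germband") |>
    dplyr::group_by(.data$grp, .data$dv_row) |>
    dplyr::arrange(.data$centroid_x, .by_group = TRUE) |>
    dplyr::mutate(coordinate = (dplyr::row_number() - 0.5) / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("cell_id", group = "grp", "dv_row", "coordinate",
                  "centroid_x", "centroid_y")
}

#' Within-parasegment AP coordinate of each cell
#'
#' Within each parasegment and dorsoventral row, ranks cells by AP centroid
#' and maps them to `[0, 1]` (anterior-most 0, posterior-most 1) at their
#' cell-centre positions, `(rank - 0.5) / n`. This dimensionless coordinate
#' pools cells from different parasegments into one stereotypical axis; a
#' single-cell row maps to 0.5.
#'
#' @param tissue A [tracked_tissue()] with parasegment labels on cells.
#' @param frame Frame number.
#' @param row_height DV row height (micrometres); default the median cell DV
#'   extent.
#' @return Tibble with `cell_id`, `group` (parasegment), `dv_row`,
#'   `coordinate`, centroid coordinates.
#' @export
within_parasegment_coordinate <- function(tissue, frame, row_height = NULL) {
  .within_coordinate(tissue, frame, "parasegment", row_height)
}

#' Within-stripe AP coordinate of each cell
#' @inheritParams within_parasegment_coordinate
#' @return Tibble as [within_parasegment_coordinate()], grouped by stripe
#'   within parasegment.
#' @export
within_stripe_coordinate <- function(tissue, frame, row_height = NULL) {
  cs <- tissue$cells[tissue$cells$frame == frame, ]
  tissue$cells$stripe_ps <- paste(tissue$cells$parasegment,
                                  tissue$cells$stripe)
  tissue$cells$stripe_ps[is.na(tissue$cells$stripe) |
                           is.na(tissue$cells$parasegment)] <- NA
  out <- .within_coordinate(tissue, frame, "stripe_ps", row_height)
  out$stripe <- sub("^\\S+ ", "", out$group)
  out
}

# ---- cells per parasegment --------------------------------------------------

#' Cells per parasegment width
#'
#' For each parasegment and dorsoventral row, estimates the parasegment AP
#' width (`psw`) as the span of the extreme cell centroids extended by half a
#' mean cell width on each side, and the mean cell AP width (`cw`) as the
#' mean centroid-to-centroid spacing (the cell's polygon AP extent for
#' single-cell rows). `psw / cw`, averaged over rows, estimates the number of
#' cells spanning the parasegment in AP.
#'
#' @param tissue A [tracked_tissue()] with parasegment labels.
#' @param frame Frame number.
#' @param row_height Optional DV row height.
#' @return A list with `per_parasegment` (tibble: `parasegment`, `psw`, `cw`,
#'   `cells_per_parasegment`) and `average` (scalar; `NA` if no labelled
#'   parasegment).
#' @export
cells_per_parasegment <- function(tissue, frame, row_height = NULL) {
  cs <- tissue$cells[tissue$cells$frame == frame, ]
  vs <- tissue$vertices[tissue$vertices$frame == frame, ]
  cs$dv_row <- .dv_rows(cs, vs, row_height)
  cs <- cs[!is.na(cs$parasegment) & cs$flag == "germband", ]
  if (!nrow(cs)) {
    return(list(per_parasegment = tibble::tibble(
      parasegment = character(0), psw = numeric(0), cw = numeric(0),
      cells_per_parasegment = numeric(0)), average = NA_real_))
  }
  ap_extent <- vapply(cs$vertices, function(vv) {
    idx <- match(vv, vs$vertex_id)
    diff(range(vs$x[idx]))
  }, numeric(1))
  cs$ap_extent <- ap_extent
  rows <- cs |>
    dplyr::group_by(.data$parasegment, .data$dv_row) |>
    dplyr::summarise(
      n = dplyr::n(),
      span = diff(range(.data$centroid_x)),
      cw = ifelse(dplyr::n() > 1L,
                  diff(range(.data$centroid_x)) / (dplyr::n() - 1L),
                  mean(.data$ap_extent)),
      .groups = "drop") |>
    dplyr::mutate(psw = ifelse(.data$n > 1L, .data$span + .data$cw,
                               .data$cw))
  per_ps <- rows |>
    dplyr::group_by(.data$parasegment) |>
    dplyr::summarise(psw = mean(.data$psw), cw = mean(.data$cw),
                     cells_per_parasegment = mean(.data$psw / .data$cw),
                     .groups = "drop")
  list(per_parasegment = per_ps,
       average = mean(per_ps$cells_per_parasegment))
}

# ---- interface classes ------------------------------------------------------

#' Classify interfaces by boundary type
#'
#' Uses cell parasegment and stripe labels to classify every interface of
#' every frame: `PSB` (cells of different parasegments), `S1/2B` and `S2/3B`
#' (stripe boundaries within a parasegment), `S3/4B` (between identities 3
#' and 4), `superboundary` (identities two apart in the 4-cycle, i.e. a
#' skipped identity), `nonboundary` (same stripe), and `other` (tissue
#' border, unlabelled, or adjacent to a non-germband cell, excluded from
#' statistics).
#'
#' @param tissue A [tracked_tissue()] with labelled cells.
#' @return Tibble with `frame`, `interface_id`, `class`.
#' @export
classify_interfaces <- function(tissue) {
  cid <- paste(tissue$cells$frame, tissue$cells$cell_id)
  st <- setNames(tissue$cells$stripe, cid)
  ps <- setNames(tissue$cells$parasegment, cid)
  fl <- setNames(tissue$cells$flag, cid)
  ka <- paste(tissue$interfaces$frame, tissue$interfaces$cell_a)
  kb <- paste(tissue$interfaces$frame, tissue$interfaces$cell_b)
  sa <- suppressWarnings(as.integer(sub("^S", "", st[ka])))
  sb <- suppressWarnings(as.integer(sub("^S", "", st[kb])))
  pa <- ps[ka]; pb <- ps[kb]
  fa <- fl[ka]; fb <- fl[kb]
  cls <- rep("other", nrow(tissue$interfaces))
  okcells <- !is.na(fa) & !is.na(fb) & fa == "germband" & fb == "germband" &
    !is.na(sa) & !is.na(sb) & !is.na(pa) & !is.na(pb)
  d <- abs(sa - sb)
  dcyc <- pmin(d, 4L - d)
  cls[okcells & dcyc == 2L] <- "superboundary"
  cls[okcells & pa != pb & dcyc != 2L] <- "PSB"
  same_ps <- okcells & pa == pb
  cls[same_ps & d == 0L] <- "nonboundary"
  cls[same_ps & pmin(sa, sb) == 1L & d == 1L] <- "S1/2B"
  cls[same_ps & pmin(sa, sb) == 2L & d == 1L] <- "S2/3B"
  cls[same_ps & pmin(sa, sb) == 3L & d == 1L] <- "S3/4B"
  tibble::tibble(frame = tissue$interfaces$frame,
                 interface_id = tissue$interfaces$interface_id,
                 class = cls)
}

#' Flanking interface classes relative to boundaries
#'
#' Adds the `-1` / `+1` flanking classes used in boundary Myosin
#' comparisons: a nonboundary interface whose AP-adjacent boundary column is
#' one cell anterior gets `+1` (it sits one cell posterior to the boundary),
#' and vice versa. Here flanks are identified through the stripe identity of
#' the two cells sharing the interface.
#'
#' @param tissue A [tracked_tissue()] with labelled cells.
#' @param boundary `"PSB"`, `"S1/2B"` or `"S2/3B"`.
#' @return Tibble with `frame`, `interface_id`, `class` in
#'   `{boundary, minus1, plus1, other}`.
#' @export
flanking_classes <- function(tissue, boundary = "PSB") {
  cls <- classify_interfaces(tissue)
  cid <- paste(tissue$cells$frame, tissue$cells$cell_id)
  st <- setNames(suppressWarnings(
    as.integer(sub("^S", "", tissue$cells$stripe))), cid)
  ka <- paste(tissue$interfaces$frame, tissue$interfaces$cell_a)
  kb <- paste(tissue$interfaces$frame, tissue$interfaces$cell_b)
  sa <- st[ka]; sb <- st[kb]
  out <- rep("other", nrow(cls))
  out[cls$class == boundary] <- "boundary"
  # flanking interfaces are nonboundary interfaces within the stripes
  # immediately anterior/posterior to the boundary
  flank <- switch(boundary,
    "PSB" = list(minus1 = 4L, plus1 = 1L),
    "S1/2B" = list(minus1 = 1L, plus1 = 2L),
    "S2/3B" = list(minus1 = 2L, plus1 = 3L))
  nonb <- cls$class == "nonboundary" & !is.na(sa) & !is.na(sb)
  out[nonb & sa == flank$minus1 & sb == flank$minus1] <- "minus1"
  out[nonb & sa == flank$plus1 & sb == flank$plus1] <- "plus1"
  tibble::tibble(frame = cls$frame, interface_id = cls$interface_id,
                 class = out)
}

# ---- boundary Myosin statistics --------------------------------------------

#' Per-minute boundary Myosin comparison with ribbon confidence intervals
#'
#' For each interface class and one-minute time bin, computes the mean
#' intensity over embryos, a ribbon half-width
#' `sqrt(var(embryo means) + mean(within-embryo variances))`, and a per-bin
#' significance test of each class against the reference class using a
#' linear mixed model with embryo as random intercept. P-values are compared
#' to `0.05 / n_bins` (Bonferroni over time bins); with fewer than two
#' embryos the mixed model is not identifiable and `p` is `NA`.
#'
#' @param data Tibble with columns `embryo`, `time` (min), `class`,
#'   `intensity`.
#' @param reference Reference class (default `"boundary"`).
#' @param bin_min Time bin width in minutes.
#' @param alpha Family-wise error rate before Bonferroni (default 0.05).
#' @return A list with `summary` (per class x bin: `mean`, `ribbon`,
#'   `n_embryos`) and `tests` (per non-reference class x bin: `p`,
#'   `significant`, `threshold`).
#' @export
boundary_myosin_comparison <- function(data, reference = "boundary",
                                       bin_min = 1, alpha = 0.05) {
  stopifnot(all(c("embryo", "time", "class", "intensity") %in% names(data)))
  df <- data |>
    dplyr::mutate(bin = floor(.data$time / bin_min) * bin_min) |>
    dplyr::filter(is.finite(.data$intensity))
  per_embryo <- df |>
    dplyr::group_by(.data$class, .data$bin, .data$embryo) |>
    dplyr::summarise(m = mean(.data$intensity),
                     v = ifelse(dplyr::n() > 1L, var(.data$intensity), 0),
                     .groups = "drop")
  summary <- per_embryo |>
    dplyr::group_by(.data$class, .data$bin) |>
    dplyr::summarise(
      mean = mean(.data$m),
      ribbon = sqrt(ifelse(dplyr::n() > 1L, var(.data$m), 0) +
                      mean(.data$v)),
      n_embryos = dplyr::n(), .groups = "drop")
  bins <- sort(unique(df$bin))
  thr <- alpha / length(bins)
  others <- setdiff(unique(df$class), reference)
  tests <- list()
  for (cl in others) {
    for (b in bins) {
      sub <- df[df$bin == b & df$class %in% c(reference, cl), ]
      p <- NA_real_
      if (length(unique(sub$embryo)) >= 2L &&
          length(unique(sub$class)) == 2L) {
        sub$class <- factor(sub$class, levels = c(reference, cl))
        fit <- tryCatch(
          suppressWarnings(suppressMessages(
            lmerTest::lmer(intensity ~ class + (1 | embryo), data = sub))),
          error = function(err) NULL)
        if (!is.null(fit)) {
          co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
          if (!is.null(co) && nrow(co) >= 2L && ncol(co) >= 5L) {
            p <- co[2, 5]
          }
        }
      }
      tests[[length(tests) + 1L]] <- tibble::tibble(
        class = cl, bin = b, p = p,
        significant = !is.na(p) & p < thr, threshold = thr)
    }
  }
  list(summary = summary,
       tests = if (length(tests)) dplyr::bind_rows(tests) else
         tibble::tibble(class = character(0), bin = numeric(0),
                        p = numeric(0), significant = logical(0),
                        threshold = numeric(0)))
}

# ---- co-alignment -----------------------------------------------------------

#' Von Mises concentration parameter
#'
#' Maximum-likelihood estimate of the concentration `kappa` of a von Mises
#' distribution via the standard Best--Fisher approximation of the inverse of
#' `A1`. Axial data (orientations modulo 180 degrees) are doubled first.
#'
#' @param theta Angles in degrees.
#' @param axial If `TRUE` (default), treat angles as axial (period 180).
#' @return Non-negative scalar `kappa` (0 for uniform).
#' @export
vonmises_kappa <- function(theta, axial = TRUE) {
  th <- theta * pi / 180
  if (axial) th <- 2 * th
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
}

#' Interface co-alignment statistics
#'
#' Quantifies how strongly each interface class aligns with the DV axis:
#' the proportion of interfaces oriented in `[60, 90]` degrees (closed
#' interval) relative to AP per class and time (LOWESS smoothed with a
#' 10-point window), cumulative orientation distributions at a chosen time,
#' pairwise two-sample Kolmogorov--Smirnov tests between classes at that
#' time, and the von Mises concentration `kappa` per class and time.
#'
#' @param orientations Tibble with columns `class`, `time`, `orientation`
#'   (degrees; raw angles in `[0, 180)` -- they are reflected into `[0, 90]`
#'   for the band proportion and cumulative distributions, while the von
#'   Mises concentration uses the unreflected axial angles).
#' @param at_time Time (min) at which distributions are compared (default:
#'   the last time present).
#' @param band Orientation band counted as DV-aligned.
#' @param lowess_points LOWESS smoothing window, in points.
#' @return A list with `proportion` (class x time tibble with `prop` and
#'   `smooth`), `kappa` (class x time), `cumulative` (at `at_time`), and
#'   `ks_tests` (pairwise, at `at_time`).
#' @export
coalignment <- function(orientations, at_time = NULL, band = c(60, 90),
                        lowess_points = 10) {
  stopifnot(all(c("class", "time", "orientation") %in% names(orientations)))
  df <- orientations |>
    dplyr::mutate(raw_axial = .data$orientation %% 180,
                  orientation = reflect_orientation(.data$orientation))
  if (is.null(at_time)) at_time <- max(df$time)
  prop <- df |>
    dplyr::group_by(.data$class, .data$time) |>
    dplyr::summarise(prop = mean(.data$orientation >= band[1] &
                                   .data$orientation <= band[2]),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$class) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::mutate(smooth = if (dplyr::n() >= 3) {
      lowess(.data$time, .data$prop,
             f = min(1, lowess_points / dplyr::n()))$y
    } else .data$prop) |>
    dplyr::ungroup()
  kap <- df |>
    dplyr::group_by(.data$class, .data$time) |>
    dplyr::summarise(kappa = vonmises_kappa(.data$raw_axial, axial = TRUE),
                     .groups = "drop")
  att <- df[df$time == at_time, ]
  cum <- att |>
    dplyr::group_by(.data$class) |>
    dplyr::arrange(.data$orientation, .by_group = TRUE) |>
    dplyr::mutate(cum_freq = dplyr::row_number() / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("class", "orientation", "cum_freq")
  classes <- unique(att$class)
  ks <- list()
  if (length(classes) >= 2L) {
    cmb <- utils::combn(classes, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- att$orientation[att$class == cmb[1, k]]
      b <- att$orientation[att$class == cmb[2, k]]
      kt <- suppressWarnings(ks.test(a, b))
      ks[[k]] <- tibble::tibble(class_a = cmb[1, k], class_b = cmb[2, k],
                                statistic = unname(kt$statistic),
                                p.value = kt$p.value)
    }
  }
  list(proportion = prop, kappa = kap, cumulative = cum,
       ks_tests = if (length(ks)) dplyr::bind_rows(ks) else
         tibble::tibble(class_a = character(0), class_b = character(0),
                        statistic = numeric(0), p.value = numeric(0)),
       at_time = at_time)
}

# ---- interface fates --------------------------------------------------------

#' Classify interface fates through axis extension
#'
#' Follows each interface track of stripes S1/S2 through the movie and
#' assigns one exclusive category: `boundary_noT1`, `boundary_T1_staysBoundary`,
#' `boundary_T1_becomesNonboundary`, `superboundary` (a boundary interface
#' between skipped identities, where the intervening stripe has local width
#' zero), `nonboundary_T1`, or `nonboundary`.
#'
#' @param tissue A [tracked_tissue()] with labelled cells and links.
#' @param events T1 events from [detect_t1()].
#' @param stripes Stripes whose interfaces are analysed (default S1 and S2
#'   and their bounding boundaries).
#' @return Tibble with one row per interface track: `track`, `category`,
#'   `t1_time` (NA if none), `first_class`, `last_class`.
#' @export
classify_interface_fates <- function(tissue, events,
                                     stripes = c(1L, 2L)) {
  cls <- classify_interfaces(tissue)
  itr <- interface_tracks(tissue)
  cls <- cls |>
    dplyr::left_join(itr, by = c("frame", "interface_id" = "id"))
  # restrict to tracks that ever involve the requested stripes
  cid <- paste(tissue$cells$frame, tissue$cells$cell_id)
  st <- setNames(suppressWarnings(
    as.integer(sub("^S", "", tissue$cells$stripe))), cid)
  sa <- st[paste(tissue$interfaces$frame, tissue$interfaces$cell_a)]
  sb <- st[paste(tissue$interfaces$frame, tissue$interfaces$cell_b)]
  in_scope <- !is.na(sa) & !is.na(sb) &
    (sa %in% stripes | sb %in% stripes)
  scope_tracks <- unique(cls$track[in_scope])
  cls <- cls[cls$track %in% scope_tracks & !is.na(cls$track), ]
  # T1 times per interface track (track of the shrinking interface)
  ev <- events
  t1_by_track <- NULL
  if (nrow(ev)) {
    ev_frames <- vapply(ev$time, function(t) {
      tissue$times$frame[max(which(tissue$times$time <= t))]
    }, numeric(1))
    pre_frames <- tissue$times$frame[match(ev_frames, tissue$times$frame) - 1L]
    tr_of <- function(f, id) {
      w <- itr$track[itr$frame == f & itr$id == id]
      if (length(w)) w[1] else NA_integer_
    }
    t1_by_track <- tibble::tibble(
      track = mapply(tr_of, pre_frames, ev$shrinking_interface),
      t1_time = ev$time)
    t1_by_track <- t1_by_track[!is.na(t1_by_track$track), ]
  }
  boundary_classes <- c("PSB", "S1/2B", "S2/3B", "S3/4B", "superboundary")
  out <- cls |>
    dplyr::filter(.data$class != "other") |>
    dplyr::group_by(.data$track) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      first_class = dplyr::first(.data$class),
      last_class = dplyr::last(.data$class),
      ever_super = any(.data$class == "superboundary"),
      ever_boundary = any(.data$class %in% boundary_classes),
      .groups = "drop")
  out$t1_time <- NA_real_
  if (!is.null(t1_by_track) && nrow(t1_by_track)) {
    m <- match(out$track, t1_by_track$track)
    out$t1_time <- t1_by_track$t1_time[m]
  }
  had_t1 <- !is.na(out$t1_time)
  cat <- character(nrow(out))
  cat[out$ever_super] <- "superboundary"
  b <- !out$ever_super & out$ever_boundary
  cat[b & !had_t1] <- "boundary_noT1"
  cat[b & had_t1 & out$last_class %in% boundary_classes] <-
    "boundary_T1_staysBoundary"
  cat[b & had_t1 & !(out$last_class %in% boundary_classes)] <-
    "boundary_T1_becomesNonboundary"
  nb <- !out$ever_super & !out$ever_boundary
  cat[nb & had_t1] <- "nonboundary_T1"
  cat[nb & !had_t1] <- "nonboundary"
  out$category <- cat
  out[, c("track", "category", "t1_time", "first_class", "last_class")]
}

#' T1 positions along the within-stripe axis
#'
#' Histograms T1 events by the within-stripe AP coordinate of the shrinking
#' interface's cells just before the swap.
#'
#' @param tissue A [tracked_tissue()] with labels.
#' @param events Events from [detect_t1()].
#' @param n_bins Number of coordinate bins over `[0, 1]`.
#' @return Tibble with `stripe`, `bin_mid`, `count` (all-zero histogram if
#'   there are no events).
#' @export
t1_position_profile <- function(tissue, events, n_bins = 10) {
  br <- seq(0, 1, length.out = n_bins + 1)
  mids <- (br[-1] + br[-length(br)]) / 2
  stripes <- c("S1", "S2", "S3", "S4")
  empty <- tidyr::expand_grid(stripe = stripes, bin_mid = mids) |>
    dplyr::mutate(count = 0L)
  if (!nrow(events)) return(empty)
  rows <- list()
  for (k in seq_len(nrow(events))) {
    fidx <- max(which(tissue$times$time <= events$time[k])) - 1L
    if (fidx < 1L) fidx <- 1L
    f <- tissue$times$frame[fidx]
    wc <- within_stripe_coordinate(tissue, f)
    tr <- cell_tracks(tissue)
    trk <- setNames(tr$track, paste(tr$frame, tr$id))
    lose_tracks <- c(events$losing_a[k], events$losing_b[k])
    cells_f <- tr$id[tr$frame == f & tr$track %in% lose_tracks]
    sel <- wc[wc$cell_id %in% cells_f, ]
    if (!nrow(sel)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      stripe = sel$stripe, coordinate = sel$coordinate)
  }
  if (!length(rows)) return(empty)
  obs <- dplyr::bind_rows(rows) |>
    dplyr::mutate(bin = pmin(pmax(findInterval(.data$coordinate, br,
                                               rightmost.closed = TRUE),
                                  1L), n_bins)) |>
    dplyr::count(.data$stripe, .data$bin, name = "count")
  empty |>
    dplyr::mutate(bin = rep(seq_len(n_bins), times = length(stripes))) |>
    dplyr::left_join(obs, by = c("stripe", "bin")) |>
    dplyr::mutate(count = .data$count.x + dplyr::coalesce(.data$count.y, 0L)) |>
    dplyr::select("stripe", "bin_mid", "count")
}

#' Intercalation rate by within-parasegment position
#'
#' Bins the DV intercalation strain rate of each cell by its
#' within-parasegment coordinate; negative DV rates indicate convergence.
#'
#' @param strain Output of [domain_strain_rates()].
#' @param coords Output of [within_parasegment_coordinate()] for the
#'   matching frame(s), or a tibble with `cell_id` and `coordinate`.
#' @param n_bins Number of coordinate bins.
#' @return Tibble with `bin_mid`, `mean_rate`, `n`.
#' @export
intercalation_by_position <- function(strain, coords, n_bins = 8) {
  df <- dplyr::inner_join(strain, coords[, c("cell_id", "coordinate")],
                          by = "cell_id", relationship = "many-to-many")
  br <- seq(0, 1, length.out = n_bins + 1)
  mids <- (br[-1] + br[-length(br)]) / 2
  df |>
    dplyr::mutate(bin = pmin(pmax(findInterval(.data$coordinate, br,
                                               rightmost.closed = TRUE),
                                  1L), n_bins)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_rate = mean(.data$intercalation_dv, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(bin_mid = mids[.data$bin]) |>
    dplyr::select("bin_mid", "mean_rate", "n")
}
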