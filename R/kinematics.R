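# ---- track identity ---------------------------------------------------------

# union-find over (frame, id) nodes connected by link rows; returns a tibble
# (kind, frame, id, track) with one track id per connected component
.tracks <- function(tissue, kind = c("cell", "interface")) {
  kind <- match.arg(kind)
  if (kind == "cell") {
    nodes <- paste(tissue$cells$frame, tissue$cells$cell_id)
  } else {
    nodes <- paste(tissue$interfaces$frame, tissue$interfaces$interface_id)
  }
  nodes <- unique(nodes)
  parent <- seq_along(nodes)
  idx <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  lk <- tissue$links[tissue$links$kind == kind, ]
  if (nrow(lk)) {
    a <- idx[paste(lk$frame, lk$id)]
    b <- idx[paste(lk$frame_next, lk$id_next)]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  track <- match(roots, unique(roots))
  parts <- strsplit(nodes, " ", fixed = TRUE)
  tibble::tibble(
    frame = as.integer(vapply(parts, `[[`, character(1), 1L)),
    id = as.integer(vapply(parts, `[[`, character(1), 2L)),
    track = track)
}

#' Cell track identities
#'
#' Assigns one track id to each chain of cells connected by forward links.
#' In tissues without explicit links, cells sharing a `cell_id` across frames
#' are *not* assumed to be the same cell; supply links or use the generators,
#' which write them.
#'
#' @param tissue A [tracked_tissue()].
#' @return Tibble with `frame`, `id` (cell id), `track`.
#' @export
cell_tracks <- function(tissue) .tracks(tissue, "cell")

#' Interface track identities
#' @inheritParams cell_tracks
#' @return Tibble with `frame`, `id` (interface id), `track`.
#' @export
interface_tracks <- function(tissue) .tracks(tissue, "interface")

# ---- strain rates -----------------------------------------------------------

# affine fit x1 ~ F x0 + c by least squares on centred coordinates
.fit_affine <- function(X0, X1) {
  X0c <- sweep(X0, 2, colMeans(X0))
  X1c <- sweep(X1, 2, colMeans(X1))
  if (qr(X0c)$rank < 2L) return(NULL)
  t(qr.solve(X0c, X1c))
}

# strain-rate tensor mapping second-moment ellipse M1 to M2 over dt:
# the unique SPD F with M2 = F M1 F, rate = log(F)/dt
.shape_rate <- function(M1, M2, dt) {
  s2 <- .sqrtm2(M2)
  inner <- .sqrtm2(s2 %*% M1 %*% s2)
  Fs <- s2 %*% solve(inner) %*% s2
  .logm2_spd((Fs + t(Fs)) / 2) / dt
}

.project_tensor <- function(S, axes) {
  c(ap = drop(t(axes$ap) %*% S %*% axes$ap),
    dv = drop(t(axes$dv) %*% S %*% axes$dv))
}

#' Domain strain rates: tissue, cell shape and intercalation
#'
#' For each focal cell and frame, defines a spatio-temporal domain (the focal
#' cell plus its first corona of neighbours, over `window_frames` consecutive
#' frames, centred by default) and computes three 2D strain-rate tensors
#' (per hour):
#'
#' * tissue: from the affine deformation best fitting the domain centroid
#'   motion between consecutive frames (symmetric part of `log(F)/dt`),
#'   averaged over the window;
#' * cell shape: from the SPD map carrying each cell's second-moment ellipse
#'   to its next-frame ellipse, averaged over domain cells and window;
#' * intercalation: tissue minus cell shape, exact by construction.
#'
#' @param tissue A [tracked_tissue()] with cell links.
#' @param window_frames Number of consecutive frames per domain (default 5,
#'   i.e. 2 min at 0.5-min frames).
#' @param alignment Window placement relative to the focal frame.
#' @param frames Focal frames to evaluate (default: all with a full window).
#' @return Tibble with one row per (frame, cell) and columns
#'   `tissue_xx/xy/yy`, `shape_xx/xy/yy`, `intercalation_xx/xy/yy`, AP/DV
#'   projections of each tensor, and `singular` flagging degenerate fits.
#' @export
domain_strain_rates <- function(tissue, window_frames = 5,
                                alignment = c("centred", "leading",
                                              "trailing"),
                                frames = NULL) {
  alignment <- match.arg(alignment)
  stopifnot(window_frames >= 2L)
  tr <- cell_tracks(tissue)
  trkey <- setNames(tr$track, paste(tr$frame, tr$id))
  fr <- tissue$times$frame
  tms <- setNames(tissue$times$time, fr)
  if (is.null(frames)) frames <- fr
  half <- switch(alignment,
                 centred = c(-floor((window_frames - 1) / 2),
                             ceiling((window_frames - 1) / 2)),
                 leading = c(0L, window_frames - 1L),
                 trailing = c(-(window_frames - 1L), 0L))
  # per-frame lookup tables
  cell_by_frame <- split(tissue$cells, tissue$cells$frame)
  vert_by_frame <- split(tissue$vertices, tissue$vertices$frame)
  ifc_by_frame <- split(tissue$interfaces, tissue$interfaces$frame)
  moments <- function(f, cid) {
    cs <- cell_by_frame[[as.character(f)]]
    vs <- vert_by_frame[[as.character(f)]]
    vv <- cs$vertices[[match(cid, cs$cell_id)]]
    idx <- match(vv, vs$vertex_id)
    .poly_moments(vs$x[idx], vs$y[idx])
  }
  out <- list()
  for (f in frames) {
    fi <- match(f, fr)
    w0 <- fi + half[1]; w1 <- fi + half[2]
    if (w0 < 1L || w1 > length(fr)) next
    wfr <- fr[w0:w1]
    cs <- cell_by_frame[[as.character(f)]]
    ifc <- ifc_by_frame[[as.character(f)]]
    adj <- ifc[!is.na(ifc$cell_b), c("cell_a", "cell_b")]
    for (ci in seq_len(nrow(cs))) {
      cid <- cs$cell_id[ci]
      if (cs$flag[ci] != "germband") next
      nb <- unique(c(adj$cell_b[adj$cell_a == cid],
                     adj$cell_a[adj$cell_b == cid]))
      dom <- c(cid, nb)
      dom_tracks <- trkey[paste(f, dom)]
      if (length(dom) < 3L || anyNA(dom_tracks)) next
      T_acc <- matrix(0, 2, 2); S_acc <- matrix(0, 2, 2)
      npair <- 0L
      singular <- FALSE
      for (k in seq_len(length(wfr) - 1L)) {
        fA <- wfr[k]; fB <- wfr[k + 1L]
        dt_h <- (tms[as.character(fB)] - tms[as.character(fA)]) / 60
        csA <- cell_by_frame[[as.character(fA)]]
        csB <- cell_by_frame[[as.character(fB)]]
        tA <- trkey[paste(fA, csA$cell_id)]
        tB <- trkey[paste(fB, csB$cell_id)]
        selA <- match(dom_tracks, tA)
        selB <- match(dom_tracks, tB)
        ok <- !is.na(selA) & !is.na(selB)
        if (sum(ok) < 3L) { singular <- TRUE; next }
        X0 <- cbind(csA$centroid_x[selA[ok]], csA$centroid_y[selA[ok]])
        X1 <- cbind(csB$centroid_x[selB[ok]], csB$centroid_y[selB[ok]])
        Fm <- .fit_affine(X0, X1)
        if (is.null(Fm)) { singular <- TRUE; next }
        L <- tryCatch(.logm2(Fm) / dt_h, error = function(err) NULL)
        if (is.null(L)) { singular <- TRUE; next }
        T_acc <- T_acc + (L + t(L)) / 2
        Sc <- matrix(0, 2, 2); nc <- 0L
        for (m in which(ok)) {
          M1 <- moments(fA, csA$cell_id[selA[m]])
          M2 <- moments(fB, csB$cell_id[selB[m]])
          r <- tryCatch(.shape_rate(M1, M2, dt_h), error = function(err) NULL)
          if (is.null(r)) next
          Sc <- Sc + r; nc <- nc + 1L
        }
        if (nc == 0L) { singular <- TRUE; next }
        S_acc <- S_acc + Sc / nc
        npair <- npair + 1L
      }
      if (npair == 0L) next
      Tt <- T_acc / npair; St <- S_acc / npair; It <- Tt - St
      pT <- .project_tensor(Tt, tissue$axes)
      pS <- .project_tensor(St, tissue$axes)
      pI <- .project_tensor(It, tissue$axes)
      out[[length(out) + 1L]] <- tibble::tibble(
        frame = f, time = tms[as.character(f)], cell_id = cid,
        tissue_xx = Tt[1, 1], tissue_xy = Tt[1, 2], tissue_yy = Tt[2, 2],
        shape_xx = St[1, 1], shape_xy = St[1, 2], shape_yy = St[2, 2],
        intercalation_xx = It[1, 1], intercalation_xy = It[1, 2],
        intercalation_yy = It[2, 2],
        tissue_ap = pT["ap"], tissue_dv = pT["dv"],
        shape_ap = pS["ap"], shape_dv = pS["dv"],
        intercalation_ap = pI["ap"], intercalation_dv = pI["dv"],
        singular = singular)
    }
  }
  dplyr::bind_rows(out)
}

# ---- movie synchronisation --------------------------------------------------

#' Synchronise a movie to the onset of axis extension
#'
#' Computes the proportional AP extension rate of the tissue between
#' consecutive frames (from the AP extent of germband cell centroids) and
#' sets time zero at the last frame before that rate first exceeds
#' `threshold` (default 0.01 per minute).
#'
#' @param tissue A [tracked_tissue()].
#' @param threshold Proportional extension rate per minute.
#' @return A list of class `gbe_sync` with `offset` (the onset time on the
#'   movie's clock, or `NA` if the rate never exceeds the threshold) and
#'   `rates`, a tibble of per-frame AP extents and rates.
#' @export
synchronize <- function(tissue, threshold = 0.01) {
  gb <- tissue$cells[tissue$cells$flag == "germband", ]
  ext <- gb |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(ap_extent = diff(range(.data$centroid_x)),
                     .groups = "drop") |>
    dplyr::left_join(tissue$times, by = "frame") |>
    dplyr::arrange(.data$time)
  n <- nrow(ext)
  rate <- c(NA_real_,
            (ext$ap_extent[-1] / ext$ap_extent[-n] - 1) /
              diff(ext$time))
  ext$rate <- rate
  first <- which(!is.na(rate) & rate > threshold)[1]
  offset <- if (is.na(first)) NA_real_ else ext$time[first - 1L]
  structure(list(offset = offset, rates = ext, threshold = threshold),
            class = "gbe_sync")
}

#' @exportS3Method base::print
print.gbe_sync <- function(x, ...) {
  if (is.na(x$offset)) {
    cat("<gbe_sync> no onset: AP extension rate never exceeded ",
        x$threshold, "/min\n", sep = "")
  } else {
    cat("<gbe_sync> extension onset at t = ", x$offset, " min\n", sep = "")
  }
  invisible(x)
}

# ---- T1 detection -----------------------------------------------------------

#' Detect productive T1 neighbour exchanges
#'
#' Registers a neighbour-exchange event when an interface swaps ownership
#' from one cell pair to the orthogonal pair of the same four-cell quartet,
#' then debounces: a swap only counts as productive if the new topology
#' persists for at least `debounce_min` minutes (or to the end of the movie);
#' swap/revert flickers within the window are ignored, as are unresolved
#' four-way configurations (no new pair gained).
#'
#' @param tissue A [tracked_tissue()] with cell links.
#' @param debounce_min Debounce window in minutes (default 5).
#' @return Tibble of events: `time`, `losing_a`, `losing_b`, `gaining_a`,
#'   `gaining_b` (cell track ids), `shrinking_interface`,
#'   `growing_interface` (interface ids in the frames flanking the swap).
#' @export
detect_t1 <- function(tissue, debounce_min = 5) {
  tr <- cell_tracks(tissue)
  trkey <- setNames(tr$track, paste(tr$frame, tr$id))
  fr <- tissue$times$frame
  tms <- tissue$times$time
  ifc_by_frame <- split(tissue$interfaces, tissue$interfaces$frame)
  pair_sets <- lapply(fr, function(f) {
    ic <- ifc_by_frame[[as.character(f)]]
    ic <- ic[!is.na(ic$cell_b), ]
    ta <- trkey[paste(f, ic$cell_a)]
    tb <- trkey[paste(f, ic$cell_b)]
    tibble::tibble(a = pmin(ta, tb), b = pmax(ta, tb),
                   interface_id = ic$interface_id)
  })
  keyf <- function(ps) paste(ps$a, ps$b)
  # candidate swaps between consecutive frames
  cand <- list()
  for (k in seq_len(length(fr) - 1L)) {
    p0 <- pair_sets[[k]]; p1 <- pair_sets[[k + 1L]]
    gained <- p1[!(keyf(p1) %in% keyf(p0)), ]
    lost <- p0[!(keyf(p0) %in% keyf(p1)), ]
    if (!nrow(gained) || !nrow(lost)) next
    for (g in seq_len(nrow(gained))) {
      A <- gained$a[g]; B <- gained$b[g]
      # the losing pair: both cells adjacent to both A and B at frame k
      nb_of <- function(t, ps) unique(c(ps$b[ps$a == t], ps$a[ps$b == t]))
      common <- intersect(nb_of(A, p0), nb_of(B, p0))
      for (l in seq_len(nrow(lost))) {
        C <- lost$a[l]; D <- lost$b[l]
        if (all(c(C, D) %in% common) && length(unique(c(A, B, C, D))) == 4L) {
          cand[[length(cand) + 1L]] <- tibble::tibble(
            k = k, time = tms[k + 1L], A = A, B = B, C = C, D = D,
            shrinking_interface = lost$interface_id[l],
            growing_interface = gained$interface_id[g])
        }
      }
    }
  }
  empty <- tibble::tibble(time = numeric(0), losing_a = integer(0),
                          losing_b = integer(0), gaining_a = integer(0),
                          gaining_b = integer(0),
                          shrinking_interface = integer(0),
                          growing_interface = integer(0))
  if (!length(cand)) return(empty)
  cand <- dplyr::bind_rows(cand)
  cand$quartet <- apply(cbind(cand$A, cand$B, cand$C, cand$D), 1,
                        function(v) paste(sort(v), collapse = "_"))
  out <- list()
  for (q in unique(cand$quartet)) {
    cq <- cand[cand$quartet == q, ]
    ids <- sort(unique(c(cq$A[1], cq$B[1], cq$C[1], cq$D[1])))
    # per-frame state of the quartet: which diagonal is adjacent
    diag1 <- c(cq$A[1], cq$B[1])   # first-seen gaining pair
    state <- vapply(seq_along(fr), function(k) {
      ps <- pair_sets[[k]]
      has <- function(p) any(ps$a == min(p) & ps$b == max(p))
      d1 <- has(diag1)
      d2 <- has(setdiff(ids, diag1))
      if (d1 && !d2) 1L else if (d2 && !d1) 2L else 0L
    }, integer(1))
    # debounce: accept a transition only if the new diagonal persists for
    # debounce_min (or to movie end) without returning to the previous
    # accepted diagonal
    accepted <- state[1]
    for (k in which(c(FALSE, diff(state) != 0))) {
      s <- state[k]
      if (s == 0L || s == accepted) next
      horizon <- tms[k] + debounce_min
      later <- which(tms > tms[k] & tms <= horizon)
      reverted <- any(state[later] == accepted)
      if (!reverted) {
        row <- cq[cq$k == k - 1L, ][1, ]
        if (is.na(row$time)) {
          row <- cq[1, ]
          row$time <- tms[k]
          row$shrinking_interface <- NA_integer_
          row$growing_interface <- NA_integer_
        }
        gain <- if (s == 1L) diag1 else setdiff(ids, diag1)
        lose <- setdiff(ids, gain)
        out[[length(out) + 1L]] <- tibble::tibble(
          time = tms[k], losing_a = min(lose), losing_b = max(lose),
          gaining_a = min(gain), gaining_b = max(gain),
          shrinking_interface = row$shrinking_interface,
          growing_interface = row$growing_interface)
        accepted <- s
      }
    }
  }
  if (!length(out)) return(empty)
  dplyr::bind_rows(out) |> dplyr::arrange(.data$time)
}

# ---- Voronoi deviation ------------------------------------------------------

# Voronoi cells of a point set by half-plane clipping; returns per ordered
# pair of Voronoi neighbours the shared edge length, plus per-point perimeter
.voronoi_edges <- function(pts, pad = NULL) {
  n <- nrow(pts)
  if (anyDuplicated(round(pts, 9))) {
    stop("duplicate centroids", call. = FALSE)
  }
  if (is.null(pad)) pad <- 2 * (diff(range(pts[, 1])) + diff(range(pts[, 2])) + 1)
  bb <- rbind(c(min(pts[, 1]) - pad, min(pts[, 2]) - pad),
              c(max(pts[, 1]) + pad, min(pts[, 2]) - pad),
              c(max(pts[, 1]) + pad, max(pts[, 2]) + pad),
              c(min(pts[, 1]) - pad, max(pts[, 2]) + pad))
  edges <- list(); perim <- numeric(n); bounded <- logical(n)
  for (i in seq_len(n)) {
    poly <- bb; labels <- rep(0L, 4)
    ds <- rowSums(sweep(pts, 2, pts[i, ])^2)
    for (j in order(ds)) {
      if (j == i) next
      nrm <- pts[j, ] - pts[i, ]
      d <- sum(nrm * (pts[i, ] + pts[j, ]) / 2)
      cl <- .clip_halfplane(poly, nrm, d, j, labels)
      poly <- cl$poly; labels <- cl$labels
      if (nrow(poly) == 0L) break
    }
    if (nrow(poly) < 3L) next
    m <- nrow(poly)
    nx <- c(2:m, 1L)
    len <- sqrt(rowSums((poly[nx, , drop = FALSE] - poly)^2))
    perim[i] <- sum(len)
    bounded[i] <- all(labels[len > 1e-12] > 0L)
    keep <- labels > 0L & len > 1e-12
    if (any(keep)) {
      edges[[length(edges) + 1L]] <- tibble::tibble(
        i = i, j = labels[keep], length = len[keep])
    }
  }
  list(edges = dplyr::bind_rows(edges), perimeter = perim, bounded = bounded)
}

#' Deviation of interface lengths from a Voronoi tessellation
#'
#' Treats the Voronoi tessellation of the observed cell centroids as a
#' mechanically relaxed reference geometry and returns, per interface,
#' observed minus tessellation-predicted length (micrometres); negative
#' values mean the interface is shorter than its relaxed prediction
#' (geometrically stressed). Also returns per-cell perimeter deviations.
#' Only interfaces whose two cells are both interior (not on the convex hull
#' of centroids) are scored, since hull cells have unbounded Voronoi cells.
#'
#' @param tissue A [tracked_tissue()].
#' @param frame Frame number.
#' @return A list with `interfaces` (tibble: `interface_id`, `cell_a`,
#'   `cell_b`, `observed`, `predicted`, `deviation`) and `cells` (tibble:
#'   `cell_id`, `observed_perimeter`, `predicted_perimeter`, `deviation`).
#' @export
voronoi_deviation <- function(tissue, frame) {
  cs <- tissue$cells[tissue$cells$frame == frame, ]
  ifc <- tissue$interfaces[tissue$interfaces$frame == frame, ]
  vs <- tissue$vertices[tissue$vertices$frame == frame, ]
  pts <- cbind(cs$centroid_x, cs$centroid_y)
  vor <- .voronoi_edges(pts)
  hull <- unique(grDevices::chull(pts))
  interior <- setdiff(which(vor$bounded), hull)
  pred <- vor$edges
  pred$key <- paste(pmin(pred$i, pred$j), pmax(pred$i, pred$j))
  pred <- pred[!duplicated(pred$key), ]
  ia <- match(ifc$cell_a, cs$cell_id)
  ib <- match(ifc$cell_b, cs$cell_id)
  ok <- !is.na(ia) & !is.na(ib) & ia %in% interior & ib %in% interior
  key <- paste(pmin(ia, ib), pmax(ia, ib))
  pidx <- match(key, pred$key)
  res <- tibble::tibble(
    interface_id = ifc$interface_id, cell_a = ifc$cell_a, cell_b = ifc$cell_b,
    observed = ifc$length,
    predicted = ifelse(ok, pred$length[pidx], NA_real_))
  res$deviation <- res$observed - res$predicted
  res <- res[ok & !is.na(res$predicted), ]
  cell_obs <- vapply(seq_len(nrow(cs)), function(k) {
    vv <- cs$vertices[[k]]
    idx <- match(vv, vs$vertex_id)
    .poly_perimeter(vs$x[idx], vs$y[idx])
  }, numeric(1))
  # per-cell comparison additionally requires the cell to be fully interior
  # to the tissue (no border interfaces), else the Voronoi cell extends
  # beyond the observed polygon by construction
  border_cells <- unique(c(ifc$cell_a[is.na(ifc$cell_b)]))
  interior <- interior[!(cs$cell_id[interior] %in% border_cells)]
  cells <- tibble::tibble(
    cell_id = cs$cell_id[interior],
    observed_perimeter = cell_obs[interior],
    predicted_perimeter = vor$perimeter[interior])
  cells$deviation <- cells$observed_perimeter - cells$predicted_perimeter
  list(interfaces = res, cells = cells)
}

# ---- event-time alignment ---------------------------------------------------

#' Align interface time series to T1 events
#'
#' Shifts each event's interface series so the swap is at time zero and
#' averages per relative-minute bin.
#'
#' @param series Tibble with columns `interface_id`, `time`, and one or more
#'   numeric measurement columns.
#' @param events Tibble with columns `shrinking_interface` and `time` (as
#'   returned by [detect_t1()]).
#' @param bin_min Width of the relative-time bins (minutes).
#' @return Tibble with `rel_min`, `n`, and the per-bin mean of every
#'   measurement column.
#' @export
align_to_t1 <- function(series, events, bin_min = 1) {
  stopifnot(all(c("interface_id", "time") %in% names(series)))
  ev <- events[!is.na(events$shrinking_interface), ]
  if (!nrow(ev)) {
    return(tibble::tibble(rel_min = numeric(0), n = integer(0)))
  }
  joined <- dplyr::inner_join(
    series,
    tibble::tibble(interface_id = ev$shrinking_interface,
                   event_time = ev$time),
    by = "interface_id", relationship = "many-to-many")
  joined$rel_min <- round((joined$time - joined$event_time) / bin_min) *
    bin_min
  meas <- setdiff(names(series), c("interface_id", "time"))
  joined |>
    dplyr::group_by(.data$rel_min) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(meas),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

# ---- ablation recoil --------------------------------------------------------

#' Recoil-velocity regression after junction ablation
#'
#' Fits an ordinary least-squares line to the vertex-to-vertex distance over
#' the first `n_post` time points after ablation (time > 0) for each
#' ablation, using the slope as the recoil velocity. With a `group` column,
#' also performs an equal-slopes test (interaction term of the pooled
#' `distance ~ time * group` fit).
#'
#' @param distances Tibble with columns `time` (s, ablation at 0),
#'   `distance` (micrometres), optional `ablation_id` and `group`.
#' @param n_post Number of post-ablation points used (default 5).
#' @return An object of class `recoil_fit`; see [tidy.recoil_fit()] and
#'   [glance.recoil_fit()].
#' @export
recoil_regression <- function(distances, n_post = 5) {
  stopifnot(all(c("time", "distance") %in% names(distances)))
  df <- distances
  if (!"ablation_id" %in% names(df)) df$ablation_id <- 1L
  if (!"group" %in% names(df)) df$group <- NA_character_
  post <- df |>
    dplyr::filter(.data$time > 0) |>
    dplyr::group_by(.data$ablation_id) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::slice_head(n = n_post) |>
    dplyr::ungroup()
  fits <- post |>
    dplyr::group_by(.data$ablation_id, .data$group) |>
    dplyr::group_modify(function(d, g) {
      fit <- lm(distance ~ time, data = d)
      ci <- suppressWarnings(confint(fit, "time"))
      tibble::tibble(slope = coef(fit)[["time"]],
                     conf.low = ci[1], conf.high = ci[2],
                     n = nrow(d))
    }) |>
    dplyr::ungroup()
  comparison <- NULL
  if (length(unique(post$group[!is.na(post$group)])) >= 2L) {
    pooled <- lm(distance ~ time * group, data = post)
    an <- stats::anova(pooled)
    comparison <- tibble::tibble(
      term = "time:group",
      statistic = an["time:group", "F value"],
      p.value = an["time:group", "Pr(>F)"])
  }
  structure(list(slopes = fits, comparison = comparison, n_post = n_post),
            class = "recoil_fit")
}

#' @exportS3Method base::print
print.recoil_fit <- function(x, ...) {
  cat("<recoil_fit> ", nrow(x$slopes), " ablation(s), first ", x$n_post,
      " post-ablation points\n", sep = "")
  print(x$slopes)
  if (!is.null(x$comparison)) {
    cat("equal-slopes test p = ", format(x$comparison$p.value), "\n",
        sep = "")
  }
  invisible(x)
}

#' Tidy recoil regression slopes
#' @param x A `recoil_fit`.
#' @param ... Unused.
#' @return Tibble of per-ablation slopes with confidence intervals.
#' @export
tidy.recoil_fit <- function(x, ...) x$slopes

#' One-row summary of a recoil regression
#' @param x A `recoil_fit`.
#' @param ... Unused.
#' @return Tibble with mean slope per group and the equal-slopes test.
#' @export
glance.recoil_fit <- function(x, ...) {
  by_group <- x$slopes |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_slope = mean(.data$slope), n = dplyr::n(),
                     .groups = "drop")
  if (!is.null(x$comparison)) {
    by_group$equal_slopes_p <- x$comparison$p.value
  }
  by_group
}
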