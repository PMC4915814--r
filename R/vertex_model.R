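#' Vertex-model parameters
#'
#' Parameters of the vertex model of axis extension. Defaults are the
#' non-dimensionalised reference values used throughout the simulations:
#' drag 1, time step 0.001, T1 threshold 0.01 with post-swap separation
#' multiplier 1.5, elastic coefficient 1, target area 1, contractility 0.04,
#' and line-tension coefficients in the ratio 1:2:8 for non-boundary,
#' stripe-boundary and skipped ("supercontractile") stripe-boundary
#' interfaces.
#'
#' The four `variant`s differ only in the line-tension energy `f`:
#' 1. linear in interface length for all interfaces (boundary interfaces
#'    simply more contractile);
#' 2. `Lambda_bdy * log(l)` for stripe-boundary interfaces (positive feedback
#'    on individual interfaces);
#' 3. `Lambda_bdy * log(L)` where `L` is the smaller, over the two cells
#'    sharing the interface, of the summed contiguous boundary-interface
#'    length including the focal interface;
#' 4. as 3 plus `Lambda_sup * log(L)` for skipped stripe-boundary interfaces
#'    (identities two apart in the 4-cycle).
#'
#' @param eta Drag coefficient.
#' @param t_end Simulation end time.
#' @param dt Time step.
#' @param d_min T1 swap threshold distance.
#' @param p T1 swap distance multiplier.
#' @param K Area elastic coefficient.
#' @param A0 Cell target area.
#' @param Gamma Perimeter contractility coefficient.
#' @param Lambda_int,Lambda_bdy,Lambda_sup Line-tension coefficients.
#' @param variant Tension law, 1--4.
#' @param log_floor Guard for `log` of near-zero lengths: lengths entering
#'   the log laws (and their force denominators) are floored here. Defaults
#'   to `d_min`, where the T1 machinery takes over; edges can only dwell
#'   below it when their swap is suppressed (border or rosette vertices).
#' @param step_cap Maximum vertex displacement per time step (`Inf`, the
#'   default, disables it). The chain-level log laws rely on large transient
#'   forces while a boundary cable snaps shut, so capping displacements
#'   suppresses convergent extension; with `log_floor = d_min` the forces
#'   stay finite without a cap.
#' @param chain_force How the log-L tension of a boundary interface acts:
#'   `"local"` (default) applies tension `Lambda / L` along the interface
#'   itself, treating the chain length as a frozen coefficient, so tension
#'   is shared equally along a boundary cable and vertices slide freely;
#'   `"gradient"` takes the exact derivative of `Lambda * log(L)`, which
#'   additionally pulls every interface of the chain and makes whole cables
#'   collapse to points at long times.
#' @return An object of class `vm_params` (a list).
#' @export
vm_params <- function(eta = 1, t_end = 500, dt = 0.001, d_min = 0.01,
                      p = 1.5, K = 1, A0 = 1, Gamma = 0.04,
                      Lambda_int = 0.05, Lambda_bdy = 2 * Lambda_int,
                      Lambda_sup = 8 * Lambda_int, variant = 4,
                      log_floor = d_min, step_cap = Inf,
                      chain_force = c("local", "gradient")) {
  chain_force = match.arg(chain_force)
  stopifnot(eta > 0, dt > 0, d_min > 0, p > 1, K > 0, A0 > 0, Gamma >= 0,
            Lambda_int >= 0, Lambda_bdy >= 0, Lambda_sup >= 0,
            variant %in% 1:4)
  structure(list(eta = eta, t_end = t_end, dt = dt, d_min = d_min, p = p,
                 K = K, A0 = A0, Gamma = Gamma, Lambda_int = Lambda_int,
                 Lambda_bdy = Lambda_bdy, Lambda_sup = Lambda_sup,
                 variant = as.integer(variant), log_floor = log_floor,
                 step_cap = step_cap,
                 chain_gradient = identical(chain_force, "gradient")),
            class = "vm_params")
}

#' Build a simulation state from a tissue frame
#'
#' @param tissue A [tracked_tissue()] (e.g. from [make_hex_tissue()]).
#' @param frame Frame number.
#' @return A `vm_state`: list with `V` (vertex matrix), `cells` (list of
#'   1-based vertex index vectors, CCW), `ident` (stripe identity per cell,
#'   0 if unlabelled), `cell_id`, `parasegment`.
#' @export
vm_state <- function(tissue, frame = tissue$times$frame[1]) {
  cs <- tissue$cells[tissue$cells$frame == frame, ]
  vs <- tissue$vertices[tissue$vertices$frame == frame, ]
  vmap <- setNames(seq_len(nrow(vs)), vs$vertex_id)
  cells <- lapply(cs$vertices, function(vv) unname(vmap[as.character(vv)]))
  ident <- suppressWarnings(as.integer(sub("^S", "", cs$stripe)))
  ident[is.na(ident)] <- 0L
  structure(list(V = cbind(vs$x, vs$y), cells = cells, ident = ident,
                 cell_id = cs$cell_id, parasegment = cs$parasegment),
            class = "vm_state")
}

.vm_par_list <- function(params) {
  params[c("eta", "dt", "d_min", "p", "K", "A0", "Gamma", "Lambda_int",
           "Lambda_bdy", "Lambda_sup", "log_floor", "step_cap", "variant",
           "chain_gradient")]
}

#' Free energy of a vertex-model state
#'
#' Sum of area-elastic, perimeter-contractility and line-tension terms, with
#' the tension law selected by `params$variant`.
#'
#' @param state A `vm_state`.
#' @param params A [vm_params()].
#' @return Scalar energy.
#' @export
vm_energy <- function(state, params) {
  vm_energy_cpp(state$V, state$cells, state$ident, .vm_par_list(params))
}

#' Forces on vertex-model vertices
#'
#' Analytic negative gradient of [vm_energy()] with respect to every vertex
#' position.
#'
#' @inheritParams vm_energy
#' @return Matrix (vertices x 2).
#' @export
vm_force <- function(state, params) {
  vm_force_cpp(state$V, state$cells, state$ident, .vm_par_list(params))
}

#' Edge table of a vertex-model state
#'
#' Lists every interface with its adjacent cells, class (0 non-boundary or
#' tissue-boundary, 1 stripe-boundary, 2 skipped stripe-boundary), length,
#' contiguous chain length `L` (the smaller of the two cells' summed
#' contiguous boundary-interface lengths) and line-tension energy under the
#' chosen variant.
#'
#' @inheritParams vm_energy
#' @return Tibble.
#' @export
vm_edges <- function(state, params) {
  tibble::as_tibble(vm_edges_cpp(state$V, state$cells, state$ident,
                                 .vm_par_list(params)))
}

#' Line-tension energy of one interface
#'
#' Evaluates the tension law for a given length (or chain length, for the
#' log-L variants) and interface class.
#'
#' @param l Interface length (variants 1--2) or contiguous chain length `L`
#'   (variants 3--4) for boundary interfaces.
#' @param class `"nonboundary"` (or `"tissue-boundary"`), `"boundary"`, or
#'   `"skipped"`.
#' @param params A [vm_params()].
#' @return Scalar energy `f`.
#' @export
vm_tension_energy <- function(l, class = c("nonboundary", "tissue-boundary",
                                           "boundary", "skipped"),
                              params = vm_params()) {
  class <- match.arg(class)
  lam_b <- if (class == "skipped" && params$variant == 4) {
    params$Lambda_sup
  } else {
    params$Lambda_bdy
  }
  if (class %in% c("nonboundary", "tissue-boundary")) {
    return(params$Lambda_int * l)
  }
  switch(as.character(params$variant),
         "1" = lam_b * l,
         lam_b * log(pmax(l, params$log_floor)))
}

#' Apply pending T1 swaps to a state
#'
#' Replaces every interior edge shorter than `d_min` whose endpoints are
#' three-valent by an orthogonal edge of length `p * d_min` through its
#' midpoint, updating cell adjacency. Swaps that would create a two-sided
#' cell or an ambiguous topology are suppressed and counted.
#'
#' @inheritParams vm_energy
#' @return List with the updated `state`, `n_swaps`, `suppressed`, and a
#'   `log` tibble of performed swaps.
#' @export
vm_t1_swap <- function(state, params) {
  res <- vm_t1_cpp(state$V, state$cells, state$ident, .vm_par_list(params))
  st <- state
  st$V <- res$V
  st$cells <- lapply(res$cells, as.integer)
  lg <- res$log
  lgt <- if (nrow(lg)) {
    tibble::tibble(time = lg[, 1], cell_c = as.integer(lg[, 2]),
                   cell_d = as.integer(lg[, 3]), cell_a = as.integer(lg[, 4]),
                   cell_b = as.integer(lg[, 5]), edge_length = lg[, 6])
  } else {
    tibble::tibble(time = numeric(0), cell_c = integer(0),
                   cell_d = integer(0), cell_a = integer(0),
                   cell_b = integer(0), edge_length = numeric(0))
  }
  list(state = st, n_swaps = res$n_swaps, suppressed = res$suppressed,
       log = lgt)
}

# convert recorded simulation frames into a tracked_tissue; interface ids are
# stable per unordered cell pair so interfaces track across frames (a T1
# retires one id and creates another)
.sim_to_tissue <- function(recV, recC, times, state, time_scale = 1) {
  nfr <- length(times)
  ident <- state$ident
  stripe <- ifelse(ident > 0L, paste0("S", ident), NA_character_)
  ps <- state$parasegment
  pair_registry <- new.env(parent = emptyenv())
  nextid <- 0L
  cells_l <- vector("list", nfr)
  verts_l <- vector("list", nfr)
  ifc_l <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    V <- recV[[k]]
    cl <- recC[[k]]
    nc <- length(cl)
    cent <- t(vapply(cl, function(vv) .poly_centroid(V[vv, 1], V[vv, 2]),
                     numeric(2)))
    cells_l[[k]] <- tibble::tibble(
      frame = k, cell_id = seq_len(nc),
      centroid_x = cent[, 1], centroid_y = cent[, 2],
      parasegment = ps, stripe = stripe, flag = "germband",
      vertices = lapply(cl, as.integer))
    verts_l[[k]] <- tibble::tibble(frame = k, vertex_id = seq_len(nrow(V)),
                                   x = V[, 1], y = V[, 2])
    ed <- list()
    for (c in seq_len(nc)) {
      vv <- cl[[c]]
      n <- length(vv)
      j <- c(2:n, 1L)
      ed[[c]] <- tibble::tibble(a = pmin(vv, vv[j]), b = pmax(vv, vv[j]),
                                cell = c)
    }
    ed <- dplyr::bind_rows(ed) |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(cell_a = min(.data$cell),
                       cell_b = if (dplyr::n() > 1L) max(.data$cell) else
                         NA_integer_,
                       .groups = "drop")
    pk <- paste(ed$cell_a, ed$cell_b)
    ids <- integer(nrow(ed))
    for (r in seq_len(nrow(ed))) {
      id <- pair_registry[[pk[r]]]
      if (is.null(id)) {
        nextid <- nextid + 1L
        id <- nextid
        assign(pk[r], id, envir = pair_registry)
      }
      ids[r] <- id
    }
    ifc_l[[k]] <- tibble::tibble(
      frame = k, interface_id = ids, v1 = ed$a, v2 = ed$b,
      cell_a = ed$cell_a, cell_b = ed$cell_b,
      length = sqrt((V[ed$b, 1] - V[ed$a, 1])^2 +
                      (V[ed$b, 2] - V[ed$a, 2])^2),
      intensity = NA_real_)
  }
  links <- list()
  for (k in seq_len(nfr - 1L)) {
    common <- intersect(ifc_l[[k]]$interface_id, ifc_l[[k + 1L]]$interface_id)
    links[[k]] <- dplyr::bind_rows(
      tibble::tibble(kind = "cell", frame = k, id = cells_l[[k]]$cell_id,
                     frame_next = k + 1L, id_next = cells_l[[k]]$cell_id),
      tibble::tibble(kind = "interface", frame = k, id = common,
                     frame_next = k + 1L, id_next = common))
  }
  tracked_tissue(dplyr::bind_rows(cells_l), dplyr::bind_rows(verts_l),
                 dplyr::bind_rows(ifc_l),
                 links = dplyr::bind_rows(links),
                 times = tibble::tibble(frame = seq_len(nfr),
                                        time = times * time_scale),
                 frame_interval = if (nfr > 1) diff(times[1:2]) * time_scale
                                  else 1,
                 validate = FALSE)
}

#' Run a vertex-model simulation of axis extension
#'
#' Starting from a hexagonal tissue organised into parasegments with stripe
#' identities, first relaxes the tissue to mechanical equilibrium under
#' uniform linear line tension, then integrates the equations of motion with
#' the chosen tension-law variant (explicit Euler; per step: T1 swaps,
#' forces, simultaneous position update). Frames are exported at a
#' configurable stride as a [tracked_tissue()] whose stripe labels carry the
#' cell identities, ready for painting and downstream analysis.
#'
#' @param params A [vm_params()].
#' @param rows,cols Initial lattice size (DV rows x AP columns); ignored if
#'   `initial` is given.
#' @param initial Optional initial tissue (a single-frame
#'   [tracked_tissue()]); default a fresh [make_hex_tissue()] with cell area
#'   `A0`.
#' @param record_dt Simulation-time interval between exported frames
#'   (default `t_end / 50`).
#' @param relax Run the pre-relaxation phase (default TRUE).
#' @param relax_tol Relaxation stops when the maximum vertex speed falls
#'   below this (default 1e-6).
#' @param relax_max_time Cap on relaxation time.
#' @param time_scale Minutes of "movie time" per simulation time unit in the
#'   exported tissue (cosmetic; default 1).
#' @return A list of class `vm_run` with `tissue`, `t1_log`, `energy`
#'   (tibble of time vs total energy), `suppressed` swap count, `params`,
#'   and `final_state`.
#' @export
vm_run <- function(params = vm_params(), rows = 20, cols = 14,
                   initial = NULL, record_dt = params$t_end / 50,
                   relax = TRUE, relax_tol = 1e-6, relax_max_time = 50,
                   time_scale = 1) {
  if (is.null(initial)) {
    initial <- make_hex_tissue(rows = rows, cols = cols,
                               cell_area = params$A0)
  }
  st <- vm_state(initial)
  if (relax) {
    rr <- vm_simulate_cpp(st$V, st$cells, st$ident, .vm_par_list(params),
                          relax_max_time, 0, TRUE, relax_tol, 0)
    st$V <- rr$final_V
    st$cells <- lapply(rr$final_cells, as.integer)
  }
  sim <- vm_simulate_cpp(st$V, st$cells, st$ident, .vm_par_list(params),
                         params$t_end, record_dt, FALSE, relax_tol,
                         record_dt)
  tis <- .sim_to_tissue(sim$V, sim$cells, sim$times, st, time_scale)
  lg <- sim$t1_log
  t1_log <- if (nrow(lg)) {
    tibble::tibble(time = lg[, 1], cell_c = as.integer(lg[, 2]),
                   cell_d = as.integer(lg[, 3]), cell_a = as.integer(lg[, 4]),
                   cell_b = as.integer(lg[, 5]), edge_length = lg[, 6])
  } else {
    tibble::tibble(time = numeric(0), cell_c = integer(0),
                   cell_d = integer(0), cell_a = integer(0),
                   cell_b = integer(0), edge_length = numeric(0))
  }
  structure(list(tissue = tis, t1_log = t1_log,
                 energy = tibble::tibble(time = sim$energy_times,
                                         energy = sim$energy),
                 suppressed = sim$suppressed, params = params,
                 final_state = list(V = sim$final_V,
                                    cells = lapply(sim$final_cells,
                                                   as.integer),
                                    ident = st$ident,
                                    cell_id = st$cell_id,
                                    parasegment = st$parasegment)),
            class = "vm_run")
}

#' @exportS3Method base::print
print.vm_run <- function(x, ...) {
  cat("<vm_run> variant ", x$params$variant, ", ",
      n_frames(x$tissue), " exported frames, ",
      nrow(x$t1_log), " T1 swap(s), ", x$suppressed, " suppressed\n",
      sep = "")
  invisible(x)
}

#' Bounding-box extension of a simulation run
#'
#' AP and DV extents of the tissue bounding box at the first and last
#' exported frame; convergent extension shows as an AP ratio above 1 and a
#' DV ratio below 1.
#'
#' @param run A `vm_run`.
#' @return One-row tibble with initial/final extents and ratios.
#' @export
vm_extension <- function(run) {
  tis <- run$tissue
  f0 <- tis$times$frame[1]
  f1 <- tis$times$frame[nrow(tis$times)]
  ext <- function(f) {
    vs <- tis$vertices[tis$vertices$frame == f, ]
    c(ap = diff(range(vs$x)), dv = diff(range(vs$y)))
  }
  e0 <- ext(f0); e1 <- ext(f1)
  tibble::tibble(ap_initial = e0["ap"], ap_final = e1["ap"],
                 dv_initial = e0["dv"], dv_final = e1["dv"],
                 ap_ratio = e1["ap"] / e0["ap"],
                 dv_ratio = e1["dv"] / e0["dv"])
}

#' Stripe-order violations along the AP axis
#'
#' Counts AP-neighbour cell pairs whose stripe identities decrease from
#' anterior to posterior -- violations of the S1 -> S4 anteroposterior order
#' within a parasegment. A pair of adjacent cells counts as AP-neighbours
#' when the vector between their centroids points more along AP than DV
#' (`|dx| > |dy|`); pairs stacked dorsoventrally, including mid-exchange
#' quartets whose centroids share an AP position, carry no order
#' information. Contacts at the cell-rearrangement scale are transient
#' topology rather than ordered adjacency, so interfaces shorter than
#' `min_length` (default 5 percent of the frame's median interface length)
#' are excluded. Zero means the parasegment pattern is ordered along every
#' DV row of the mesh.
#'
#' @param tissue A [tracked_tissue()] with stripe and parasegment labels.
#' @param frame Frame number (default: last).
#' @param min_length Minimum interface length for a contact to count;
#'   `NULL` for the default.
#' @return Total violation count (integer).
#' @export
stripe_order_violations <- function(tissue,
                                    frame = tissue$times$frame[
                                      nrow(tissue$times)],
                                    min_length = NULL) {
  cs <- tissue$cells[tissue$cells$frame == frame, ]
  ifc <- tissue$interfaces[tissue$interfaces$frame == frame, ]
  ident <- setNames(suppressWarnings(
    as.integer(sub("^S", "", cs$stripe))), cs$cell_id)
  ps <- setNames(cs$parasegment, cs$cell_id)
  cx <- setNames(cs$centroid_x, cs$cell_id)
  cy <- setNames(cs$centroid_y, cs$cell_id)
  ifc <- ifc[!is.na(ifc$cell_b), ]
  if (is.null(min_length)) min_length <- 0.05 * median(ifc$length)
  ifc <- ifc[ifc$length >= min_length, ]
  ia <- as.character(ifc$cell_a); ib <- as.character(ifc$cell_b)
  dx <- cx[ib] - cx[ia]
  dy <- cy[ib] - cy[ia]
  ok <- !is.na(ident[ia]) & !is.na(ident[ib]) &
    !is.na(ps[ia]) & !is.na(ps[ib]) & ps[ia] == ps[ib] &
    abs(dx) > abs(dy)
  anterior <- ifelse(dx >= 0, ident[ia], ident[ib])
  posterior <- ifelse(dx >= 0, ident[ib], ident[ia])
  sum(ok & posterior < anterior, na.rm = TRUE)
}
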