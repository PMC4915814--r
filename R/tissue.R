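#' Embryonic coordinate axes
#'
#' Defines the anteroposterior (AP) and dorsoventral (DV) unit vectors used to
#' interpret tissue coordinates. AP points towards the embryonic posterior;
#' the pair must be orthonormal. All angles in the package are measured in
#' degrees anticlockwise from the AP (East/posterior) direction.
#'
#' @param origin 2-vector, coordinate origin in micrometres.
#' @param ap 2-vector, AP unit direction (positive towards posterior).
#' @param dv 2-vector, DV unit direction.
#' @return An object of class `embryo_axes`.
#' @export
embryo_axes <- function(origin = c(0, 0), ap = c(1, 0), dv = c(0, 1)) {
  origin <- as.numeric(origin); ap <- as.numeric(ap); dv <- as.numeric(dv)
  stopifnot(length(origin) == 2, length(ap) == 2, length(dv) == 2)
  if (abs(sum(ap^2) - 1) > 1e-8 || abs(sum(dv^2) - 1) > 1e-8 ||
      abs(sum(ap * dv)) > 1e-8) {
    stop("AP and DV must be orthonormal unit vectors", call. = FALSE)
  }
  structure(list(origin = origin, ap = ap, dv = dv), class = "embryo_axes")
}

#' Construct a tracked tissue
#'
#' The central data container: a time series of polygonal cell meshes with
#' track links. All component tables are tibbles, so the object works
#' directly with dplyr pipelines.
#'
#' @param cells Tibble with columns `frame`, `cell_id`, `centroid_x`,
#'   `centroid_y`, `parasegment` (character or `NA`), `stripe` (one of
#'   `"S1"`--`"S4"` or `NA`), `flag` (`"germband"`, `"mesectoderm"` or
#'   `"excluded"`), and `vertices` (list column of integer vertex ids in
#'   counter-clockwise order).
#' @param vertices Tibble with columns `frame`, `vertex_id`, `x`, `y`
#'   (micrometres, embryonic AP--DV coordinates).
#' @param interfaces Tibble with columns `frame`, `interface_id`, `v1`, `v2`,
#'   `cell_a`, `cell_b` (`NA` for the tissue border side), `length`,
#'   `intensity`. Interior interfaces are stored once with
#'   `cell_a < cell_b`.
#' @param links Tibble with columns `kind` (`"cell"` or `"interface"`),
#'   `frame`, `id`, `frame_next`, `id_next`, joining objects forwards in time
#'   (including through neighbour exchange for interfaces).
#' @param times Tibble with columns `frame`, `time` (minutes relative to the
#'   onset of germband extension).
#' @param frame_interval Frame spacing in minutes (default 0.5).
#' @param axes An [embryo_axes()].
#' @param validate Run [validate_tissue()] on the result.
#' @return An object of class `tracked_tissue`.
#' @export
tracked_tissue <- function(cells, vertices, interfaces, links = NULL,
                           times = NULL, frame_interval = 0.5,
                           axes = embryo_axes(), validate = TRUE) {
  cells <- tibble::as_tibble(cells)
  vertices <- tibble::as_tibble(vertices)
  interfaces <- tibble::as_tibble(interfaces)
  if (is.null(links)) {
    links <- tibble::tibble(kind = character(), frame = integer(),
                            id = integer(), frame_next = integer(),
                            id_next = integer())
  }
  if (is.null(times)) {
    fr <- sort(unique(cells$frame))
    times <- tibble::tibble(frame = fr,
                            time = (seq_along(fr) - 1) * frame_interval)
  }
  x <- structure(
    list(cells = cells, vertices = vertices, interfaces = interfaces,
         links = tibble::as_tibble(links), times = tibble::as_tibble(times),
         frame_interval = frame_interval, axes = axes),
    class = "tracked_tissue")
  if (validate) validate_tissue(x)
  x
}

#' @exportS3Method base::print
print.tracked_tissue <- function(x, ...) {
  nf <- nrow(x$times)
  cat("<tracked_tissue> ", nf, " frame(s), ",
      nrow(x$cells), " cell instance(s), ",
      nrow(x$interfaces), " interface instance(s)\n", sep = "")
  if (nf > 0) {
    cat("  time ", min(x$times$time), " .. ", max(x$times$time),
        " min (interval ", x$frame_interval, " min)\n", sep = "")
  }
  invisible(x)
}

#' Number of frames of a tracked tissue
#' @param x A [tracked_tissue()].
#' @return Integer frame count.
#' @export
n_frames <- function(x) nrow(x$times)

#' Validate tracked-tissue invariants
#'
#' Checks that every interface's vertex pair belongs to both adjacent cells'
#' polygons, polygons are simple and counter-clockwise, stored interface
#' lengths equal the Euclidean distance of their vertex pairs, times are
#' strictly increasing, and link maps are injective per frame pair.
#' Violations are reported with frame and object ids.
#'
#' @param x A [tracked_tissue()].
#' @param tol Relative tolerance on interface lengths.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_tissue <- function(x, tol = 1e-6) {
  stopifnot(inherits(x, "tracked_tissue"))
  if (is.unsorted(x$times$time, strictly = TRUE)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  for (f in x$times$frame) {
    vs <- x$vertices[x$vertices$frame == f, ]
    cs <- x$cells[x$cells$frame == f, ]
    is <- x$interfaces[x$interfaces$frame == f, ]
    vx <- setNames(vs$x, vs$vertex_id)
    vy <- setNames(vs$y, vs$vertex_id)
    if (!all(is.finite(vs$x)) || !all(is.finite(vs$y))) {
      stop("frame ", f, ": non-finite vertex coordinates", call. = FALSE)
    }
    cell_vsets <- setNames(cs$vertices, cs$cell_id)
    for (k in seq_len(nrow(cs))) {
      vv <- cs$vertices[[k]]
      if (length(vv) < 3L) {
        stop("frame ", f, ", cell ", cs$cell_id[k], ": fewer than 3 vertices",
             call. = FALSE)
      }
      if (!all(as.character(vv) %in% names(vx))) {
        stop("frame ", f, ", cell ", cs$cell_id[k],
             ": polygon cites absent vertex", call. = FALSE)
      }
      px <- vx[as.character(vv)]; py <- vy[as.character(vv)]
      if (.poly_signed_area(px, py) <= 0) {
        stop("frame ", f, ", cell ", cs$cell_id[k],
             ": polygon not counter-clockwise", call. = FALSE)
      }
      if (!.poly_is_simple(px, py)) {
        stop("frame ", f, ", cell ", cs$cell_id[k],
             ": polygon self-intersects", call. = FALSE)
      }
    }
    if (nrow(is)) {
      lens <- sqrt((vx[as.character(is$v1)] - vx[as.character(is$v2)])^2 +
                   (vy[as.character(is$v1)] - vy[as.character(is$v2)])^2)
      bad <- which(abs(lens - is$length) > tol * pmax(1, lens))
      if (length(bad)) {
        stop("frame ", f, ", interface ", is$interface_id[bad[1]],
             ": stored length disagrees with vertex positions", call. = FALSE)
      }
      for (k in seq_len(nrow(is))) {
        for (cl in c(is$cell_a[k], is$cell_b[k])) {
          if (is.na(cl)) next
          vv <- cell_vsets[[as.character(cl)]]
          if (is.null(vv)) {
            stop("frame ", f, ", interface ", is$interface_id[k],
                 ": cites absent cell ", cl, call. = FALSE)
          }
          if (!(is$v1[k] %in% vv) || !(is$v2[k] %in% vv)) {
            stop("frame ", f, ", interface ", is$interface_id[k],
                 ": vertex pair not part of cell ", cl, "'s polygon",
                 call. = FALSE)
          }
        }
      }
    }
  }
  if (nrow(x$links)) {
    dup <- x$links |>
      dplyr::count(.data$kind, .data$frame, .data$id) |>
      dplyr::filter(.data$n > 1L)
    dup2 <- x$links |>
      dplyr::count(.data$kind, .data$frame_next, .data$id_next) |>
      dplyr::filter(.data$n > 1L)
    if (nrow(dup) || nrow(dup2)) {
      stop("link maps must be injective per frame pair", call. = FALSE)
    }
  }
  invisible(x)
}

#' Extract one frame of a tracked tissue
#' @param x A [tracked_tissue()].
#' @param frame Frame number.
#' @return A single-frame `tracked_tissue`.
#' @export
tissue_frame <- function(x, frame) {
  stopifnot(inherits(x, "tracked_tissue"), frame %in% x$times$frame)
  tracked_tissue(
    cells = x$cells[x$cells$frame == frame, ],
    vertices = x$vertices[x$vertices$frame == frame, ],
    interfaces = x$interfaces[x$interfaces$frame == frame, ],
    links = x$links[0, ],
    times = x$times[x$times$frame == frame, ],
    frame_interval = x$frame_interval, axes = x$axes, validate = FALSE)
}

#' Cell polygon coordinates
#' @param x A [tracked_tissue()].
#' @param frame Frame number.
#' @param cell_id Cell id within the frame.
#' @return Matrix with columns `x`, `y`, counter-clockwise.
#' @export
cell_polygon <- function(x, frame, cell_id) {
  cs <- x$cells[x$cells$frame == frame & x$cells$cell_id == cell_id, ]
  if (nrow(cs) != 1L) stop("no such cell", call. = FALSE)
  vs <- x$vertices[x$vertices$frame == frame, ]
  idx <- match(cs$vertices[[1]], vs$vertex_id)
  cbind(x = vs$x[idx], y = vs$y[idx])
}

#' Cell areas of one frame
#' @inheritParams tissue_frame
#' @return Tibble with `cell_id`, `area` (square micrometres).
#' @export
cell_areas <- function(x, frame) {
  cs <- x$cells[x$cells$frame == frame, ]
  vs <- x$vertices[x$vertices$frame == frame, ]
  area <- vapply(cs$vertices, function(vv) {
    idx <- match(vv, vs$vertex_id)
    .poly_signed_area(vs$x[idx], vs$y[idx])
  }, numeric(1))
  tibble::tibble(cell_id = cs$cell_id, area = area)
}

#' Interface orientation relative to the AP axis
#'
#' Returns the orientation of interfaces as angles reflected around 90
#' degrees into `[0, 90]`: 0 means parallel to AP, 90 parallel to DV.
#'
#' @param x A [tracked_tissue()].
#' @param frame Frame number.
#' @param interface_id Optional interface ids (default: all in the frame).
#' @return Tibble with `interface_id`, `angle_raw` (degrees in `[0, 180)`)
#'   and `orientation` (reflected, `[0, 90]`).
#' @export
interface_orientation <- function(x, frame, interface_id = NULL) {
  is <- x$interfaces[x$interfaces$frame == frame, ]
  if (!is.null(interface_id)) {
    miss <- setdiff(interface_id, is$interface_id)
    if (length(miss)) stop("no such interface: ", miss[1], call. = FALSE)
    is <- is[is$interface_id %in% interface_id, ]
  }
  vs <- x$vertices[x$vertices$frame == frame, ]
  i1 <- match(is$v1, vs$vertex_id); i2 <- match(is$v2, vs$vertex_id)
  dx <- vs$x[i2] - vs$x[i1]; dy <- vs$y[i2] - vs$y[i1]
  if (any(dx == 0 & dy == 0)) {
    stop("zero-length interface: orientation undefined (interface ",
         is$interface_id[which(dx == 0 & dy == 0)[1]], ")", call. = FALSE)
  }
  ap <- x$axes$ap; dv <- x$axes$dv
  ang <- .angle_deg(dx * ap[1] + dy * ap[2], dx * dv[1] + dy * dv[2]) %% 180
  tibble::tibble(interface_id = is$interface_id,
                 angle_raw = ang,
                 orientation = reflect_orientation(ang))
}

#' Reflect an interface angle into the AP--DV quadrant
#'
#' Maps any angle (degrees) to `[0, 90]` so that `theta` and `180 - theta`
#' coincide; the map is idempotent.
#'
#' @param theta Angles in degrees.
#' @return Angles in `[0, 90]`.
#' @export
reflect_orientation <- function(theta) {
  a <- theta %% 180
  ifelse(a > 90, 180 - a, a)
}

#' Write a tracked tissue to disk
#'
#' Two plain-text formats are supported: a CSV bundle (`cells.csv`,
#' `vertices.csv`, `interfaces.csv`, `links.csv`, `times.csv`, with polygons
#' serialised as `;`-separated vertex ids in `cells.csv`) or a single JSON
#' document with the same fields.
#'
#' @param x A [tracked_tissue()].
#' @param path Directory (csv) or file path (json).
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_tissue <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cells_flat <- x$cells |>
    dplyr::mutate(vertices = vapply(.data$vertices, paste, character(1),
                                    collapse = ";"))
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(cells_flat, file.path(path, "cells.csv"))
    readr::write_csv(x$vertices, file.path(path, "vertices.csv"))
    readr::write_csv(x$interfaces, file.path(path, "interfaces.csv"))
    readr::write_csv(x$links, file.path(path, "links.csv"))
    readr::write_csv(x$times, file.path(path, "times.csv"))
    meta <- list(frame_interval = x$frame_interval,
                 axes = list(origin = x$axes$origin, ap = x$axes$ap,
                             dv = x$axes$dv))
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    doc <- list(cells = cells_flat, vertices = x$vertices,
                interfaces = x$interfaces, links = x$links, times = x$times,
                frame_interval = x$frame_interval,
                axes = list(origin = x$axes$origin, ap = x$axes$ap,
                            dv = x$axes$dv))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read a tracked tissue from disk
#'
#' Reads the formats written by [write_tissue()] and validates all tissue
#' invariants, reporting violations with frame and object ids.
#'
#' @inheritParams write_tissue
#' @param validate Run [validate_tissue()] after reading.
#' @return A [tracked_tissue()].
#' @export
read_tissue <- function(path, format = c("csv", "json"), validate = TRUE) {
  format <- match.arg(format)
  if (format == "csv") {
    req <- c("cells.csv", "vertices.csv", "interfaces.csv", "times.csv")
    miss <- req[!file.exists(file.path(path, req))]
    if (length(miss)) {
      stop("missing bundle file(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    cells <- readr::read_csv(file.path(path, "cells.csv"),
                             show_col_types = FALSE)
    vertices <- readr::read_csv(file.path(path, "vertices.csv"),
                                show_col_types = FALSE)
    interfaces <- readr::read_csv(file.path(path, "interfaces.csv"),
                                  show_col_types = FALSE)
    links <- if (file.exists(file.path(path, "links.csv"))) {
      readr::read_csv(file.path(path, "links.csv"), show_col_types = FALSE,
                      col_types = readr::cols(kind = readr::col_character()))
    } else NULL
    times <- readr::read_csv(file.path(path, "times.csv"),
                             show_col_types = FALSE)
    meta <- jsonlite::read_json(file.path(path, "meta.json"),
                                simplifyVector = TRUE)
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    cells <- tibble::as_tibble(doc$cells)
    vertices <- tibble::as_tibble(doc$vertices)
    interfaces <- tibble::as_tibble(doc$interfaces)
    links <- if (!is.null(doc$links) && length(doc$links)) {
      tibble::as_tibble(doc$links)
    } else NULL
    times <- tibble::as_tibble(doc$times)
    meta <- doc
  }
  need <- c("frame", "cell_id", "centroid_x", "centroid_y", "parasegment",
            "stripe", "flag", "vertices")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("cells table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cells$vertices <- lapply(strsplit(as.character(cells$vertices), ";"),
                           as.integer)
  if (is.logical(cells$parasegment)) cells$parasegment <- as.character(cells$parasegment)
  if (is.logical(cells$stripe)) cells$stripe <- as.character(cells$stripe)
  axes <- embryo_axes(meta$axes$origin, meta$axes$ap, meta$axes$dv)
  tracked_tissue(cells, vertices, interfaces, links, times,
                 frame_interval = meta$frame_interval, axes = axes,
                 validate = validate)
}
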