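# Fixture builders shared across test files. Everything is generated in code;
# no data files are read.

# replicate a single-frame tissue into a linked multi-frame movie, applying
# `transform(vertices, s)` to the vertex table at step s (0-based)
replicate_frames <- function(base, n_frames, transform = function(v, s) v,
                             frame_interval = 0.5) {
  cells <- list(); verts <- list(); ifcs <- list(); links <- list()
  for (s in seq_len(n_frames)) {
    v <- transform(base$vertices, s - 1L)
    v$frame <- s
    cl <- base$cells
    cl$frame <- s
    # recompute centroids from transformed vertices
    cl$centroid_x <- vapply(seq_len(nrow(cl)), function(k) {
      idx <- match(cl$vertices[[k]], v$vertex_id)
      gbex:::.poly_centroid(v$x[idx], v$y[idx])[1]
    }, numeric(1))
    cl$centroid_y <- vapply(seq_len(nrow(cl)), function(k) {
      idx <- match(cl$vertices[[k]], v$vertex_id)
      gbex:::.poly_centroid(v$x[idx], v$y[idx])[2]
    }, numeric(1))
    cells[[s]] <- cl
    verts[[s]] <- v
    ic <- base$interfaces
    ic$frame <- s
    i1 <- match(ic$v1, v$vertex_id); i2 <- match(ic$v2, v$vertex_id)
    ic$length <- sqrt((v$x[i2] - v$x[i1])^2 + (v$y[i2] - v$y[i1])^2)
    ifcs[[s]] <- ic
    if (s > 1L) {
      links[[s]] <- dplyr::bind_rows(
        tibble::tibble(kind = "cell", frame = s - 1L, id = cl$cell_id,
                       frame_next = s, id_next = cl$cell_id),
        tibble::tibble(kind = "interface", frame = s - 1L,
                       id = ic$interface_id, frame_next = s,
                       id_next = ic$interface_id))
    }
  }
  tracked_tissue(dplyr::bind_rows(cells), dplyr::bind_rows(verts),
                 dplyr::bind_rows(ifcs), dplyr::bind_rows(links),
                 times = tibble::tibble(frame = seq_len(n_frames),
                                        time = (seq_len(n_frames) - 1) *
                                          frame_interval),
                 frame_interval = frame_interval)
}

# small hexagonal tissue cached per session
hex44 <- function() make_hex_tissue(4, 4)

# quadrature oracle: mean over [a, b] degrees of the wrapped double-Gaussian
# perimeter model, by numerical integration (independent of the closed form)
gauss_arc_mean_quadrature <- function(a, b, mu, s) {
  f <- function(th) {
    out <- 0
    for (k in -2:2) out <- out + exp(-((th - mu + 360 * k)^2) / (2 * s^2))
    out
  }
  stats::integrate(f, a, b, rel.tol = 1e-10)$value / (b - a)
}
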