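#' Receptor expression configurations on a periodic double parasegment
#'
#' The germband repeats its cell identities with a two-parasegment period.
#' A `receptor_config` describes the expression of one or more receptors over
#' the eight cells of such a double-parasegment unit (cells 1--8, circular:
#' cell 8 abuts cell 1). Parasegment boundaries (PSBs) lie between cells 4|5
#' and 8|1, so cells 1--4 and 5--8 carry within-parasegment identities 1--4.
#'
#' @param ... One or more receptors, each an integer vector of the cells
#'   (subset of 1:8) in which that receptor is expressed. Receptors may be
#'   named; unnamed receptors are labelled `A`, `B`, `C`, ...
#' @param pair_rule If `TRUE` (default), require each receptor to be expressed
#'   in exactly 4 of the 8 cells, the pair-rule constraint used in pattern
#'   searches.
#'
#' @return An object of class `receptor_config`: a logical matrix with one row
#'   per receptor and one column per cell.
#' @examples
#' cfg <- receptor_config(A = c(3, 4, 5, 6), B = c(2, 3, 6, 7))
#' interface_differences(cfg)
#' robustness_score(cfg)
#' @export
receptor_config <- function(..., pair_rule = TRUE) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is.numeric(sets[[1]])) {
    sets <- sets[[1]]
  }
  n <- length(sets)
  m <- matrix(FALSE, nrow = n, ncol = 8L)
  for (i in seq_len(n)) {
    cells <- as.integer(sets[[i]])
    if (length(cells) && (anyNA(cells) || any(cells < 1L | cells > 8L))) {
      stop("receptor ", i, ": cell indices must lie in 1..8", call. = FALSE)
    }
    if (anyDuplicated(cells)) {
      stop("receptor ", i, ": duplicated cell indices", call. = FALSE)
    }
    if (pair_rule && length(cells) != 4L) {
      stop("receptor ", i, ": pair-rule patterns occupy exactly 4 of 8 cells ",
           "(use pair_rule = FALSE to lift this)", call. = FALSE)
    }
    m[i, cells] <- TRUE
  }
  nm <- names(sets)
  if (is.null(nm)) nm <- rep("", n)
  auto <- LETTERS[seq_len(n)]
  nm[!nzchar(nm)] <- auto[!nzchar(nm)]
  rownames(m) <- nm
  colnames(m) <- paste0("cell", 1:8)
  structure(m, class = c("receptor_config", "matrix"))
}

#' @exportS3Method base::print
print.receptor_config <- function(x, ...) {
  cat("<receptor_config> ", nrow(x), " receptor(s) over 8 cells",
      " (PSBs at 4|5 and 8|1)\n", sep = "")
  for (r in seq_len(nrow(x))) {
    cat("  ", rownames(x)[r], ": {",
        paste(which(x[r, ]), collapse = ","), "}\n", sep = "")
  }
  invisible(x)
}

# circular indexing into 1..8
.wrap8 <- function(i) ((i - 1L) %% 8L) + 1L

.hamming8 <- function(cfg, a, b) {
  if (nrow(cfg) == 0L) return(0L)
  sum(xor(cfg[, .wrap8(a), drop = TRUE], cfg[, .wrap8(b), drop = TRUE]))
}

#' Receptor differences across the eight cell-cell interfaces
#'
#' Interface `i` separates cells `i` and `i + 1` (circular, so interface 8
#' separates cells 8 and 1). The receptor difference at an interface is the
#' Hamming distance between the two cells' expression vectors: the number of
#' receptors expressed in one cell but not the other. Under the differential
#' identity model a difference of one receptor or more triggers Myosin II
#' enrichment at the interface.
#'
#' @param config A [receptor_config()].
#' @return A tibble with columns `interface` (1--8), `cell_a`, `cell_b`,
#'   `psb` (is this a parasegment boundary interface), and `differences`.
#' @export
interface_differences <- function(config) {
  stopifnot(inherits(config, "receptor_config"))
  d <- vapply(1:8, function(i) .hamming8(config, i, i + 1L), integer(1))
  tibble::tibble(
    interface = 1:8,
    cell_a = 1:8,
    cell_b = .wrap8(2:9),
    psb = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    differences = d
  )
}

#' Receptor differences at interfaces bridging deleted cells
#'
#' When cell `at` (or the contiguous pair `at`, `at + 1`) is missing from the
#' anteroposterior sequence, its former neighbours meet at a new bridging
#' interface. This returns the receptor (Hamming) difference across that
#' bridging interface, with circular indexing over the 8-cell unit.
#'
#' @param config A [receptor_config()].
#' @param at Position(s) of the deleted cell (first deleted cell for `n = 2`);
#'   defaults to all eight positions.
#' @param n Number of contiguous cells deleted: 1 or 2.
#' @return A tibble with columns `at`, `n_missing`, `cell_left`, `cell_right`
#'   and `differences`.
#' @export
deletion_differences <- function(config, at = 1:8, n = 1) {
  stopifnot(inherits(config, "receptor_config"))
  n <- as.integer(n)
  if (!n %in% 1:2) stop("`n` must be 1 or 2", call. = FALSE)
  at <- as.integer(at)
  left <- .wrap8(at - 1L)
  right <- .wrap8(at + n)
  d <- mapply(function(a, b) .hamming8(config, a, b), left, right)
  tibble::tibble(
    at = at, n_missing = n,
    cell_left = left, cell_right = right,
    differences = as.integer(d)
  )
}

#' Robustness score of a receptor configuration
#'
#' Scores how well receptor-difference heterotypy persists or increases when
#' cells are missing from the anteroposterior sequence, as a grey-box count
#' over a double-parasegment unit. The total is the sum of three lines:
#'
#' * `line1`: the number of intact interfaces (of 8) with at least one
#'   receptor difference;
#' * `line2`: the number of single-cell deletions (of 8) whose bridging
#'   interface carries strictly more receptor differences than either of the
#'   two intact interfaces it replaces;
#' * `line3`: the number of contiguous two-cell deletions (of 8) whose
#'   bridging interface carries strictly more receptor differences than either
#'   of the two overlapping single-deletion bridging interfaces.
#'
#' Each line is at most 8, so the total never exceeds the structural ceiling
#' of 24. With `line1 = "sum"` the first line instead sums the difference
#' magnitudes; the two readings coincide on the canonical two- and
#' three-receptor scenarios, and counting is the default.
#'
#' @param config A [receptor_config()].
#' @param line1 `"count"` (default) or `"sum"`.
#' @return An object of class `robustness_score`: a list with `line1`,
#'   `line2`, `line3`, `total` and per-position detail tibbles.
#' @export
robustness_score <- function(config, line1 = c("count", "sum")) {
  stopifnot(inherits(config, "receptor_config"))
  line1 <- match.arg(line1)
  intact <- interface_differences(config)
  sing <- deletion_differences(config, 1:8, n = 1)
  dbl <- deletion_differences(config, 1:8, n = 2)

  adj <- intact$differences
  # deleting cell k replaces interfaces k-1 (cells k-1|k) and k (cells k|k+1)
  sing$replaced_max <- pmax(adj[.wrap8(sing$at - 1L)], adj[sing$at])
  sing$grey <- sing$differences > sing$replaced_max
  # deleting cells (k, k+1) overlaps single deletions at k and k+1
  dbl$single_max <- pmax(sing$differences[dbl$at],
                         sing$differences[.wrap8(dbl$at + 1L)])
  dbl$grey <- dbl$differences > dbl$single_max

  l1 <- if (line1 == "count") sum(adj >= 1L) else sum(adj)
  l2 <- sum(sing$grey)
  l3 <- sum(dbl$grey)
  structure(
    list(line1 = as.integer(l1), line2 = as.integer(l2), line3 = as.integer(l3),
         total = as.integer(l1 + l2 + l3),
         intact = intact, single = sing, double = dbl,
         line1_mode = line1),
    class = "robustness_score"
  )
}

#' @exportS3Method base::print
print.robustness_score <- function(x, ...) {
  cat("<robustness_score> total ", x$total,
      " = ", x$line1, " (intact) + ", x$line2, " (1 missing) + ",
      x$line3, " (2 missing)\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.robustness_score <- function(x, ...) {
  tibble::tibble(
    line = c("intact", "one_missing", "two_missing"),
    grey_boxes = c(x$line1, x$line2, x$line3)
  )
}

#' @export
glance.robustness_score <- function(x, ...) {
  tibble::tibble(total = x$total, line1 = x$line1, line2 = x$line2,
                 line3 = x$line3, ceiling = 24L)
}

# All C(8,4) = 70 four-of-eight patterns as a 70 x 8 logical matrix.
.pair_rule_patterns <- function() {
  combs <- utils::combn(8L, 4L)
  m <- matrix(FALSE, ncol(combs), 8L)
  for (j in seq_len(ncol(combs))) m[j, combs[, j]] <- TRUE
  m
}

# Per-pattern contributions to the 24 cell-pair Hamming distances needed for
# scoring: adjacent pairs (i, i+1), single-deletion bridges (k-1, k+1) and
# double-deletion bridges (k-1, k+2). Row r gives, for pattern r, the XOR of
# its expression at each pair of cells. Hamming distances of a multi-receptor
# config are sums of these rows.
.pattern_pair_xor <- function(pat = .pair_rule_patterns()) {
  pairs <- rbind(
    cbind(1:8, .wrap8(2:9)),          # adjacent interfaces 1..8
    cbind(.wrap8(0:7), .wrap8(2:9)),  # single-deletion bridges k = 1..8
    cbind(.wrap8(0:7), .wrap8(3:10))  # double-deletion bridges k = 1..8
  )
  x <- matrix(0L, nrow(pat), 24L)
  for (p in seq_len(24L)) {
    x[, p] <- as.integer(xor(pat[, pairs[p, 1]], pat[, pairs[p, 2]]))
  }
  x
}

# Vectorised scoring from a configs x 24 matrix of pair distances.
.score_from_pairs <- function(d, line1 = "count") {
  adj <- d[, 1:8, drop = FALSE]
  sng <- d[, 9:16, drop = FALSE]
  dbl <- d[, 17:24, drop = FALSE]
  prev <- .wrap8(0:7)
  nxt <- .wrap8(2:9)
  l1 <- if (line1 == "count") rowSums(adj >= 1L) else rowSums(adj)
  l2 <- rowSums(sng > pmax(adj[, prev, drop = FALSE], adj, na.rm = FALSE))
  l3 <- rowSums(dbl > pmax(sng, sng[, nxt, drop = FALSE]))
  as.integer(l1 + l2 + l3)
}

#' Search the space of pair-rule receptor placements
#'
#' Scores placements of `n_receptors` receptors, each expressed in exactly 4
#' of the 8 cells of the periodic double-parasegment unit (70 possible
#' patterns per receptor), with [robustness_score()]. Exhaustive mode covers
#' all `choose(8,4)^n` placements, deduplicated by receptor-label permutation
#' symmetry (multisets of patterns) and re-weighted so the returned histogram
#' counts ordered placements. Random mode draws placements uniformly.
#'
#' @param n_receptors Number of receptors (0 or more; exhaustive search is
#'   practical up to 4).
#' @param mode `"exhaustive"` or `"random"`.
#' @param n_draws Number of random draws (random mode).
#' @param seed Integer seed for random mode.
#' @param line1 Passed to the scoring rule; see [robustness_score()].
#' @return A list with `best_score`, `best_configs` (list of
#'   [receptor_config()] objects attaining the maximum, up to label
#'   permutation; random mode returns the distinct best draws), and
#'   `histogram` (tibble of score vs count).
#' @export
search_patterns <- function(n_receptors,
                            mode = c("exhaustive", "random"),
                            n_draws = 1e6, seed = 1L,
                            line1 = c("count", "sum")) {
  mode <- match.arg(mode)
  line1 <- match.arg(line1)
  n_receptors <- as.integer(n_receptors)
  stopifnot(n_receptors >= 0L)
  pat <- .pair_rule_patterns()
  if (n_receptors == 0L) {
    return(list(best_score = 0L,
                best_configs = list(receptor_config()),
                histogram = tibble::tibble(score = 0L, count = 1)))
  }
  xr <- .pattern_pair_xor(pat)

  if (mode == "random") {
    set.seed(as.integer(seed))
    idx <- matrix(sample.int(70L, n_draws * n_receptors, replace = TRUE),
                  ncol = n_receptors)
    sc <- .score_chunked(idx, xr, weight = NULL, line1 = line1)
    best <- max(sc$scores)
    bi <- unique(idx[sc$scores == best, , drop = FALSE])
    cfgs <- .configs_from_index(bi, pat)
    return(list(best_score = as.integer(best), best_configs = cfgs,
                histogram = sc$hist))
  }

  # exhaustive over multisets (i1 <= i2 <= ... <= in) of pattern indices
  idx <- .multisets(70L, n_receptors)
  w <- .multiset_weights(idx)
  sc <- .score_chunked(idx, xr, weight = w, line1 = line1)
  best <- max(sc$scores)
  bi <- idx[sc$scores == best, , drop = FALSE]
  cfgs <- .configs_from_index(bi, pat)
  list(best_score = as.integer(best), best_configs = cfgs, histogram = sc$hist)
}

# all non-decreasing n-tuples from 1..k, as a matrix (rows = tuples)
.multisets <- function(k, n) {
  if (n == 1L) return(matrix(seq_len(k), ncol = 1))
  prev <- .multisets(k, n - 1L)
  reps <- k - prev[, n - 1L] + 1L
  first <- prev[rep(seq_len(nrow(prev)), reps), , drop = FALSE]
  last <- unlist(lapply(prev[, n - 1L], function(s) s:k), use.names = FALSE)
  cbind(first, last)
}

# number of ordered arrangements of each multiset row
.multiset_weights <- function(idx) {
  n <- ncol(idx)
  apply(idx, 1L, function(r) {
    tab <- table(r)
    factorial(n) / prod(factorial(tab))
  })
}

.configs_from_index <- function(idx, pat) {
  lapply(seq_len(nrow(idx)), function(i) {
    sets <- lapply(idx[i, ], function(j) which(pat[j, ]))
    names(sets) <- LETTERS[seq_along(sets)]
    do.call(receptor_config, sets)
  })
}

.score_chunked <- function(idx, xr, weight = NULL, line1 = "count",
                           chunk = 200000L) {
  nr <- nrow(idx)
  scores <- integer(nr)
  starts <- seq(1L, nr, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, nr)
    rows <- s:e
    d <- xr[idx[rows, 1L], , drop = FALSE]
    if (ncol(idx) > 1L) {
      for (j in 2:ncol(idx)) d <- d + xr[idx[rows, j], , drop = FALSE]
    }
    scores[rows] <- .score_from_pairs(d, line1 = line1)
  }
  w <- if (is.null(weight)) rep(1, nr) else weight
  hist <- tibble::tibble(score = scores, w = w) |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(count = sum(.data$w), .groups = "drop") |>
    dplyr::arrange(.data$score)
  list(scores = scores, hist = hist)
}
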