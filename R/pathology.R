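# Cell density and fraction features from classified cell tables
# (x, y in pixels, class in {cancer, stromal, lymphocyte}).

cell_classes <- function() c("cancer", "stromal", "lymphocyte")

# Distance to the Nth nearest neighbour within `pts` for each row of `pts`
# (excluding itself); compiled brute force, slides hold at most a few
# thousand cells.
knn_dist_n <- function(pts, n_neighbour) {
  m <- nrow(pts)
  stopifnot(m > n_neighbour)
  .knn_dist_n_cpp(pts, as.integer(n_neighbour))
}

#' Nearest-neighbour cell density
#'
#' For each cell of the target class, the local density is
#' \eqn{\Sigma_N = N / (\pi d_N^2)} (pixel^-2), where \eqn{d_N} is the
#' distance to its Nth nearest neighbour within the density-defining
#' population (by default, cells of the same class). The slide-level summary
#' is the median of the per-cell densities (the mean is also reported).
#'
#' @param cells data.frame with columns `x`, `y`, `class`.
#' @param target_class Class whose density is computed (default
#'   "lymphocyte").
#' @param n_neighbour N, the neighbour order (default 50).
#' @param population_class Density-defining population (defaults to
#'   `target_class`).
#' @return list: `per_cell` (numeric vector of densities, one per target
#'   cell; NULL when there are fewer than N + 1 population cells), `median`,
#'   `mean` (NA when not computable), `n_cells`.
#' @export
knn_density <- function(cells, target_class = "lymphocyte",
                        n_neighbour = 50, population_class = target_class) {
  stop_if_missing_cols(cells, c("x", "y", "class"), "cell table")
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y))) {
    stop("non-finite cell coordinates")
  }
  pop <- cells[cells$class == population_class, c("x", "y"), drop = FALSE]
  tgt <- cells[cells$class == target_class, c("x", "y"), drop = FALSE]
  n_t <- nrow(tgt)
  if (n_t == 0 || nrow(pop) < n_neighbour + 1) {
    return(list(per_cell = NULL, median = NA_real_, mean = NA_real_,
                n_cells = n_t))
  }
  pts <- as.matrix(pop)
  if (anyDuplicated(pts)) {
    warning("duplicate coordinates; jittering by machine epsilon")
    eps <- max(abs(pts)) * sqrt(.Machine$double.eps)
    dup <- duplicated(pts)
    pts[dup, ] <- pts[dup, ] + stats::runif(2 * sum(dup), -eps, eps)
  }
  if (identical(population_class, target_class)) {
    d_n <- knn_dist_n(pts, n_neighbour)
  } else {
    # Cross-class: neighbours come from the population, not the targets.
    tm <- as.matrix(tgt)
    d_n <- vapply(seq_len(n_t), function(i) {
      d2 <- (pts[, 1] - tm[i, 1])^2 + (pts[, 2] - tm[i, 2])^2
      sqrt(sort.int(d2, partial = n_neighbour)[n_neighbour])
    }, 0.0)
  }
  dens <- n_neighbour / (pi * d_n^2)
  list(per_cell = dens, median = stats::median(dens), mean = mean(dens),
       n_cells = n_t)
}

#' Stability of the density estimate over the neighbour-order grid
#'
#' Recomputes the slide density summary for N in a grid (default 40-60 in
#' steps of 5) and reports the maximum relative deviation from the N = 50
#' (or grid-central) value.
#'
#' @inheritParams knn_density
#' @param n_grid Neighbour orders to evaluate.
#' @param reference_n Grid member used as the reference (default 50).
#' @return list: `summaries` (data.frame n, median, mean),
#'   `max_rel_deviation` of the median vs the reference N.
#' @export
density_stability <- function(cells, target_class = "lymphocyte",
                              n_grid = seq(40, 60, by = 5),
                              reference_n = 50) {
  res <- lapply(n_grid, function(n)
    knn_density(cells, target_class, n_neighbour = n))
  summaries <- data.frame(
    n = n_grid,
    median = vapply(res, function(r) r$median, 0.0),
    mean = vapply(res, function(r) r$mean, 0.0)
  )
  ref <- if (reference_n %in% n_grid) {
    summaries$median[summaries$n == reference_n]
  } else summaries$median[ceiling(length(n_grid) / 2)]
  list(summaries = summaries,
       max_rel_deviation = max(abs(summaries$median - ref)) / abs(ref))
}

#' Per-class cell fractions
#'
#' @param cells data.frame with a `class` column.
#' @param classes Class vocabulary (default cancer, stromal, lymphocyte).
#' @return Named numeric vector of fractions summing to 1.
#' @export
cell_fractions <- function(cells, classes = cell_classes()) {
  stop_if_missing_cols(cells, "class", "cell table")
  if (nrow(cells) == 0) stop("empty cell table")
  tab <- table(factor(cells$class, levels = classes))
  stats::setNames(as.vector(tab) / nrow(cells), classes)
}
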