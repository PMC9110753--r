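#' Rectangular option grid
#'
#' Defines the lattice of options (arms) for a spatially correlated bandit.
#' Options are indexed 0-based in row-major order; each index maps to a
#' 0-based `(row, col)` coordinate used for all distance computations.
#'
#' @param n_rows Number of grid rows (default 11, the task's screen layout).
#' @param n_cols Number of grid columns (default 15).
#'
#' @return An object of class `grid_spec`: a list with `n_rows`, `n_cols`,
#'   `n_options`, and a `coords` matrix (`n_options` x 2, columns `row`,
#'   `col`, 0-based).
#' @export
#' @examples
#' g <- grid_spec()
#' g$n_options # 165
grid_spec <- function(n_rows = 11L, n_cols = 15L) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  idx <- 0:(n_rows * n_cols - 1L)
  coords <- cbind(row = idx %/% n_cols, col = idx %% n_cols)
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         n_options = n_rows * n_cols, coords = coords),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d grid, %d options (0-based row-major indices)\n",
              x$n_rows, x$n_cols, x$n_options))
  invisible(x)
}

#' Map option indices to grid coordinates
#'
#' @param grid A [grid_spec()].
#' @param index Integer vector of 0-based option indices.
#' @return Matrix with columns `row`, `col` (0-based).
#' @export
option_coordinates <- function(grid, index) {
  check_option_index(grid, index)
  grid$coords[index + 1L, , drop = FALSE]
}

#' Map grid coordinates to option indices
#'
#' @param grid A [grid_spec()].
#' @param row,col 0-based coordinates.
#' @return Integer vector of 0-based option indices.
#' @export
option_index <- function(grid, row, col) {
  stopifnot(length(row) == length(col))
  if (any(row < 0 | row >= grid$n_rows | col < 0 | col >= grid$n_cols)) {
    stop("coordinate out of range for ", grid$n_rows, " x ", grid$n_cols, " grid")
  }
  as.integer(row) * grid$n_cols + as.integer(col)
}

check_option_index <- function(grid, index) {
  if (any(is.na(index)) || any(index < 0L | index >= grid$n_options)) {
    stop("option index out of range [0, ", grid$n_options - 1L, "]")
  }
  invisible(TRUE)
}

#' Squared-distance matrix between all options
#'
#' Squared Euclidean distances between grid coordinates, the quantity the
#' RBF kernel decays over. Values are integers (sums of two squares).
#'
#' @param grid A [grid_spec()].
#' @return `n_options` x `n_options` numeric matrix.
#' @export
squared_distances <- function(grid) {
  r <- grid$coords[, "row"]
  cl <- grid$coords[, "col"]
  outer(r, r, function(a, b) (a - b)^2) + outer(cl, cl, function(a, b) (a - b)^2)
}

#' Radial-basis-function kernel between options
#'
#' `k(i, j) = exp(-d2(i, j) / lambda)` where `d2` is the squared Euclidean
#' distance between the grid coordinates of the two options and `lambda`
#' the length-scale governing how quickly spatial correlation decays.
#'
#' @param i,j 0-based option indices (vectors recycle as in base R).
#' @param lambda_ Positive length-scale.
#' @param grid A [grid_spec()].
#' @return Kernel values in `(0, 1]`.
#' @export
#' @examples
#' g <- grid_spec()
#' rbf_kernel(0, 0, 1.5, g)  # 1
#' rbf_kernel(0, 1, 1.5, g)  # exp(-1/1.5)
rbf_kernel <- function(i, j, lambda_, grid) {
  if (!is.numeric(lambda_) || length(lambda_) != 1L || !is.finite(lambda_) ||
      lambda_ <= 0) {
    stop("lambda_ must be a positive finite scalar")
  }
  check_option_index(grid, i)
  check_option_index(grid, j)
  ci <- grid$coords[i + 1L, , drop = FALSE]
  cj <- grid$coords[j + 1L, , drop = FALSE]
  d2 <- unname((ci[, 1] - cj[, 1])^2 + (ci[, 2] - cj[, 2])^2)
  exp(-d2 / lambda_)
}

#' Full RBF kernel matrix over the grid
#'
#' @param grid A [grid_spec()].
#' @param lambda_ Positive length-scale.
#' @return `n_options` x `n_options` kernel matrix (symmetric, unit diagonal).
#' @export
kernel_matrix <- function(grid, lambda_) {
  if (lambda_ <= 0) stop("lambda_ must be a positive finite scalar")
  exp(-squared_distances(grid) / lambda_)
}
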