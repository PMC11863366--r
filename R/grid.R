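#' Discretize a box into a normalization grid
#'
#' Divides an orthorhombic box into `n` subdivisions per edge (`n^3` cells;
#' the cells are cubic for cubic boxes and rectangular otherwise, with
#' edges `L/n`). The per-cell free volume, binned by signed distance to
#' the interface, is what normalizes intrinsic density profiles.
#'
#' @param box length-3 numeric, box edge lengths in Angstrom.
#' @param n subdivisions per box edge, at least 2.
#' @return a `density_grid` with the cell centers
#'   (`(i + 1/2) L/n`, 0-based `i`), cell volume and dimensions.
#' @export
make_grid <- function(box, n) {
  stopifnot(length(box) == 3, all(is.finite(box)), all(box > 0))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop_fmt("n must be an integer >= 2")
  ax <- lapply(box, function(L) (seq_len(n) - 0.5) * L / n)
  centers <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                                   KEEP.OUT.ATTRS = FALSE))
  dimnames(centers) <- NULL
  structure(list(n = n, box = as.numeric(box), centers = centers,
                 cell_volume = prod(box / n)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d^3 cells of %.3g A^3 in a %.4g x %.4g x %.4g A box\n",
              x$n, x$cell_volume, x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Signed distances from grid cell centers to an interface
#'
#' @param grid a `density_grid`.
#' @param mesh an `interface_mesh`.
#' @return a `signed_grid`: the grid plus a vector `r` of per-cell signed
#'   distances (Angstrom, negative inside the interface).
#' @export
grid_distances <- function(grid, mesh) {
  stopifnot(inherits(grid, "density_grid"), inherits(mesh, "interface_mesh"))
  grid$r <- signed_distance(mesh, grid$centers)
  class(grid) <- c("signed_grid", "density_grid")
  grid
}

#' @export
as.data.frame.signed_grid <- function(x, ...) {
  data.frame(x = x$centers[, 1], y = x$centers[, 2], z = x$centers[, 3],
             r = x$r)
}

#' Free volume per signed-distance bin
#'
#' Each bin's free volume is the number of cell centers whose signed
#' distance falls in the bin, times the cell volume. Bins use the
#' half-open convention `[lo, hi)`. When the edges cover the full distance
#' range the bin volumes partition the box volume exactly.
#'
#' @param sgrid a `signed_grid` from [grid_distances()].
#' @param bin_edges strictly increasing numeric vector of bin edges
#'   (Angstrom).
#' @return numeric vector of per-bin volumes (Angstrom^3), length
#'   `length(bin_edges) - 1`.
#' @export
bin_free_volume <- function(sgrid, bin_edges) {
  stopifnot(inherits(sgrid, "signed_grid"))
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0))
    stop_fmt("bin_edges must be strictly increasing with at least 2 values")
  idx <- findInterval(sgrid$r, bin_edges, rightmost.closed = FALSE)
  idx[sgrid$r == bin_edges[length(bin_edges)]] <- length(bin_edges) - 1L
  counts <- tabulate(idx[idx >= 1L & idx <= length(bin_edges) - 1L],
                     nbins = length(bin_edges) - 1L)
  counts * sgrid$cell_volume
}
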