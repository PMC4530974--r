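#' Minimum-weight boundary path through a gradient region
#'
#' Models the region as an 8-connected graph: one vertex per pixel, plus two
#' virtual columns of gradient value 1 appended on either side so that the
#' endpoints need no initialization (vertical moves inside a virtual column
#' cost only `w_min`, so the entry/exit rows are free). The arc weight
#' between neighbouring pixels `a`, `b` is
#' `2 - (g_a + g_b) + w_min`,
#' so bright gradient pixels attract the path. An infinitesimal penalty of
#' `w_min / 1000` per row of vertical travel is added so that ties among
#' equal-gradient paths (uniform regions, e.g. vessel-shadowed spans whose
#' gradient is set to a constant) resolve to the geometrically straightest
#' path instead of an arbitrary equal-weight zigzag. The globally
#' minimum-weight path from the top of the left virtual column to the top of
#' the right one is found with Dijkstra's algorithm; remaining ties in
#' tentative distance are settled towards the smaller row index, making the
#' result deterministic.
#'
#' @param g_roi Numeric matrix in `[0, 1]` (a gradient region of interest) or
#'   a `gradient_image`.
#' @param w_min Small positive stabilization constant keeping all arc weights
#'   positive; default `1e-5`.
#' @return An object of class `path_result`: list with `rows` (one axial row
#'   index per real column — the row at which the path first enters that
#'   column) and `total_weight`.
#' @export
shortest_path_boundary <- function(g_roi, w_min = 1e-5) {
  m <- as_grid(g_roi)
  if (!is.matrix(m) || length(m) == 0L)
    stop("`g_roi` must be a non-empty matrix", call. = FALSE)
  if (!is.finite(w_min) || w_min <= 0)
    stop("`w_min` must be a positive scalar", call. = FALSE)
  res <- cpp_dijkstra_path(m, w_min)
  structure(list(rows = res$rows + 1L, total_weight = res$total_weight),
            class = "path_result")
}

#' Exhaustive-search boundary oracle
#'
#' Independent reference implementation of [shortest_path_boundary()] for
#' small grids: a depth-first enumeration of all simple 8-connected
#' left-to-right paths between the two virtual end columns, with
#' branch-and-bound pruning of provably suboptimal prefixes (the bound prunes
#' a prefix only when its weight plus `w_min` per remaining column advance
#' already meets the incumbent, so the minimum is exact). Uses the same arc
#' weight definition as [shortest_path_boundary()], including the
#' vertical-travel tie-break penalty. Refuses grids larger than 8 x 8.
#'
#' @inheritParams shortest_path_boundary
#' @return A `path_result`, same contract as [shortest_path_boundary()].
#' @export
brute_force_boundary <- function(g_roi, w_min = 1e-5) {
  m <- as_grid(g_roi)
  if (!is.matrix(m) || length(m) == 0L)
    stop("`g_roi` must be a non-empty matrix", call. = FALSE)
  if (nrow(m) > 8L || ncol(m) > 8L)
    stop("brute-force search refused for grids larger than 8x8", call. = FALSE)
  if (!is.finite(w_min) || w_min <= 0)
    stop("`w_min` must be a positive scalar", call. = FALSE)
  res <- cpp_brute_force_path(m, w_min)
  structure(list(rows = res$rows + 1L, total_weight = res$total_weight),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("Boundary path over %d columns, total weight %.6g\n",
              length(x$rows), x$total_weight))
  invisible(x)
}
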