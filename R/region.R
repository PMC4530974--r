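#' Boundary polyline for one frame
#'
#' One axial position per lateral column (fractional pixels allowed).
#'
#' @param z Numeric vector of axial positions.
#' @param frame Frame index the boundary belongs to.
#' @param label Boundary name (one of [boundary_labels()], or free text).
#' @return Object of class `oct_boundary`.
#' @export
oct_boundary <- function(z, frame = NA_integer_, label = "") {
  if (!is.numeric(z) || length(z) == 0L || any(!is.finite(z)))
    stop("`z` must be a non-empty finite numeric vector", call. = FALSE)
  structure(list(z = as.numeric(z), frame = frame, label = label),
            class = "oct_boundary")
}

bz <- function(b) if (inherits(b, "oct_boundary")) b$z else as.numeric(b)

#' @export
print.oct_boundary <- function(x, ...) {
  cat(sprintf("Boundary %s (frame %s): %d columns, z in [%.1f, %.1f]\n",
              if (nzchar(x$label)) x$label else "<unnamed>",
              x$frame, length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' Flatten a B-scan against a reference boundary
#'
#' Shifts every A-scan (column) vertically so that the reference boundary
#' becomes the horizontal line `target_row`. The target is the rounded
#' maximum of the reference, so all shifts are downward-or-zero and the
#' retina is never pushed off the top of the frame; pixels vacated at the top
#' are filled by edge replication. The integer per-column shifts are returned
#' for exact inversion.
#'
#' @param frame Numeric matrix (axial x lateral).
#' @param reference Boundary (or numeric vector) defined on every column.
#' @return List with `frame` (flattened matrix) and `record` (a
#'   `flatten_record` with fields `shifts`, `target_row`).
#' @export
flatten <- function(frame, reference) {
  z <- bz(reference)
  H <- nrow(frame); W <- ncol(frame)
  if (length(z) != W)
    stop("reference must be defined on every column of the frame", call. = FALSE)
  if (any(z < 1 | z > H))
    stop("reference boundary lies outside the frame", call. = FALSE)
  target <- round(max(z))
  shifts <- as.integer(round(target - z))
  out <- frame
  rows <- seq_len(H)
  for (x in which(shifts != 0L)) {
    out[, x] <- frame[pmax(1L, rows - shifts[x]), x]
  }
  list(frame = out,
       record = structure(list(shifts = shifts, target_row = target),
                          class = "flatten_record"))
}

#' Undo flattening on a frame
#'
#' Inverse column shifts of [flatten()]; pixels vacated at the bottom are
#' filled by edge replication. Exact inverse on all rows untouched by fill.
#'
#' @param frame Flattened matrix.
#' @param record A `flatten_record`.
#' @return The unflattened matrix.
#' @export
unflatten_frame <- function(frame, record) {
  H <- nrow(frame); rows <- seq_len(H)
  out <- frame
  for (x in which(record$shifts != 0L)) {
    out[, x] <- frame[pmin(H, rows + record$shifts[x]), x]
  }
  out
}

#' Map a boundary into flattened coordinates
#' @param b Boundary (or numeric vector) in raw frame coordinates.
#' @param record A `flatten_record` from [flatten()].
#' @return Object of the same type with shifted axial positions.
#' @export
flatten_boundary <- function(b, record) {
  z <- bz(b)
  if (length(z) != length(record$shifts))
    stop("boundary/record length mismatch", call. = FALSE)
  zz <- z + record$shifts
  if (inherits(b, "oct_boundary")) { b$z <- zz; b } else zz
}

#' Map a boundary back to raw frame coordinates
#' @inheritParams flatten_boundary
#' @param b Boundary (or numeric vector) in flattened coordinates.
#' @return Object of the same type with the per-column shifts subtracted.
#' @export
unflatten_boundary <- function(b, record) {
  z <- bz(b)
  if (length(z) != length(record$shifts))
    stop("boundary/record length mismatch", call. = FALSE)
  zz <- z - record$shifts
  if (inherits(b, "oct_boundary")) { b$z <- zz; b } else zz
}

#' Axial search region
#'
#' An inclusive axial band `[z_top, z_bottom]` restricting graph
#' construction, optionally with per-column curve bounds (band mode).
#'
#' @param z_top,z_bottom Scalar inclusive row bounds, `1 <= z_top <= z_bottom`.
#' @param per_col_top,per_col_bottom Optional per-column integer bounds lying
#'   inside `[z_top, z_bottom]`.
#' @return Object of class `search_region` with an `M` field (row count).
#' @export
search_region <- function(z_top, z_bottom,
                          per_col_top = NULL, per_col_bottom = NULL) {
  z_top <- as.integer(z_top); z_bottom <- as.integer(z_bottom)
  if (is.na(z_top) || is.na(z_bottom) || z_top < 1L || z_top > z_bottom)
    stop("invalid search region: need 1 <= z_top <= z_bottom", call. = FALSE)
  structure(list(z_top = z_top, z_bottom = z_bottom,
                 M = z_bottom - z_top + 1L,
                 per_col_top = per_col_top, per_col_bottom = per_col_bottom),
            class = "search_region")
}

#' @export
print.search_region <- function(x, ...) {
  cat(sprintf("Search region: rows [%d, %d] (%d rows)%s\n",
              x$z_top, x$z_bottom, x$M,
              if (!is.null(x$per_col_top)) ", per-column bounds" else ""))
  invisible(x)
}

#' Inter-frame search region
#'
#' The axial band around the corresponding boundary of the previous frame:
#' `[min(z) - margin, max(z) + margin]`, clamped to the frame. Rests on the
#' smoothness of retinal surfaces between adjacent B-scans (axial change
#' under 10 px at typical inter-frame spacing).
#'
#' @param prev Boundary from the previous frame (same coordinate system as
#'   the current search).
#' @param margin Band margin in pixels (default 10).
#' @param frame_height Axial frame extent for clamping.
#' @return A [search_region()].
#' @export
interframe_region <- function(prev, margin = 10, frame_height) {
  z <- bz(prev)
  search_region(max(1L, floor(min(z)) - margin),
                min(frame_height, ceiling(max(z)) + margin))
}

#' Intra-frame search region
#'
#' Region defined by boundaries already detected in the same frame:
#' `rect_between_extremes` spans from the lowest point of the upper curve to
#' the highest point of the lower curve (a rectangle); `rect_below` is a
#' fixed-height rectangle starting at a reference row; `band` keeps
#' per-column curve bounds.
#'
#' @param upper Upper boundary or scalar row (for `rect_below`, the reference
#'   row).
#' @param lower Lower boundary or scalar row (unused by `rect_below`).
#' @param mode One of `"band"`, `"rect_below"`, `"rect_between_extremes"`.
#' @param height Row count for `rect_below`.
#' @param frame_height Axial frame extent for clamping.
#' @return A [search_region()].
#' @export
intraframe_region <- function(upper, lower = NULL,
                              mode = c("rect_between_extremes", "rect_below", "band"),
                              height = NULL, frame_height = NULL) {
  mode <- match.arg(mode)
  if (mode == "rect_below") {
    ref <- round(max(bz(upper)))
    if (is.null(height) || height < 1)
      stop("`height` required for rect_below", call. = FALSE)
    bottom <- ref + height - 1L
    if (!is.null(frame_height)) bottom <- min(bottom, frame_height)
    return(search_region(ref, bottom))
  }
  zu <- bz(upper); zl <- bz(lower)
  if (mode == "rect_between_extremes") {
    top <- ceiling(max(zu)); bottom <- floor(min(zl))
    if (top > bottom)
      stop("inverted bounds: upper boundary below lower boundary", call. = FALSE)
    return(search_region(top, bottom))
  }
  # band: per-column curve bounds
  if (length(zu) != length(zl))
    stop("band bounds must share length", call. = FALSE)
  if (any(zu > zl))
    stop("inverted bounds: upper boundary below lower boundary", call. = FALSE)
  search_region(min(ceiling(zu)), max(floor(zl)),
                per_col_top = ceiling(zu), per_col_bottom = floor(zl))
}

#' Extract a search region from a gradient image
#'
#' Returns the rectangular hull of the region; in band mode, pixels outside
#' the per-column bounds are zeroed.
#'
#' @param g Gradient image or matrix.
#' @param region A [search_region()].
#' @return Numeric matrix of `region$M` rows.
#' @export
crop_region <- function(g, region) {
  m <- as_grid(g)
  if (region$z_bottom > nrow(m))
    stop("search region exceeds the frame", call. = FALSE)
  out <- m[region$z_top:region$z_bottom, , drop = FALSE]
  if (!is.null(region$per_col_top)) {
    Z <- row(out) + region$z_top - 1L
    B_top <- matrix(region$per_col_top, nrow(out), ncol(out), byrow = TRUE)
    B_bot <- matrix(region$per_col_bottom, nrow(out), ncol(out), byrow = TRUE)
    out[Z < B_top | Z > B_bot] <- 0
  }
  out
}

#' Lower-bias map multiplication
#'
#' Multiplies row `z` of an `M`-row region by `(z - 1) / (M - 1)` so the top
#' row vanishes and the bottom row is unchanged; used to make the lowest of
#' several same-orientation boundaries in a region the most attractive.
#'
#' @param g_roi Numeric matrix with at least 2 rows.
#' @return The biased matrix.
#' @export
apply_lower_bias <- function(g_roi) {
  m <- as_grid(g_roi)
  M <- nrow(m)
  if (M < 2L) stop("bias map needs at least 2 rows", call. = FALSE)
  m * ((row(m) - 1) / (M - 1))
}

#' Zero a gradient region relative to a detected boundary
#'
#' Sets gradient pixels on the given side of a boundary to zero (in the
#' region's local row coordinates). `pad` widens the zeroed zone towards the
#' boundary by `pad` rows, which removes the boundary's own kernel-response
#' shoulder as well. `outside_pair` zeroes above the upper and below the
#' lower of two boundaries. Idempotent.
#'
#' @param g_roi Numeric matrix (region of interest).
#' @param b Boundary or numeric vector in local row coordinates.
#' @param side `"below"`, `"above"` or `"outside_pair"`.
#' @param b2 Second (lower) boundary for `outside_pair`.
#' @param pad Non-negative integer widening of the zeroed zone.
#' @return The masked matrix.
#' @export
mask_relative <- function(g_roi, b, side = c("below", "above", "outside_pair"),
                          b2 = NULL, pad = 0) {
  side <- match.arg(side)
  m <- as_grid(g_roi)
  M <- nrow(m); N <- ncol(m)
  zb <- bz(b)
  if (length(zb) == 1L) zb <- rep(zb, N)
  if (length(zb) != N || any(zb < 1 | zb > M))
    stop("boundary outside the region of interest", call. = FALSE)
  Z <- row(m)
  B <- matrix(zb, M, N, byrow = TRUE)
  if (side == "below") {
    m[Z > B - pad] <- 0
  } else if (side == "above") {
    m[Z < B + pad] <- 0
  } else {
    if (is.null(b2)) stop("`b2` required for outside_pair", call. = FALSE)
    z2 <- bz(b2)
    if (length(z2) == 1L) z2 <- rep(z2, N)
    if (length(z2) != N || any(z2 < 1 | z2 > M))
      stop("boundary outside the region of interest", call. = FALSE)
    B2 <- matrix(z2, M, N, byrow = TRUE)
    m[Z < B + pad | Z > B2 - pad] <- 0
  }
  m
}

#' Centered moving average with edge truncation
#' @param z Numeric vector.
#' @param window Window length in columns; `<= 1` is a no-op.
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(z, window = 5) {
  n <- length(z)
  if (window <= 1 || n == 1L) return(z)
  half <- floor(window / 2)
  cs <- c(0, cumsum(z))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Down-sampled graph search with interpolation and smoothing
#'
#' Runs [shortest_path_boundary()] on every `factor`-th column of the region
#' (keeping columns 1, 1+factor, ...), linearly interpolates the detected row
#' positions back to full width (nearest-value extrapolation at the right
#' edge) and applies a centered moving average with edge truncation.
#' `factor = 1, smooth_window = 1` reproduces the plain search exactly.
#'
#' @param g_roi Numeric matrix (region of interest).
#' @param factor Lateral down-sampling factor (default 2).
#' @param smooth_window Moving-average window in columns (default 5).
#' @param w_min Stabilization constant for the graph search.
#' @return Numeric vector of axial positions in local region coordinates
#'   (fractional), one per column of `g_roi`.
#' @export
downsample_search_upsample <- function(g_roi, factor = 2, smooth_window = 5,
                                       w_min = 1e-5) {
  m <- as_grid(g_roi)
  N <- ncol(m)
  factor <- max(1L, as.integer(factor))
  idx <- seq(1L, N, by = factor)
  pr <- shortest_path_boundary(m[, idx, drop = FALSE], w_min)
  z <- if (length(idx) == N) as.numeric(pr$rows)
       else approx(idx, pr$rows, xout = seq_len(N), rule = 2)$y
  moving_average(z, smooth_window)
}
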