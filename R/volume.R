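#' OCT volume container
#'
#' An OCT volume is an ordered stack of B-scans (grayscale cross-sectional
#' frames) together with the physical sampling geometry. Frames are stored as
#' numeric matrices with axial rows (depth `z`, increasing towards the
#' choroid) and lateral columns (`x`), intensities in `[0, 1]`.
#'
#' @param frames List of numeric matrices, all with identical dimensions,
#'   intensities in `[0, 1]`.
#' @param axial_res_um Axial sampling, microns per pixel (rows).
#' @param lateral_res_um Lateral sampling, microns per pixel (columns).
#' @param frame_spacing_um Azimuthal spacing between consecutive B-scans,
#'   microns.
#' @param source_id Free-text provenance tag.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(frames, axial_res_um, lateral_res_um, frame_spacing_um,
                       source_id = "") {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions", call. = FALSE)
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("frame intensities must lie in [0, 1]", call. = FALSE)
  res <- c(axial_res_um, lateral_res_um, frame_spacing_um)
  if (any(!is.finite(res)) || any(res <= 0))
    stop("all three resolutions must be strictly positive", call. = FALSE)
  structure(list(
    frames = frames,
    n_frames = length(frames),
    n_rows = dims[1, 1],
    n_cols = dims[2, 1],
    axial_res_um = axial_res_um,
    lateral_res_um = lateral_res_um,
    frame_spacing_um = frame_spacing_um,
    source_id = source_id
  ), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf("OCT volume: %d frames of %d x %d px (axial x lateral)\n",
              x$n_frames, x$n_rows, x$n_cols))
  cat(sprintf("  resolution: %.2f um axial, %.2f um lateral, %.1f um between frames\n",
              x$axial_res_um, x$lateral_res_um, x$frame_spacing_um))
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' Surface set container
#'
#' The assembled output of the segmentation: for each of the eight boundary
#' labels, a matrix of axial positions indexed `(column m, frame n)`
#' (fractional pixels allowed), plus the offsets that map the (possibly
#' cropped) grid back into the source volume and the physical resolutions.
#'
#' @param surfaces Named list of numeric matrices (columns x frames), names a
#'   subset of [boundary_labels()] in anatomical order.
#' @param column_offset,frame_offset Integer offsets (0 when uncropped): the
#'   surface grid cell `(m, n)` corresponds to column `m + column_offset` and
#'   frame `n + frame_offset` of the source volume.
#' @param axial_res_um,lateral_res_um,frame_spacing_um Resolutions copied from
#'   the source volume.
#' @param n_rows Axial extent (frame height in px) used for bounds checking,
#'   or `NA` when unknown.
#' @param source_id Free-text provenance tag.
#' @param check Validate the top-to-bottom ordering invariant (default TRUE).
#' @return An object of class `surface_set`.
#' @export
surface_set <- function(surfaces, column_offset = 0L, frame_offset = 0L,
                        axial_res_um = NA_real_, lateral_res_um = NA_real_,
                        frame_spacing_um = NA_real_, n_rows = NA_integer_,
                        source_id = "", check = TRUE) {
  if (!is.list(surfaces) || is.null(names(surfaces)))
    stop("`surfaces` must be a named list of matrices", call. = FALSE)
  unknown <- setdiff(names(surfaces), BOUNDARY_LABELS)
  if (length(unknown))
    stop("unknown boundary labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  surfaces <- surfaces[intersect(BOUNDARY_LABELS, names(surfaces))]
  dims <- vapply(surfaces, dim, integer(2))
  if (length(surfaces) > 1 &&
      (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])))
    stop("all surfaces must share identical dimensions", call. = FALSE)
  s <- structure(list(
    surfaces = surfaces,
    column_offset = as.integer(column_offset),
    frame_offset = as.integer(frame_offset),
    axial_res_um = axial_res_um,
    lateral_res_um = lateral_res_um,
    frame_spacing_um = frame_spacing_um,
    n_rows = n_rows,
    source_id = source_id
  ), class = "surface_set")
  if (check) validate_surface_set(s)
  s
}

#' Validate the ordering invariant of a surface set
#'
#' Checks that at every `(column, frame)` cell the stored boundaries are
#' ordered top-to-bottom (ILM above RNFL_o above ... above RPE-CH, ties
#' allowed) and that all positions lie within the axial image bounds when the
#' frame height is known.
#'
#' @param s A [surface_set()].
#' @param tol Numerical slack for the ordering comparison.
#' @return `s`, invisibly; stops with an informative error on violation.
#' @export
validate_surface_set <- function(s, tol = 1e-9) {
  labs <- names(s$surfaces)
  if (length(labs) > 1) {
    for (i in seq_len(length(labs) - 1)) {
      a <- s$surfaces[[i]]; b <- s$surfaces[[i + 1]]
      bad <- which(a - b > tol, arr.ind = TRUE)
      if (nrow(bad))
        stop(sprintf("surface ordering violated: %s below %s at column %d, frame %d",
                     labs[i], labs[i + 1], bad[1, 1], bad[1, 2]), call. = FALSE)
    }
  }
  if (!is.na(s$n_rows)) {
    for (lab in labs) {
      v <- s$surfaces[[lab]]
      if (any(v < 1 - tol | v > s$n_rows + tol))
        stop(sprintf("surface %s leaves the axial image bounds [1, %d]",
                     lab, s$n_rows), call. = FALSE)
    }
  }
  invisible(s)
}

#' @export
print.surface_set <- function(x, ...) {
  d <- if (length(x$surfaces)) dim(x$surfaces[[1]]) else c(0L, 0L)
  cat(sprintf("Surface set: %d boundaries on a %d column x %d frame grid\n",
              length(x$surfaces), d[1], d[2]))
  cat(sprintf("  boundaries: %s\n", paste(names(x$surfaces), collapse = ", ")))
  cat(sprintf("  offsets: column %d, frame %d\n", x$column_offset, x$frame_offset))
  invisible(x)
}

#' @export
as.data.frame.surface_set <- function(x, ...) {
  do.call(rbind, lapply(names(x$surfaces), function(lab) {
    m <- x$surfaces[[lab]]
    data.frame(
      boundary = lab,
      frame = rep(seq_len(ncol(m)) + x$frame_offset, each = nrow(m)),
      column = rep(seq_len(nrow(m)) + x$column_offset, times = ncol(m)),
      z_pixels = as.vector(m),
      z_um = if (is.na(x$axial_res_um)) NA_real_ else
        as.vector(m) * x$axial_res_um,
      stringsAsFactors = FALSE
    )
  }))
}
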