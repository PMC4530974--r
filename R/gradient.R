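#' Directional edge kernel
#'
#' The matched filter for a horizontal step edge: an 11 x 5 (axial x lateral)
#' kernel whose every lateral column is `(1,1,1,1,1,0,-1,-1,-1,-1,-1)'`. The
#' dark-to-bright kernel responds to intensity increasing downwards (towards
#' the choroid); the bright-to-dark kernel is its negation. Column sums are
#' zero, so a constant image has zero gradient.
#'
#' @param orientation `"dark_to_bright"` or `"bright_to_dark"`.
#' @return An 11 x 5 numeric matrix.
#' @export
edge_kernel <- function(orientation = c("dark_to_bright", "bright_to_dark")) {
  orientation <- match.arg(orientation)
  taps <- matrix(rep(c(1, 1, 1, 1, 1, 0, -1, -1, -1, -1, -1), 5), nrow = 11)
  if (orientation == "bright_to_dark") taps <- -taps
  taps
}

KERNEL_HALF_HEIGHT <- 5L   # axial reach of the edge kernel on each side
KERNEL_HALF_WIDTH  <- 2L

as_grid <- function(g) {
  if (inherits(g, "gradient_image")) g$values else g
}

#' Directional gradient image of a B-scan
#'
#' Convolves the frame with the [edge_kernel()] of the requested orientation
#' (edge-replication padding, output the same size as the input), clamps
#' negative responses to zero and min-max normalizes the whole frame to
#' `[0, 1]`. A frame whose clamped response is identically zero is returned
#' as all zeros.
#'
#' The kernel is separable (identical lateral columns), so the convolution is
#' computed as an axial difference-of-running-sums followed by a lateral
#' running sum, which is exact and fast.
#'
#' @param frame Numeric matrix (axial rows x lateral columns), finite values.
#' @param orientation `"dark_to_bright"` or `"bright_to_dark"`.
#' @return An object of class `gradient_image`: list with `values` (matrix in
#'   `[0, 1]`) and `orientation`.
#' @export
compute_gradient <- function(frame,
                             orientation = c("dark_to_bright", "bright_to_dark")) {
  orientation <- match.arg(orientation)
  frame <- as_grid(frame)
  if (!is.matrix(frame) || any(!is.finite(frame)))
    stop("`frame` must be a finite numeric matrix", call. = FALSE)
  H <- nrow(frame); W <- ncol(frame)
  if (H < 11L || W < 5L)
    stop("frame smaller than the 11 x 5 edge kernel", call. = FALSE)

  hh <- KERNEL_HALF_HEIGHT; hw <- KERNEL_HALF_WIDTH
  # edge-replication padding
  P <- frame[c(rep(1L, hh), seq_len(H), rep(H, hh)),
             c(rep(1L, hw), seq_len(W), rep(W, hw)), drop = FALSE]

  # axial response: (sum of the 5 rows below) - (sum of the 5 rows above)
  cs <- apply(P, 2L, cumsum)                      # (H+10) x (W+4)
  cs0 <- rbind(0, cs)
  z <- seq_len(H) + hh                            # padded row index of each output row
  below <- cs0[z + hh + 1L, , drop = FALSE] - cs0[z + 1L, , drop = FALSE]
  above <- cs0[z, , drop = FALSE] - cs0[z - hh, , drop = FALSE]
  A <- below - above
  if (orientation == "bright_to_dark") A <- -A

  # lateral running sum of width 5
  rs <- t(apply(A, 1L, cumsum))
  rs0 <- cbind(0, rs)
  x <- seq_len(W) + hw
  G <- rs0[, x + hw + 1L, drop = FALSE] - rs0[, x - hw, drop = FALSE]

  G[G < 1e-9] <- 0       # clamp negatives and cumsum round-off dust
  mn <- min(G); mx <- max(G)
  G <- if (mx > mn) (G - mn) / (mx - mn) else matrix(0, H, W)
  structure(list(values = G, orientation = orientation),
            class = "gradient_image")
}

#' @export
print.gradient_image <- function(x, ...) {
  cat(sprintf("Gradient image (%s): %d x %d, range [%.3f, %.3f]\n",
              x$orientation, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Per-column min-max normalization
#'
#' Rescales each column of a gradient region independently to `[0, 1]`;
#' constant columns map to all zeros (a featureless column must not attract
#' the path). Applied after biasing/masking to restore contrast. Idempotent.
#'
#' @param g Numeric matrix (a region of interest) or `gradient_image`.
#' @return Object of the same type with normalized columns.
#' @export
normalize_columns <- function(g) {
  m <- as_grid(g)
  if (!is.matrix(m) || length(m) == 0L)
    stop("empty region", call. = FALSE)
  mn <- apply(m, 2L, min)
  mx <- apply(m, 2L, max)
  rng <- mx - mn
  out <- sweep(m, 2L, mn, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, rng[nz], "/")
  out[, !nz] <- 0
  if (inherits(g, "gradient_image")) { g$values <- out; g } else out
}
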