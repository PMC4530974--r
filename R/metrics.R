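error_stats_one <- function(d) {
  n <- length(d)
  a <- abs(d)
  mse <- mean(d)
  list(mse = mse,
       sse = sqrt(mean((d - mse)^2)),   # population standard deviation
       mue = mean(a),
       e95 = sort(a)[ceiling(0.95 * n)],
       n = n)
}

#' Compare two surface sets
#'
#' Pools the per-cell axial differences `a - b` on the jointly defined grid
#' (after aligning column/frame offsets) and computes, per boundary and
#' overall: the mean signed error (MSE, the detection bias), the population
#' standard deviation of the signed error (SSE), the mean unsigned error
#' (MUE) and the 95th-percentile unsigned error E95, taken as the order
#' statistic at `ceiling(0.95 n)` — the largest unsigned error after removing
#' the top 5% of values. All in pixels; multiply by the axial resolution for
#' microns.
#'
#' @param a,b [surface_set()] objects sharing at least one boundary label and
#'   overlapping grids.
#' @return Object of class `oct_error_stats`: list with `per_boundary` (data
#'   frame with columns boundary, mse, sse, mue, e95, n), `overall` (same
#'   statistics pooled over all shared boundaries) and `axial_res_um`.
#' @export
compare_surfaces <- function(a, b) {
  labs <- intersect(names(a$surfaces), names(b$surfaces))
  if (!length(labs))
    stop("the two surface sets share no boundary labels", call. = FALSE)

  grid_idx <- function(s) {
    d <- dim(s$surfaces[[1]])
    list(cols = seq_len(d[1]) + s$column_offset,
         frames = seq_len(d[2]) + s$frame_offset)
  }
  ga <- grid_idx(a); gb <- grid_idx(b)
  cols <- intersect(ga$cols, gb$cols)
  frames <- intersect(ga$frames, gb$frames)
  if (!length(cols) || !length(frames))
    stop("the two surface sets have disjoint grids", call. = FALSE)

  per <- vector("list", length(labs))
  pooled <- numeric(0)
  for (i in seq_along(labs)) {
    da <- a$surfaces[[labs[i]]][cols - a$column_offset,
                                frames - a$frame_offset, drop = FALSE]
    db <- b$surfaces[[labs[i]]][cols - b$column_offset,
                                frames - b$frame_offset, drop = FALSE]
    d <- as.vector(da - db)
    st <- error_stats_one(d)
    per[[i]] <- data.frame(boundary = labs[i], mse = st$mse, sse = st$sse,
                           mue = st$mue, e95 = st$e95, n = st$n,
                           stringsAsFactors = FALSE)
    pooled <- c(pooled, d)
  }
  structure(list(per_boundary = do.call(rbind, per),
                 overall = error_stats_one(pooled),
                 axial_res_um = a$axial_res_um %||% NA_real_),
            class = "oct_error_stats")
}

#' @export
print.oct_error_stats <- function(x, digits = 3, ...) {
  cat("Surface agreement (pixels):\n")
  tab <- x$per_boundary
  tab[c("mse", "sse", "mue", "e95")] <-
    lapply(tab[c("mse", "sse", "mue", "e95")], round, digits)
  print(tab, row.names = FALSE)
  o <- x$overall
  cat(sprintf("Overall: MSE %.3f +/- %.3f, MUE %.3f, E95 %.3f px (n = %d)\n",
              o$mse, o$sse, o$mue, o$e95, o$n))
  if (!is.na(x$axial_res_um))
    cat(sprintf("         MUE %.2f um at %.2f um axial resolution\n",
                o$mue * x$axial_res_um, x$axial_res_um))
  invisible(x)
}

#' @export
as.data.frame.oct_error_stats <- function(x, ...) {
  rbind(x$per_boundary,
        data.frame(boundary = "overall", mse = x$overall$mse,
                   sse = x$overall$sse, mue = x$overall$mue,
                   e95 = x$overall$e95, n = x$overall$n,
                   stringsAsFactors = FALSE))
}
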