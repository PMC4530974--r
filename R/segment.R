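#' Segment the eight intraretinal boundaries of an OCT volume
#'
#' The full schedule: fovea localization, macular cropping, a frame-
#' sequential first pass detecting the IS-OS, ILM, OS-RPE/RPE-CH pair and
#' inner triplet (the first frame bootstraps with intra-frame modes; later
#' frames reuse the previous frame's ILM/IS-OS for flattening and search
#' region refinement), enface vessel-shadow detection from the assembled
#' partial surfaces, and a second per-frame pass for the RNFL_o with vessel
#' handling. The assembled surface set must satisfy the anatomical ordering
#' invariant; violations abort with the offending boundary and frame rather
#' than being clamped. The whole pipeline is deterministic given the volume
#' and configuration.
#'
#' @param vol An [oct_volume()].
#' @param cfg A [pipeline_config()].
#' @param crop Localize the fovea and crop to the macular area first
#'   (default `TRUE`); `FALSE` segments the volume as-is.
#' @param verbose Log per-frame progress to `stderr`.
#' @return Object of class `oct_segmentation`: list with `surfaces` (a
#'   [surface_set()]), `enface` (an `enface_map`), `fovea`, `config`,
#'   `timing_s` (named per-stage seconds) and `volume_info`.
#' @export
segment_volume <- function(vol, cfg = pipeline_config(), crop = TRUE,
                           verbose = FALSE) {
  stopifnot(inherits(vol, "oct_volume"), inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timing <- c(fovea = 0, first_pass = 0, enface = 0, rnflo = 0)

  t0 <- tic()
  if (crop) {
    fovea <- detect_fovea(vol, cfg)
    say("fovea at frame %d, column %d", fovea$frame, fovea$column)
    cr <- crop_macula(vol, fovea, cfg)
    vol2 <- cr$volume; col_off <- cr$column_offset; fr_off <- cr$frame_offset
  } else {
    fovea <- NULL; vol2 <- vol; col_off <- 0L; fr_off <- 0L
  }
  timing["fovea"] <- tic() - t0

  W <- vol2$n_cols; Fn <- vol2$n_frames
  surf <- sapply(BOUNDARY_LABELS, function(l) matrix(NA_real_, W, Fn),
                 simplify = FALSE)

  t0 <- tic()
  prev_ilm <- NULL; prev_isos <- NULL
  for (n in seq_len(Fn)) {
    fr <- vol2$frames[[n]]
    if (is.null(prev_ilm)) {
      isos <- detect_isos(fr, cfg = cfg, frame_index = n)
      ilm <- detect_ilm(fr, isos = isos, cfg = cfg, frame_index = n)
    } else {
      isos <- detect_isos(fr, prev_ilm, prev_isos, cfg, n)
      ilm <- detect_ilm(fr, prev_ilm = prev_ilm, cfg = cfg, frame_index = n)
    }
    pair <- detect_rpe_pair(fr, isos, cfg, n)
    trip <- detect_inner_triplet(fr, ilm, isos, cfg, n)
    surf[["ILM"]][, n] <- bz(ilm)
    surf[["IPL-INL"]][, n] <- bz(trip$ipl_inl)
    surf[["INL-OPL"]][, n] <- bz(trip$inl_opl)
    surf[["OPL_o"]][, n] <- bz(trip$opl_o)
    surf[["IS-OS"]][, n] <- bz(isos)
    surf[["OS-RPE"]][, n] <- bz(pair$os_rpe)
    surf[["RPE-CH"]][, n] <- bz(pair$rpe_ch)
    prev_ilm <- ilm; prev_isos <- isos
    say("frame %d/%d: first pass done", n, Fn)
  }
  timing["first_pass"] <- tic() - t0

  t0 <- tic()
  enface <- compute_enface(vol2, surf[["ILM"]], surf[["IS-OS"]],
                           surf[["RPE-CH"]], cfg$enface_threshold)
  timing["enface"] <- tic() - t0

  t0 <- tic()
  for (n in seq_len(Fn)) {
    # the 5-column lateral kernel contaminates the gradient within 2 columns
    # of a shadow edge, so treat those neighbours as affected too
    vcols <- dilate_columns(enface$vessel_mask[n, ], KERNEL_HALF_WIDTH)
    rnflo <- detect_rnflo(vol2$frames[[n]],
                          surf[["ILM"]][, n], surf[["IPL-INL"]][, n],
                          vcols, cfg, n)
    surf[["RNFL_o"]][, n] <- bz(rnflo)
  }
  timing["rnflo"] <- tic() - t0

  surfaces <- surface_set(surf, column_offset = col_off,
                          frame_offset = fr_off,
                          axial_res_um = vol$axial_res_um,
                          lateral_res_um = vol$lateral_res_um,
                          frame_spacing_um = vol$frame_spacing_um,
                          n_rows = vol$n_rows, source_id = vol$source_id)

  structure(list(surfaces = surfaces, enface = enface, fovea = fovea,
                 config = cfg, timing_s = timing,
                 volume_info = list(n_frames = vol$n_frames,
                                    n_rows = vol$n_rows, n_cols = vol$n_cols,
                                    cropped_frames = Fn, cropped_cols = W,
                                    source_id = vol$source_id)),
            class = "oct_segmentation")
}

#' @export
print.oct_segmentation <- function(x, ...) {
  vi <- x$volume_info
  cat(sprintf("OCT segmentation of %s\n",
              if (nzchar(vi$source_id)) vi$source_id else "volume"))
  cat(sprintf("  input: %d frames x %d x %d px; segmented grid: %d columns x %d frames\n",
              vi$n_frames, vi$n_rows, vi$n_cols, vi$cropped_cols,
              vi$cropped_frames))
  if (!is.null(x$fovea))
    cat(sprintf("  fovea: frame %d, column %d (ILM to RPE-CH %.1f px)\n",
                x$fovea$frame, x$fovea$column, x$fovea$distance_px))
  cat(sprintf("  vessel-shadowed A-scans: %d of %d\n",
              sum(x$enface$vessel_mask), length(x$enface$vessel_mask)))
  cat(sprintf("  elapsed: %.2f s (%s)\n", sum(x$timing_s),
              paste(sprintf("%s %.2f", names(x$timing_s), x$timing_s),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.oct_segmentation <- function(object, ...) {
  s <- object$surfaces$surfaces
  tab <- data.frame(
    boundary = names(s),
    z_min = vapply(s, min, numeric(1)),
    z_mean = vapply(s, mean, numeric(1)),
    z_max = vapply(s, max, numeric(1)),
    row.names = NULL)
  cat("Axial position (px) per boundary over the segmented grid:\n")
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' @export
coef.oct_segmentation <- function(object, ...) object$surfaces$surfaces

#' @export
as.data.frame.oct_segmentation <- function(x, ...) as.data.frame(x$surfaces)

#' Plot segmented boundaries over a B-scan
#'
#' @param x An `oct_segmentation`.
#' @param vol The source [oct_volume()] (for the image background; omit to
#'   plot boundaries only).
#' @param frame Frame of the segmented grid to display.
#' @param ... Passed to [graphics::image()].
#' @export
plot.oct_segmentation <- function(x, vol = NULL, frame = 1, ...) {
  s <- x$surfaces
  W <- nrow(s$surfaces[[1]])
  H <- if (!is.na(s$n_rows)) s$n_rows else max(s$surfaces[["RPE-CH"]]) + 20
  if (!is.null(vol)) {
    img <- vol$frames[[frame + s$frame_offset]]
    img <- img[, seq_len(W) + s$column_offset, drop = FALSE]
    image(x = seq_len(ncol(img)), y = seq_len(nrow(img)),
          z = t(img)[, rev(seq_len(nrow(img)))],
          col = gray(seq(0, 1, length.out = 256)),
          xlab = "lateral column", ylab = "axial row (inverted)", ...)
    yz <- function(z) nrow(img) + 1 - z
  } else {
    plot(NULL, xlim = c(1, W), ylim = c(H, 1),
         xlab = "lateral column", ylab = "axial row", ...)
    yz <- identity
  }
  cols <- grDevices::hcl.colors(length(s$surfaces), "Dark 3")
  for (i in seq_along(s$surfaces))
    lines(seq_len(W), yz(s$surfaces[[i]][, frame]), col = cols[i], lwd = 1.5)
  legend("bottomleft", legend = names(s$surfaces), col = cols, lwd = 1.5,
         cex = 0.7, bg = "white")
  invisible(x)
}
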