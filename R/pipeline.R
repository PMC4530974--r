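#' Pipeline configuration
#'
#' Tunable parameters of the segmentation schedule. Defaults are the working
#' values of the method: a 10-px inter-frame search margin (adjacent B-scans
#' shift by less than 10 px axially at typical inter-frame spacing), a 40-px
#' band below the flattened IS-OS for the RPE pair, lateral down-sampling by
#' 2 with a 5-column moving-average smoothing of the interpolated boundary,
#' an enface vessel threshold of -0.1, a 6 mm x 6 mm macular crop, and fovea
#' localization on frames 21..40.
#'
#' @param w_min Positive stabilization constant of the graph arc weights.
#' @param interframe_margin Axial margin (px) of the inter-frame search
#'   region.
#' @param rpe_band_height Height (px) of the search band below the flattened
#'   IS-OS edge for the OS-RPE / RPE-CH pair.
#' @param downsample_factor Lateral down-sampling factor of the graph search.
#' @param smooth_window Moving-average window (columns, full resolution)
#'   applied to interpolated boundaries.
#' @param enface_threshold Enface value below which an A-scan is flagged as
#'   vessel-shadowed.
#' @param crop_extent_mm Side length (mm) of the macular crop centered at the
#'   fovea.
#' @param fovea_frame_range Inclusive frame range searched for the fovea
#'   (clipped to the volume; volumes ending before the range use all frames).
#' @param edge_exclusion_px Rows excluded from a search region at an edge
#'   bounded by an already-detected boundary of the same gradient
#'   orientation, so its kernel-response shoulder (half the 11-row kernel)
#'   cannot capture the path.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(w_min = 1e-5, interframe_margin = 10,
                            rpe_band_height = 40, downsample_factor = 2,
                            smooth_window = 5, enface_threshold = -0.1,
                            crop_extent_mm = 6, fovea_frame_range = c(21L, 40L),
                            edge_exclusion_px = 5) {
  stopifnot(w_min > 0, interframe_margin >= 0, rpe_band_height >= 1,
            downsample_factor >= 1, smooth_window >= 1,
            crop_extent_mm > 0, length(fovea_frame_range) == 2L,
            fovea_frame_range[1] <= fovea_frame_range[2],
            edge_exclusion_px >= 0)
  structure(list(w_min = w_min, interframe_margin = interframe_margin,
                 rpe_band_height = rpe_band_height,
                 downsample_factor = downsample_factor,
                 smooth_window = smooth_window,
                 enface_threshold = enface_threshold,
                 crop_extent_mm = crop_extent_mm,
                 fovea_frame_range = as.integer(fovea_frame_range),
                 edge_exclusion_px = as.integer(edge_exclusion_px)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm,
                                   paste(x[[nm]], collapse = ":")))
  invisible(x)
}

run_search <- function(groi, cfg) {
  downsample_search_upsample(groi, cfg$downsample_factor, cfg$smooth_window,
                             cfg$w_min)
}

detection_error <- function(boundary, frame_index, msg) {
  stop(sprintf("detection of %s failed on frame %s: %s",
               boundary, frame_index, msg), call. = FALSE)
}

#' Detect the IS-OS boundary in one frame
#'
#' The IS-OS junction is the most prominent flat dark-to-bright boundary. On
#' a bootstrap frame (no previous-frame context) the whole gradient image is
#' searched after multiplication with the lower-bias map, which suppresses
#' the shallower high-contrast ILM. On subsequent frames the frame is
#' flattened with the previous frame's ILM and the search restricted to the
#' inter-frame region around the previous IS-OS.
#'
#' @param frame B-scan matrix.
#' @param prev_ilm,prev_isos Previous-frame boundaries (both `NULL` for the
#'   bootstrap mode).
#' @param cfg A [pipeline_config()].
#' @param frame_index Frame number, for error messages and the result.
#' @return An [oct_boundary()] in raw frame coordinates.
#' @export
detect_isos <- function(frame, prev_ilm = NULL, prev_isos = NULL,
                        cfg = pipeline_config(), frame_index = NA_integer_) {
  H <- nrow(frame)
  if (is.null(prev_ilm)) {
    g <- compute_gradient(frame, "dark_to_bright")
    z <- run_search(apply_lower_bias(g$values), cfg)
    return(oct_boundary(z, frame_index, "IS-OS"))
  }
  fl <- flatten(frame, prev_ilm)
  prev_isos_f <- flatten_boundary(bz(prev_isos), fl$record)
  region <- interframe_region(prev_isos_f, cfg$interframe_margin, H)
  g <- compute_gradient(fl$frame, "dark_to_bright")
  groi <- crop_region(g, region)
  # The adjacent-frame smoothness assumption is per A-scan: zero the
  # gradient outside each column's own +/- margin band. The scalar hull
  # alone would admit the RPE-CH, which runs nearly flat across the foveal
  # anti-pit left on the IS-OS by ILM-referenced flattening.
  local_prev <- prev_isos_f - region$z_top + 1
  groi <- mask_relative(groi, pmax(1, local_prev - cfg$interframe_margin),
                        "above")
  groi <- mask_relative(groi, pmin(region$M, local_prev + cfg$interframe_margin),
                        "below")
  zl <- run_search(groi, cfg)
  oct_boundary(unflatten_boundary(zl + region$z_top - 1, fl$record),
               frame_index, "IS-OS")
}

#' Detect the ILM boundary in one frame
#'
#' Dark-to-bright search above the flattened IS-OS (bootstrap mode:
#' intra-frame flattening with the current frame's IS-OS, search region the
#' area above it), or — on subsequent frames — inter-frame flattening with
#' the previous frame's ILM, which removes most of the foveal curvature and
#' keeps the residual boundary within the 8-connected path's reach, plus the
#' inter-frame search region.
#'
#' @inheritParams detect_isos
#' @param isos Current-frame IS-OS boundary (bootstrap mode).
#' @param prev_ilm Previous-frame ILM (inter-frame mode; wins over `isos`
#'   when both are given).
#' @return An [oct_boundary()] in raw frame coordinates.
#' @export
detect_ilm <- function(frame, isos = NULL, prev_ilm = NULL,
                       cfg = pipeline_config(), frame_index = NA_integer_) {
  H <- nrow(frame)
  if (!is.null(prev_ilm)) {
    fl <- flatten(frame, prev_ilm)
    prev_f <- flatten_boundary(bz(prev_ilm), fl$record)  # == target_row
    region <- interframe_region(prev_f, cfg$interframe_margin, H)
    g <- compute_gradient(fl$frame, "dark_to_bright")
    zl <- run_search(crop_region(g, region), cfg)
    return(oct_boundary(unflatten_boundary(zl + region$z_top - 1, fl$record),
                        frame_index, "ILM"))
  }
  if (is.null(isos))
    stop("either `isos` or `prev_ilm` is required", call. = FALSE)
  fl <- flatten(frame, isos)
  r <- fl$record$target_row
  bottom <- r - 1L - cfg$edge_exclusion_px    # exclude the IS-OS response shoulder
  if (bottom < 1L)
    detection_error("ILM", frame_index, "empty search region above the IS-OS")
  g <- compute_gradient(fl$frame, "dark_to_bright")
  zl <- run_search(g$values[seq_len(bottom), , drop = FALSE], cfg)
  oct_boundary(unflatten_boundary(zl, fl$record), frame_index, "ILM")
}

#' Detect the OS-RPE and RPE-CH boundaries
#'
#' Intra-frame flattening with the IS-OS; the search region is the rectangle
#' of `rpe_band_height` rows below the flattened IS-OS edge. The RPE-CH is
#' detected first on the dark-to-bright gradient (with the IS-OS's own
#' response shoulder at the band top masked out and per-column
#' normalization); the band is then masked below the RPE-CH and the OS-RPE
#' detected on the bright-to-dark gradient. The pair ordering OS-RPE <=
#' RPE-CH is enforced, never silently repaired.
#'
#' @inheritParams detect_isos
#' @param isos Current-frame IS-OS boundary.
#' @return List with `os_rpe` and `rpe_ch` boundaries in raw coordinates.
#' @export
detect_rpe_pair <- function(frame, isos, cfg = pipeline_config(),
                            frame_index = NA_integer_) {
  H <- nrow(frame)
  fl <- flatten(frame, isos)
  r <- fl$record$target_row
  region <- intraframe_region(r, mode = "rect_below",
                              height = cfg$rpe_band_height, frame_height = H)

  g8 <- compute_gradient(fl$frame, "dark_to_bright")
  groi8 <- crop_region(g8, region)
  top_excl <- min(nrow(groi8), cfg$edge_exclusion_px + 1L)
  groi8[seq_len(top_excl), ] <- 0      # IS-OS response shoulder at the band top
  z8l <- run_search(normalize_columns(groi8), cfg)

  g7 <- compute_gradient(fl$frame, "bright_to_dark")
  groi7 <- crop_region(g7, region)
  groi7[seq_len(top_excl), ] <- 0      # keep the path off the band's IS-OS edge
  groi7 <- mask_relative(groi7, z8l, "below")
  z7l <- run_search(normalize_columns(groi7), cfg)

  if (any(z7l > z8l + 1e-9))
    detection_error("OS-RPE/RPE-CH", frame_index,
                    "ordering violated (OS-RPE below RPE-CH)")
  list(os_rpe = oct_boundary(unflatten_boundary(z7l + region$z_top - 1,
                                                fl$record),
                             frame_index, "OS-RPE"),
       rpe_ch = oct_boundary(unflatten_boundary(z8l + region$z_top - 1,
                                                fl$record),
                             frame_index, "RPE-CH"))
}

#' Detect the IPL-INL, INL-OPL and OPL_o boundaries
#'
#' Intra-frame flattening with the IS-OS; the search region is the rectangle
#' between the lowest point of the flattened ILM and the flattened IS-OS.
#' The OPL_o (lowest bright-to-dark boundary in the region) is detected
#' first after multiplication with the lower-bias map; masking below the
#' OPL_o (response shoulder included) then isolates the IPL-INL; the INL-OPL
#' is detected on the dark-to-bright gradient masked to strictly between the
#' two. Per-column normalization is applied before each search; ordering is
#' enforced.
#'
#' @inheritParams detect_isos
#' @param ilm,isos Current-frame ILM and IS-OS boundaries.
#' @return List with `ipl_inl`, `inl_opl`, `opl_o` boundaries in raw
#'   coordinates.
#' @export
detect_inner_triplet <- function(frame, ilm, isos, cfg = pipeline_config(),
                                 frame_index = NA_integer_) {
  fl <- flatten(frame, isos)
  r <- fl$record$target_row
  ilm_f <- flatten_boundary(bz(ilm), fl$record)
  region <- tryCatch(intraframe_region(ilm_f, rep(r, length(ilm_f)),
                                       mode = "rect_between_extremes"),
                     error = function(e)
                       detection_error("IPL-INL/INL-OPL/OPL_o", frame_index,
                                       conditionMessage(e)))
  b2d <- crop_region(compute_gradient(fl$frame, "bright_to_dark"), region)

  # The lower-bias map selects the OPL_o corridor but tilts near-tie rows
  # towards the region bottom (the bias ratio between adjacent rows is
  # ~1 + 1/z), which can displace the path by one row where the boundary
  # steps. Select with bias, then refine on the unbiased gradient inside a
  # narrow corridor around the selected path.
  z5b <- run_search(normalize_columns(apply_lower_bias(b2d)), cfg)
  M5 <- nrow(b2d)
  corr <- cfg$edge_exclusion_px
  g5 <- mask_relative(b2d, pmax(1, z5b - corr), "above")
  g5 <- mask_relative(g5, pmin(M5, z5b + corr), "below")
  z5l <- run_search(normalize_columns(g5), cfg)

  pad <- cfg$edge_exclusion_px + 1L
  g_ipl <- mask_relative(b2d, z5l, "below", pad = pad)
  z3l <- run_search(normalize_columns(g_ipl), cfg)

  d2b <- crop_region(compute_gradient(fl$frame, "dark_to_bright"), region)
  g_inl <- mask_relative(d2b, z3l, "outside_pair", b2 = z5l)
  z4l <- run_search(normalize_columns(g_inl), cfg)

  if (any(z3l > z4l + 1e-9) || any(z4l > z5l + 1e-9))
    detection_error("IPL-INL/INL-OPL/OPL_o", frame_index,
                    "ordering violated within the inner triplet")
  un <- function(zl, lab)
    oct_boundary(unflatten_boundary(zl + region$z_top - 1, fl$record),
                 frame_index, lab)
  list(ipl_inl = un(z3l, "IPL-INL"), inl_opl = un(z4l, "INL-OPL"),
       opl_o = un(z5l, "OPL_o"))
}

#' Detect the outer RNFL boundary with vessel handling
#'
#' Intra-frame flattening with the ILM; bright-to-dark search between the
#' flattened ILM edge and the highest point of the IPL-INL (its response
#' shoulder excluded). The gradient of vessel-shadowed A-scans is set to 1,
#' so crossing them costs only `w_min` per arc and the path bridges the
#' disrupted edge smoothly.
#'
#' @inheritParams detect_isos
#' @param ilm,ipl_inl Current-frame ILM and IPL-INL boundaries.
#' @param vessel_cols Logical vector (one per column): A-scan shadowed by a
#'   vessel.
#' @return An [oct_boundary()] in raw frame coordinates.
#' @export
detect_rnflo <- function(frame, ilm, ipl_inl, vessel_cols,
                         cfg = pipeline_config(), frame_index = NA_integer_) {
  W <- ncol(frame)
  if (length(vessel_cols) != W)
    stop("`vessel_cols` must have one flag per column", call. = FALSE)
  fl <- flatten(frame, ilm)
  r <- fl$record$target_row
  ipl_f <- flatten_boundary(bz(ipl_inl), fl$record)
  bottom <- floor(min(ipl_f)) - cfg$edge_exclusion_px - 1L
  if (bottom < r)
    detection_error("RNFL_o", frame_index,
                    "empty search region between ILM and IPL-INL")
  g <- compute_gradient(fl$frame, "bright_to_dark")
  groi <- g$values[r:bottom, , drop = FALSE]
  groi[seq_len(min(nrow(groi), cfg$edge_exclusion_px + 1L)), ] <- 0
  groi[, vessel_cols] <- 1
  zl <- run_search(groi, cfg)
  oct_boundary(unflatten_boundary(zl + r - 1, fl$record),
               frame_index, "RNFL_o")
}

#' Enface projection and vessel-shadow detection
#'
#' For every A-scan `(frame n, column x)`, the mean intensity between the
#' IS-OS and RPE-CH minus the mean of the 30 pixels below the ILM. A vessel
#' shadow attenuates the first term and brightens the second, so shadowed
#' A-scans have a markedly negative enface value; they are flagged where the
#' value falls below the threshold.
#'
#' @param vol An [oct_volume()] (typically the cropped volume).
#' @param ilm_surf,isos_surf,rpech_surf Numeric matrices (columns x frames)
#'   of the three surfaces in `vol` coordinates.
#' @param threshold Vessel threshold (default -0.1).
#' @return Object of class `enface_map`: list with `values` (frames x
#'   columns), `threshold` and logical `vessel_mask`.
#' @export
compute_enface <- function(vol, ilm_surf, isos_surf, rpech_surf,
                           threshold = -0.1) {
  H <- vol$n_rows; W <- vol$n_cols; Fn <- vol$n_frames
  z1 <- round(ilm_surf); z6 <- round(isos_surf); z8 <- round(rpech_surf)
  if (any(z8 < z6))
    stop("RPE-CH surface above IS-OS: invalid enface bands", call. = FALSE)
  E <- matrix(0, Fn, W)
  x <- seq_len(W)
  for (n in seq_len(Fn)) {
    cs0 <- rbind(0, apply(vol$frames[[n]], 2L, cumsum))
    lo6 <- pmax(1, pmin(H, z6[, n])); hi8 <- pmax(1, pmin(H, z8[, n]))
    t1 <- (cs0[cbind(hi8 + 1L, x)] - cs0[cbind(lo6, x)]) / (hi8 - lo6 + 1L)
    lo1 <- pmax(1, pmin(H, z1[, n])); hi1 <- pmin(H, lo1 + 29L)
    t2 <- (cs0[cbind(hi1 + 1L, x)] - cs0[cbind(lo1, x)]) / (hi1 - lo1 + 1L)
    E[n, ] <- t1 - t2
  }
  structure(list(values = E, threshold = threshold,
                 vessel_mask = E < threshold),
            class = "enface_map")
}

#' @export
print.enface_map <- function(x, ...) {
  cat(sprintf("Enface map: %d frames x %d columns; %d A-scans flagged as vessel (threshold %g)\n",
              nrow(x$values), ncol(x$values), sum(x$vessel_mask), x$threshold))
  invisible(x)
}

dilate_columns <- function(v, width) {
  out <- v
  for (k in seq_len(width)) {
    n <- length(v)
    out <- out | c(v[-seq_len(k)], rep(FALSE, k)) |
           c(rep(FALSE, k), v[seq_len(n - k)])
  }
  out
}

bootstrap_frame <- function(frame, cfg, frame_index = NA_integer_) {
  isos <- detect_isos(frame, cfg = cfg, frame_index = frame_index)
  ilm <- detect_ilm(frame, isos = isos, cfg = cfg, frame_index = frame_index)
  list(isos = isos, ilm = ilm)
}

#' Locate the fovea
#'
#' Segments the ILM and RPE-CH on each frame of the configured range with
#' the single-frame (bootstrap) detectors and returns the `(frame, column)`
#' with the smallest ILM-to-RPE-CH axial distance; ties resolve to the
#' smaller frame, then column.
#'
#' @param vol An [oct_volume()].
#' @param cfg A [pipeline_config()].
#' @return List with `frame`, `column` and the minimal `distance_px`.
#' @export
detect_fovea <- function(vol, cfg = pipeline_config()) {
  rng <- intersect(seq(cfg$fovea_frame_range[1], cfg$fovea_frame_range[2]),
                   seq_len(vol$n_frames))
  if (!length(rng)) rng <- seq_len(vol$n_frames)
  best <- list(frame = NA_integer_, column = NA_integer_, distance_px = Inf)
  for (n in rng) {
    fr <- vol$frames[[n]]
    bs <- bootstrap_frame(fr, cfg, n)
    pair <- detect_rpe_pair(fr, bs$isos, cfg, n)
    d <- bz(pair$rpe_ch) - bz(bs$ilm)
    i <- which.min(d)
    if (d[i] < best$distance_px) {
      best <- list(frame = n, column = i, distance_px = d[i])
    }
  }
  best
}

#' Crop a volume to the macular area around the fovea
#'
#' Keeps A-scans within half the crop extent of the fovea column laterally
#' and of the fovea frame azimuthally, clipped to the volume (one-sided at
#' edges; a crop larger than the volume is the identity).
#'
#' @param vol An [oct_volume()].
#' @param fovea List with `frame` and `column` (from [detect_fovea()]).
#' @param cfg A [pipeline_config()].
#' @return List with `volume` (cropped [oct_volume()]), `column_offset` and
#'   `frame_offset` (0-based offsets into the source volume).
#' @export
crop_macula <- function(vol, fovea, cfg = pipeline_config()) {
  half_um <- cfg$crop_extent_mm / 2 * 1000
  half_cols <- floor(half_um / vol$lateral_res_um)
  half_frames <- floor(half_um / vol$frame_spacing_um)
  cols <- max(1L, fovea$column - half_cols):min(vol$n_cols,
                                                fovea$column + half_cols)
  frs <- max(1L, fovea$frame - half_frames):min(vol$n_frames,
                                                fovea$frame + half_frames)
  cropped <- oct_volume(lapply(vol$frames[frs],
                               function(f) f[, cols, drop = FALSE]),
                        vol$axial_res_um, vol$lateral_res_um,
                        vol$frame_spacing_um, vol$source_id)
  list(volume = cropped,
       column_offset = cols[1] - 1L,
       frame_offset = frs[1] - 1L)
}
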