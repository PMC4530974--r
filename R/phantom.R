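#' Specification of a synthetic layered-retina phantom
#'
#' Describes an OCT-like volume with exactly known geometry: nine
#' reflectivity bands separated by the eight target boundaries, a shared
#' low-frequency curvature (lateral and inter-frame sinusoid), a foveal pit
#' (2-D Gaussian depression of the five inner boundaries, tapering with
#' depth), multiplicative gamma speckle, and vessel-shadow columns
#' (brightened just below the ILM, attenuated beneath).
#'
#' Band reflectivities default to values giving every boundary the transition
#' direction the detection schedule expects: dark-to-bright at the ILM,
#' INL-OPL, IS-OS and RPE-CH; bright-to-dark at the RNFL_o, IPL-INL, OPL_o
#' and OS-RPE.
#'
#' @param n_frames,n_rows,n_cols Volume dimensions (frames, axial px,
#'   lateral px).
#' @param reflectivities Named vector of nine band intensities, vitreous to
#'   choroid.
#' @param ilm_depth_px Base axial position of the ILM.
#' @param thickness_px Named vector of the seven band thicknesses between
#'   consecutive boundaries (rnfl, gcl_ipl, inl, opl, onl, is_os, os).
#' @param lateral_amp,lateral_period Shared lateral curvature sinusoid
#'   applied to all surfaces: amplitude (px) and period (px).
#' @param frame_amp,frame_period Bulk axial motion: a frame-wise sinusoidal
#'   shift (px / frames) of the whole retina, emulating residual axial eye
#'   motion between B-scans.
#' @param pit_depth ILM pit depth in px (0 disables the pit).
#' @param pit_taper Multipliers applied to `pit_depth` for the five inner
#'   boundaries (ILM .. OPL_o), non-increasing (frame-varying pit only; the
#'   frame-constant pit tapers by integer offsets).
#' @param pit_center_frame,pit_center_col Pit center (defaults: volume
#'   center).
#' @param pit_sigma_col,pit_sigma_frame Gaussian widths of the pit (px,
#'   frames). `pit_sigma_frame = Inf` renders the pit identically on every
#'   frame, the regime in which the pipeline can recover every boundary
#'   exactly; a finite value fades the pit across frames, which is more
#'   realistic but, combined with pixel rounding, leaves ~1-px residuals at
#'   rounding-step columns.
#' @param speckle_shape Gamma shape of the unit-mean multiplicative speckle
#'   (variance `1/shape`); `Inf` disables noise. The default 20 emulates the
#'   residual speckle contrast of a 5-frame-averaged acquisition.
#' @param vessels `NULL`, or a data frame with columns `center`, `width`,
#'   `attenuation`, `brightening` (one row per vessel-shadow band, spanning
#'   all frames).
#' @param axial_res_um,lateral_res_um,frame_spacing_um Physical sampling.
#' @param seed Integer seed fully determining the generated volume.
#' @param name Fixture name tag.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_frames = 51L, n_rows = 496L, n_cols = 644L,
                         reflectivities = c(vitreous = 0.05, rnfl = 0.60,
                                            gcl_ipl = 0.45, inl = 0.22,
                                            opl = 0.42, onl = 0.10,
                                            is_os = 0.85, os = 0.35,
                                            choroid = 0.60),
                         ilm_depth_px = 140,
                         thickness_px = c(rnfl = 15, gcl_ipl = 25, inl = 15,
                                          opl = 12, onl = 45, is_os = 12,
                                          os = 10),
                         lateral_amp = 3, lateral_period = 200,
                         frame_amp = 1, frame_period = 8,
                         pit_depth = 30,
                         pit_taper = c(1, 0.9, 0.833, 0.767, 0.7),
                         pit_center_frame = NA, pit_center_col = NA,
                         pit_sigma_col = 11, pit_sigma_frame = 2.2,
                         speckle_shape = 20,
                         vessels = NULL,
                         axial_res_um = 3.9, lateral_res_um = 9.3,
                         frame_spacing_um = 120,
                         seed = 1L, name = "custom") {
  if (length(reflectivities) != 9L)
    stop("nine band reflectivities required", call. = FALSE)
  if (length(thickness_px) != 7L)
    stop("seven band thicknesses required", call. = FALSE)
  if (length(pit_taper) != 5L || is.unsorted(rev(pit_taper)))
    stop("`pit_taper` must be five non-increasing multipliers", call. = FALSE)
  structure(as.list(environment()), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec '%s': %d frames x %d x %d px, pit depth %g px, %s noise, %d vessels\n",
              x$name, x$n_frames, x$n_rows, x$n_cols, x$pit_depth,
              if (is.finite(x$speckle_shape))
                sprintf("gamma(%g) speckle", x$speckle_shape) else "no",
              if (is.null(x$vessels)) 0L else nrow(x$vessels)))
  invisible(x)
}

# Evaluate the true integer surfaces of a spec.
#
# Every term is rounded separately before summation ("rounding-coherent"
# construction): the shared lateral curvature R(x), the shared bulk axial
# motion B(n) and the pit displacement D_i. This matters: the segmenter
# flattens frames by integer column shifts derived from a reference surface,
# and if two surfaces carried independently rounded copies of a shared
# smooth term, their difference would acquire one-column +/-1 "blips" that
# no 8-connected path can trace. With coherent rounding, every flattened
# target boundary is a single rounded staircase.
#
# The pit comes in two flavours:
#  - frame-varying (pit_sigma_frame finite): D_i = round(taper_i * depth *
#    P(x) * Gn(n)); adjacent-frame residuals then carry the +/-1 rounding
#    blips and, when the wall slope exceeds 1 px/column, two-row lateral
#    steps — the realistic regime, recoverable to ~1 px but not exactly.
#  - frame-constant (pit_sigma_frame = Inf): a single rounded lateral
#    staircase A(x) = round(depth * P(x)) with integer per-surface taper
#    offsets D_i = max(0, A - (i-1)); combined with the bulk motion B(n)
#    this gives genuine inter-frame variation while keeping every flattened
#    residual an isolated-step staircase — the exact-recovery regime.
phantom_surfaces <- function(spec) {
  n <- spec$n_frames; W <- spec$n_cols
  cf <- if (is.na(spec$pit_center_frame)) (n + 1) / 2 else spec$pit_center_frame
  cx <- if (is.na(spec$pit_center_col)) (W + 1) / 2 else spec$pit_center_col
  base <- spec$ilm_depth_px + c(0, cumsum(spec$thickness_px))
  x <- seq_len(W)
  R <- round(spec$lateral_amp * sin(2 * pi * x / spec$lateral_period + 0.7))
  B <- round(spec$frame_amp * sin(2 * pi * seq_len(n) / spec$frame_period + 0.3))
  P <- if (spec$pit_depth > 0)
    exp(-0.5 * ((x - cx) / spec$pit_sigma_col)^2) else rep(0, W)

  surfs <- lapply(1:8, function(i) matrix(0L, W, n))
  names(surfs) <- BOUNDARY_LABELS
  frame_constant_pit <- !is.finite(spec$pit_sigma_frame)
  A <- round(spec$pit_depth * P)
  for (fr in seq_len(n)) {
    D <- matrix(0, W, 8)
    if (spec$pit_depth > 0) {
      if (frame_constant_pit) {
        for (i in 1:5) D[, i] <- pmax(0, A - (i - 1))
      } else {
        Gn <- exp(-0.5 * ((fr - cf) / spec$pit_sigma_frame)^2)
        for (i in 1:5)
          D[, i] <- round(spec$pit_taper[i] * spec$pit_depth * P * Gn)
      }
    }
    for (i in 1:8)
      surfs[[i]][, fr] <- as.integer(base[i] + R + B[fr] + D[, i])
  }
  list(surfaces = surfs, center_frame = cf, center_col = cx)
}

check_phantom_invariants <- function(spec, surfs) {
  labs <- BOUNDARY_LABELS
  for (i in 1:7) {
    gap <- surfs[[i + 1]] - surfs[[i]]
    if (min(gap) < 2)
      stop(sprintf("phantom spec violates constraint: layer %s-%s thinner than 2 px",
                   labs[i], labs[i + 1]), call. = FALSE)
  }
  if (min(surfs[[1]]) < 2 || max(surfs[[8]]) > spec$n_rows - 1)
    stop("phantom spec violates constraint: surfaces leave the axial extent",
         call. = FALSE)
  if (spec$n_frames > 1) {
    for (i in 1:8) {
      step <- abs(surfs[[i]][, -1, drop = FALSE] -
                  surfs[[i]][, -spec$n_frames, drop = FALSE])
      if (max(step) > 10)
        stop(sprintf("phantom spec violates constraint: %s shifts more than 10 px between adjacent frames",
                     labs[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic OCT phantom volume
#'
#' Renders piecewise-constant reflectivity bands between the true surfaces
#' with a one-pixel blended transition row on each boundary (the discrete
#' step-edge model the detection kernel is matched to), plants vessel-shadow
#' columns, applies multiplicative gamma speckle, and returns the volume
#' together with the exact ground truth.
#'
#' @param spec A [phantom_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return List with `volume` (an [oct_volume()]), `truth` (a
#'   [surface_set()] of the rounded true surfaces), `vessel_mask` (logical
#'   frames x columns matrix of planted shadow columns) and `spec`.
#' @export
generate_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  seed <- if (is.null(seed)) spec$seed else seed
  ps <- phantom_surfaces(spec)
  surfs <- ps$surfaces
  check_phantom_invariants(spec, surfs)

  H <- spec$n_rows; W <- spec$n_cols
  lv <- as.numeric(spec$reflectivities)
  trans <- (lv[-9] + lv[-1]) / 2          # blended transition-row values
  vals <- numeric(17)
  vals[seq(1, 17, 2)] <- lv
  vals[seq(2, 16, 2)] <- trans

  vmask <- matrix(FALSE, spec$n_frames, W)
  vcols <- list()
  if (!is.null(spec$vessels)) {
    for (k in seq_len(nrow(spec$vessels))) {
      v <- spec$vessels[k, ]
      cols <- max(1L, round(v$center - (v$width - 1) / 2)) :
              min(W, round(v$center + (v$width - 1) / 2))
      vcols[[k]] <- cols
      vmask[, cols] <- TRUE
    }
  }

  frames <- with_seed(seed, {
    lapply(seq_len(spec$n_frames), function(fr) {
      zs <- vapply(surfs, function(s) s[, fr], numeric(W))
      img <- vapply(seq_len(W), function(x) {
        z <- zs[x, ]
        lens <- numeric(17)
        lens[seq(1, 17, 2)] <- c(z[1] - 1, diff(z) - 1, H - z[8])
        lens[seq(2, 16, 2)] <- 1
        rep(vals, times = lens)
      }, numeric(H))
      if (length(vcols)) {
        for (k in seq_along(vcols)) {
          v <- spec$vessels[k, ]
          for (x in vcols[[k]]) {
            z1 <- zs[x, 1]
            hi <- min(H, z1 + 12)
            img[(z1 + 3):hi, x] <- img[(z1 + 3):hi, x] * v$brightening
            if (hi < H)
              img[(hi + 1):H, x] <- img[(hi + 1):H, x] * v$attenuation
          }
        }
      }
      if (is.finite(spec$speckle_shape))
        img <- img * matrix(rgamma(H * W, shape = spec$speckle_shape,
                                   rate = spec$speckle_shape), H, W)
      img[img > 1] <- 1
      img[img < 0] <- 0
      img
    })
  })

  vol <- oct_volume(frames, spec$axial_res_um, spec$lateral_res_um,
                    spec$frame_spacing_um,
                    source_id = sprintf("phantom:%s:seed%d", spec$name, seed))
  truth <- surface_set(lapply(surfs, function(s) s + 0.0),
                       axial_res_um = spec$axial_res_um,
                       lateral_res_um = spec$lateral_res_um,
                       frame_spacing_um = spec$frame_spacing_um,
                       n_rows = H,
                       source_id = vol$source_id)
  list(volume = vol, truth = truth, vessel_mask = vmask, spec = spec)
}

default_vessels <- function(n_cols) {
  data.frame(center = round(c(0.15, 0.35, 0.62, 0.85) * n_cols),
             width = c(9, 7, 11, 9),
             attenuation = 0.35,
             brightening = 1.3)
}

#' Named phantom fixtures
#'
#' Standard study conditions used throughout the test-bench:
#' * `flat_noiseless` — 3 small flat frames, no curvature, pit, noise or
#'   vessels; the identity case.
#' * `fovea_clean` — 10 full-width frames with lateral curvature, bulk
#'   axial motion and a wide frame-constant foveal pit (wall slope below
#'   1 px/column, the regime where the graph search can recover every
#'   boundary exactly); no noise.
#' * `fovea_speckle` — 10 frames with the narrow frame-varying pit (wall
#'   slope above 1 px/column) plus speckle.
#' * `vessels_speckle` — `fovea_speckle` plus four vessel-shadow bands.
#' * `full_volume` — the full 51-frame, 496 x 644 cropped-macula geometry
#'   with speckle and vessels.
#'
#' @return Named list of [phantom_spec()] objects.
#' @export
default_specs <- function() {
  list(
    flat_noiseless = phantom_spec(n_frames = 3L, n_rows = 300L, n_cols = 220L,
                                  lateral_amp = 0, frame_amp = 0,
                                  pit_depth = 0, speckle_shape = Inf,
                                  name = "flat_noiseless"),
    fovea_clean = phantom_spec(n_frames = 10L, speckle_shape = Inf,
                               pit_sigma_col = 30, pit_sigma_frame = Inf,
                               frame_amp = 3, name = "fovea_clean"),
    fovea_speckle = phantom_spec(n_frames = 10L, name = "fovea_speckle"),
    vessels_speckle = phantom_spec(n_frames = 10L,
                                   vessels = default_vessels(644L),
                                   name = "vessels_speckle"),
    full_volume = phantom_spec(n_frames = 51L,
                               vessels = default_vessels(644L),
                               name = "full_volume")
  )
}

#' Retrieve a named phantom fixture
#' @param name One of the names of [default_specs()].
#' @param seed Optional seed override.
#' @return A [phantom_spec()].
#' @export
phantom_fixture <- function(name, seed = NULL) {
  specs <- default_specs()
  if (!name %in% names(specs))
    stop("unknown phantom fixture '", name, "'; available: ",
         paste(names(specs), collapse = ", "), call. = FALSE)
  sp <- specs[[name]]
  if (!is.null(seed)) sp$seed <- as.integer(seed)
  sp
}
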