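read_image_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L)                 # RGB(A): average color channels
    img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
  img
}

numeric_file_order <- function(files) {
  base <- basename(files)
  num <- suppressWarnings(as.numeric(
    vapply(base, function(f) {
      m <- regmatches(f, regexpr("[0-9]+", f))
      if (length(m)) m else NA_character_
    }, character(1))))
  num[is.na(num)] <- Inf
  order(num, base)
}

parse_metadata <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(list(axial_res_um = meta$axial_res_um,
                lateral_res_um = meta$lateral_res_um,
                frame_spacing_um = meta$frame_spacing_um,
                source_id = meta$source_id %||% ""))
  }
  if (ext == "xml") {
    # minimal acquisition-geometry dialect: ScaleZ / ScaleX / Distance
    # elements in millimeters (the device export convention)
    doc <- xml2::read_xml(path)
    grab <- function(tag) {
      node <- xml2::xml_find_first(doc, paste0("//*[local-name()='", tag, "']"))
      if (inherits(node, "xml_missing")) NULL
      else as.numeric(xml2::xml_text(node)) * 1000
    }
    return(list(axial_res_um = grab("ScaleZ"),
                lateral_res_um = grab("ScaleX"),
                frame_spacing_um = grab("Distance"),
                source_id = ""))
  }
  stop("unsupported metadata format: ", ext, call. = FALSE)
}

#' Load an OCT volume from an image stack
#'
#' Reads a directory of grayscale B-scan images (PNG/JPEG/TIFF), ordered by
#' the first numeric component of their filenames (lexicographic tie-break),
#' rescales intensities to `[0, 1]` (8- and 16-bit inputs map to the same
#' scale; intensities are treated as linear) and attaches the acquisition
#' geometry from a metadata sidecar — a JSON file with fields
#' `axial_res_um`, `lateral_res_um`, `frame_spacing_um` (and optionally
#' `source_id`), or an XML file carrying `ScaleZ`/`ScaleX`/`Distance`
#' elements in millimeters. Explicitly passed resolutions override the
#' sidecar.
#'
#' @param path Directory containing the B-scan images.
#' @param metadata_path Optional sidecar path; by default a single `.json` or
#'   `.xml` file in `path` is used when present.
#' @param axial_res_um,lateral_res_um,frame_spacing_um Optional explicit
#'   resolutions (microns).
#' @param source_id Optional provenance tag (default: the directory name).
#' @return An [oct_volume()].
#' @export
load_volume <- function(path, metadata_path = NULL,
                        axial_res_um = NULL, lateral_res_um = NULL,
                        frame_spacing_um = NULL, source_id = NULL) {
  if (!dir.exists(path))
    stop("input directory does not exist: ", path, call. = FALSE)
  files <- list.files(path, pattern = "\\.(png|jpe?g|tiff?)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!length(files))
    stop("no B-scan images (png/jpg/tiff) found in ", path, call. = FALSE)
  files <- files[numeric_file_order(files)]

  if (is.null(metadata_path)) {
    side <- list.files(path, pattern = "\\.(json|xml)$", ignore.case = TRUE,
                       full.names = TRUE)
    if (length(side) == 1L) metadata_path <- side
  }
  meta <- if (!is.null(metadata_path)) parse_metadata(metadata_path)
          else list(source_id = "")
  axial_res_um <- axial_res_um %||% meta$axial_res_um
  lateral_res_um <- lateral_res_um %||% meta$lateral_res_um
  frame_spacing_um <- frame_spacing_um %||% meta$frame_spacing_um
  if (is.null(axial_res_um) || is.null(lateral_res_um) ||
      is.null(frame_spacing_um))
    stop("resolutions missing: supply a metadata sidecar or explicit ",
         "axial_res_um/lateral_res_um/frame_spacing_um", call. = FALSE)

  frames <- lapply(files, read_image_gray)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent frame dimensions across the image stack",
         call. = FALSE)
  oct_volume(frames, axial_res_um, lateral_res_um, frame_spacing_um,
             source_id = source_id %||% meta$source_id %||% basename(path))
}

#' Write segmentation surfaces to CSV
#'
#' Long-format CSV with columns `boundary, frame, column, z_pixels, z_um`
#' preceded by a single JSON header line (prefixed `#`) carrying the grid
#' offsets, resolutions, axial extent and provenance. Round-trips through
#' [read_surfaces()] to better than 1e-6 px.
#'
#' @param s A [surface_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surfaces <- function(s, path) {
  header <- jsonlite::toJSON(list(
    format = "octrima3d-surfaces", version = 1L,
    column_offset = s$column_offset, frame_offset = s$frame_offset,
    axial_res_um = s$axial_res_um, lateral_res_um = s$lateral_res_um,
    frame_spacing_um = s$frame_spacing_um, n_rows = s$n_rows,
    source_id = s$source_id), auto_unbox = TRUE, digits = NA)
  df <- as.data.frame(s)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  writeLines("boundary,frame,column,z_pixels,z_um", con)
  writeLines(sprintf("%s,%d,%d,%.12g,%.12g", df$boundary, df$frame,
                     df$column, df$z_pixels, df$z_um), con)
  invisible(path)
}

#' Read segmentation surfaces from CSV
#' @param path A file written by [write_surfaces()].
#' @return A [surface_set()].
#' @export
read_surfaces <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# "))
    stop("malformed surfaces file (line 1): missing JSON header", call. = FALSE)
  meta <- tryCatch(jsonlite::fromJSON(sub("^# ", "", lines[1])),
                   error = function(e)
                     stop("malformed surfaces file (line 1): ",
                          conditionMessage(e), call. = FALSE))
  df <- tryCatch(
    read.csv(text = lines[-1], stringsAsFactors = FALSE),
    error = function(e) stop("malformed surfaces file: ",
                             conditionMessage(e), call. = FALSE))
  need <- c("boundary", "frame", "column", "z_pixels")
  if (!all(need %in% names(df)))
    stop("malformed surfaces file (line 2): expected columns ",
         paste(need, collapse = ","), call. = FALSE)
  for (col in c("frame", "column", "z_pixels"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(!is.finite(df$z_pixels) | !is.finite(df$frame) |
               !is.finite(df$column))
  if (length(bad))
    stop("malformed surfaces file (line ", bad[1] + 2L,
         "): non-numeric values", call. = FALSE)

  num <- function(x) suppressWarnings(as.numeric(x %||% NA))
  col_off <- meta$column_offset %||% 0L
  fr_off <- meta$frame_offset %||% 0L
  cols <- sort(unique(df$column)) ; frs <- sort(unique(df$frame))
  surfaces <- lapply(split(df, df$boundary), function(d) {
    m <- matrix(NA_real_, length(cols), length(frs))
    m[cbind(match(d$column, cols), match(d$frame, frs))] <- d$z_pixels
    m
  })
  surface_set(surfaces,
              column_offset = col_off, frame_offset = fr_off,
              axial_res_um = num(meta$axial_res_um),
              lateral_res_um = num(meta$lateral_res_um),
              frame_spacing_um = num(meta$frame_spacing_um),
              n_rows = as.integer(num(meta$n_rows)),
              source_id = meta$source_id %||% "",
              check = FALSE)
}

#' Write / read a vessel-shadow map
#'
#' Plain CSV with columns `frame, column, flag` (flag 1 = A-scan shadowed by
#' a retinal vessel).
#'
#' @param mask Logical matrix (frames x columns).
#' @param path File path.
#' @return `path` (write) or the logical matrix (read).
#' @export
write_vessel_map <- function(mask, path) {
  df <- data.frame(frame = rep(seq_len(nrow(mask)), times = ncol(mask)),
                   column = rep(seq_len(ncol(mask)), each = nrow(mask)),
                   flag = as.integer(as.vector(mask)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vessel_map
#' @export
read_vessel_map <- function(path) {
  df <- read.csv(path)
  m <- matrix(FALSE, max(df$frame), max(df$column))
  m[cbind(df$frame, df$column)] <- df$flag != 0
  m
}

#' Save a gradient image as a PNG (debug aid)
#' @param g A `gradient_image` or matrix in `[0, 1]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_gradient_png <- function(g, path) {
  png::writePNG(as_grid(g), path)
  invisible(path)
}

#' Write a phantom volume as an image-stack directory
#'
#' Renders a [generate_phantom()] result to PNG frames plus a JSON metadata
#' sidecar, a ground-truth surfaces CSV and a vessel-map CSV, directly
#' consumable by [load_volume()] / [segment_volume()] / [compare_surfaces()].
#'
#' @param ph Result of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_dir <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vol <- ph$volume
  width <- nchar(as.character(vol$n_frames))
  for (i in seq_len(vol$n_frames))
    png::writePNG(vol$frames[[i]],
                  file.path(dir, sprintf(paste0("frame%0", width, "d.png"), i)))
  jsonlite::write_json(list(axial_res_um = vol$axial_res_um,
                            lateral_res_um = vol$lateral_res_um,
                            frame_spacing_um = vol$frame_spacing_um,
                            source_id = vol$source_id),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE,
                       digits = NA)
  write_surfaces(ph$truth, file.path(dir, "truth_surfaces.csv"))
  write_vessel_map(ph$vessel_mask, file.path(dir, "vessel_map.csv"))
  invisible(dir)
}
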