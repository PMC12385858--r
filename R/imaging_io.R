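#' Read an 8-bit grayscale image
#'
#' Reads a lossless 8-bit grayscale raster (TIFF or PNG) into an integer
#' matrix with values in \[0, 255\]. Multi-channel files whose channels are
#' identical (optionally with a fully opaque alpha channel) are collapsed to
#' a single channel; bit depths other than 8 are rejected, as are images
#' smaller than 8x8 pixels.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return An integer matrix (rows x columns) of gray levels in \[0, 255\].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (!is.null(bits) && any(bits != 8L)) {
      stop("unsupported bit depth: ", paste(unique(bits), collapse = "/"),
           " (only 8-bit images are supported)", call. = FALSE)
    }
    vals <- x
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L) {
      stop("unsupported bit depth: ", info$bit.depth,
           " (only 8-bit images are supported)", call. = FALSE)
    }
    vals <- round(unclass(x) * 255)
  } else {
    stop("unsupported image format: .", ext, " (use TIFF or PNG)", call. = FALSE)
  }
  vals <- collapse_channels(vals, path)
  if (max(vals) > 255 || min(vals) < 0) {
    stop("unsupported bit depth: values outside [0, 255] in ", path,
         call. = FALSE)
  }
  img <- matrix(as.integer(round(vals)), nrow = nrow(vals), ncol = ncol(vals))
  validate_raw_image(img)
  img
}

# collapse HxWxC arrays with identical gray channels; alpha must be opaque
collapse_channels <- function(x, path) {
  if (length(dim(x)) == 2L) return(x)
  if (length(dim(x)) != 3L) {
    stop("cannot interpret image with ", length(dim(x)), " dimensions: ",
         path, call. = FALSE)
  }
  nch <- dim(x)[3]
  if (nch == 4L || nch == 2L) { # trailing alpha channel
    alpha <- x[, , nch]
    if (any(alpha != max(alpha))) {
      stop("non-grayscale multi-channel image (non-constant alpha): ", path,
           call. = FALSE)
    }
    x <- x[, , -nch, drop = FALSE]
    nch <- dim(x)[3]
  }
  if (nch == 1L) return(x[, , 1])
  for (ch in 2:nch) {
    if (any(x[, , ch] != x[, , 1])) {
      stop("non-grayscale multi-channel image (channels differ): ", path,
           call. = FALSE)
    }
  }
  x[, , 1]
}

validate_raw_image <- function(img) {
  if (!is.matrix(img)) stop("image must be a matrix", call. = FALSE)
  if (nrow(img) < 8L || ncol(img) < 8L) {
    stop("image too small: ", nrow(img), "x", ncol(img),
         " (minimum extent is 8x8)", call. = FALSE)
  }
  if (anyNA(img) || min(img) < 0L || max(img) > 255L) {
    stop("image values must be integers in [0, 255]", call. = FALSE)
  }
  invisible(img)
}

#' Write an 8-bit grayscale image as PNG
#'
#' Lossless round-trip companion of [read_gray_image()]:
#' `read_gray_image(write_gray_image(img, f))` returns `img` unchanged.
#'
#' @param image Integer matrix of gray levels in \[0, 255\].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  storage.mode(image) <- "integer"
  validate_raw_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Rectangular region of interest
#'
#' 0-based, half-open pixel bounds `[row_start, row_stop) x
#' [col_start, col_stop)`, the convention used throughout the package.
#'
#' @param row_start,col_start First row/column included (0-based).
#' @param row_stop,col_stop First row/column excluded.
#' @return An object of class `"roi"`.
#' @export
roi <- function(row_start, col_start, row_stop, col_stop) {
  r <- list(row_start = as.integer(row_start), col_start = as.integer(col_start),
            row_stop = as.integer(row_stop), col_stop = as.integer(col_stop))
  if (r$row_start < 0L || r$col_start < 0L ||
      r$row_start >= r$row_stop || r$col_start >= r$col_stop) {
    stop("invalid ROI: require 0 <= start < stop on both axes", call. = FALSE)
  }
  structure(r, class = "roi")
}

#' Crop an image to a region of interest
#'
#' @param image Integer gray-level matrix.
#' @param region An [roi()] within the image bounds.
#' @return The cropped matrix, values copied unchanged.
#' @export
crop_image <- function(image, region) {
  stopifnot(inherits(region, "roi"))
  if (region$row_stop > nrow(image) || region$col_stop > ncol(image)) {
    stop("ROI out of bounds: stops (", region$row_stop, ",", region$col_stop,
         ") exceed image extent (", nrow(image), ",", ncol(image), ")",
         call. = FALSE)
  }
  image[(region$row_start + 1L):region$row_stop,
        (region$col_start + 1L):region$col_stop, drop = FALSE]
}

VALID_GROUPS <- c("endovascular", "surgical")
TIMEPOINTS <- c("pre", "post")
PROJECTIONS <- c("AP", "LAT")

#' Load a cohort manifest
#'
#' Reads a YAML manifest mapping patients to treatment group and to matched
#' pre/post frame files per projection, and validates the pairing contract:
#' every listed file exists, every `(timepoint, projection)` list that is
#' present is non-empty, and pre and post frames have identical pixel
#' dimensions within each projection.
#'
#' The expected YAML layout is
#' ```
#' patients:
#'   - patient_id: P01
#'     group: endovascular
#'     frames:
#'       pre:  {AP: [p01_pre_AP_1.png], LAT: [...]}
#'       post: {AP: [p01_post_AP_1.png], LAT: [...]}
#' ```
#' with paths relative to the manifest file.
#'
#' @param path Path to `manifest.yaml`.
#' @return A list of patient records (class `"patient_record"`), each with
#'   `patient_id`, `group`, and `frames[[timepoint]][[projection]]` character
#'   vectors of absolute file paths.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$patients) || !length(doc$patients)) {
    stop("manifest has no 'patients' entries", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  lapply(doc$patients, function(p) {
    if (is.null(p$patient_id) || is.null(p$group) || is.null(p$frames)) {
      stop("manifest entry missing patient_id, group or frames", call. = FALSE)
    }
    if (!p$group %in% VALID_GROUPS) {
      stop("unknown group label '", p$group, "' for patient ", p$patient_id,
           " (allowed: ", paste(VALID_GROUPS, collapse = ", "), ")",
           call. = FALSE)
    }
    frames <- list()
    for (tp in TIMEPOINTS) {
      if (is.null(p$frames[[tp]])) {
        stop("patient ", p$patient_id, " has no '", tp, "' frames",
             call. = FALSE)
      }
      for (proj in intersect(names(p$frames[[tp]]), PROJECTIONS)) {
        files <- unlist(p$frames[[tp]][[proj]])
        if (!length(files)) {
          stop("patient ", p$patient_id, " has an empty ", tp, "/", proj,
               " frame list", call. = FALSE)
        }
        files <- ifelse(grepl("^/", files), files, file.path(base, files))
        missing <- files[!file.exists(files)]
        if (length(missing)) {
          stop("missing frame file(s) for patient ", p$patient_id, ": ",
               paste(missing, collapse = ", "), call. = FALSE)
        }
        frames[[tp]][[proj]] <- files
      }
    }
    # pairing contract: pre/post dimensions identical per projection.
    # Files that fail to decode are skipped here; the pipeline reports them
    # as per-frame failures instead of aborting the whole cohort.
    for (proj in intersect(names(frames$pre), names(frames$post))) {
      dim_of <- function(f) tryCatch(dim(read_gray_image(f)),
                                     error = function(e) NULL)
      dims <- Filter(Negate(is.null),
                     lapply(c(frames$pre[[proj]], frames$post[[proj]]), dim_of))
      if (length(dims) > 1) {
        ref <- dims[[1]]
        for (d in dims) {
          if (!identical(d, ref)) {
            stop("dimension mismatch for patient ", p$patient_id,
                 " projection ", proj, ": ", paste(ref, collapse = "x"),
                 " vs ", paste(d, collapse = "x"), call. = FALSE)
          }
        }
      }
    }
    structure(list(patient_id = p$patient_id, group = p$group,
                   frames = frames),
              class = "patient_record")
  })
}
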