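#' Read an image stack from disk
#'
#' Reads either a multi-page TIFF or a directory of lexicographically ordered
#' single-frame images (TIFF or PNG). Frame order is page order for a
#' multi-page file and file-name order for a directory.
#'
#' @param path a multi-page TIFF file or a directory of single-frame images.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @param mode `"fluorescence"` or `"brightfield"`.
#' @param bit_depth expected bit depth; inferred from the data when `NULL`
#'   (16 if any value exceeds 255, else 8).
#' @return An [image_stack].
#' @export
read_stack <- function(path, pixel_size = 1, frame_interval = 1,
                       mode = c("fluorescence", "brightfield"),
                       bit_depth = NULL) {
  mode <- match.arg(mode)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L)
      stop("no TIFF/PNG frames found in directory: ", path)
    frames <- lapply(files, read_frame)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("tif", "tiff"))
      stop("single-file input must be a multi-page TIFF (got .", ext, ")")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, as_gray_matrix)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mismatched dimensions")
  if (is.null(bit_depth))
    bit_depth <- if (max(vapply(frames, max, numeric(1))) > 255) 16L else 8L
  image_stack(frames, bit_depth = bit_depth, pixel_size = pixel_size,
              frame_interval = frame_interval, mode = mode)
}

# one single-frame image file -> integer-valued intensity matrix
read_frame <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(file, as.is = TRUE)
    as_gray_matrix(img)
  } else if (ext == "png") {
    img <- png::readPNG(file)
    # readPNG rescales to [0,1]; recover the stored integer grid (values are
    # exact multiples of 1/255 for 8-bit and 1/65535 for 16-bit files)
    m <- as_gray_matrix(img)
    v8 <- m * 255
    bits <- if (max(abs(v8 - round(v8))) < 1e-9) 8 else 16
    round(m * (2^bits - 1))
  } else {
    stop("unsupported image format: .", ext)
  }
}

as_gray_matrix <- function(img) {
  if (length(dim(img)) == 3L) {
    # collapse RGB(A) to gray by channel mean (alpha dropped)
    nc <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  m <- as.matrix(img)
  storage.mode(m) <- "double"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image stack to disk
#'
#' Writes a multi-page TIFF (when `path` ends in `.tif`/`.tiff`) or a
#' directory of numbered PNG frames. The written file reproduces the stack
#' bit-exactly under [read_stack].
#'
#' @param stack an [image_stack].
#' @param path output file (`.tif`) or directory (PNG sequence).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  maxv <- max_intensity(stack)
  bits <- stack$bit_depth
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(lapply(stack$frames, function(f) f / maxv), path,
                    bits.per.sample = bits)
  } else if (ext == "") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    nd <- max(4L, nchar(as.character(n_frames(stack) - 1L)))
    for (i in seq_len(n_frames(stack))) {
      fn <- file.path(path, sprintf(paste0("frame%0", nd, "d.png"), i - 1L))
      png::writePNG(stack$frames[[i]] / maxv, fn)
    }
  } else {
    stop("unsupported output format: .", ext)
  }
  invisible(path)
}

#' Write a calibrated track table
#'
#' Writes one CSV row per tracked point with columns `track_id, frame, x_px,
#' y_px, x_um, y_um`, where the micrometre columns are the pixel columns
#' multiplied by `pixel_size`. Rows are sorted by `(track_id, frame)`. This is
#' the plain-text analogue of an MTrackJ point export: calibrated x and y per
#' point, one trajectory per track id.
#'
#' @param tracks a track table as returned by [link_tracks()]: a data frame
#'   with columns `track_id, frame, x, y` (pixel coordinates, 0-based frames).
#' @param pixel_size micrometres per pixel.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, pixel_size, path) {
  tracks <- as.data.frame(tracks)
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(tracks)))
    stop("tracks must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(track_id = tracks$track_id, frame = tracks$frame,
                    x_px = tracks$x, y_px = tracks$y,
                    x_um = tracks$x * pixel_size,
                    y_um = tracks$y * pixel_size)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a track table written by [write_tracks()]
#' @param path CSV path.
#' @return data frame with columns `track_id, frame, x, y` (pixels).
#' @export
read_tracks <- function(path) {
  d <- read.csv(path)
  data.frame(track_id = d$track_id, frame = d$frame, x = d$x_px, y = d$y_px)
}

#' Write / read a per-column CFL thickness profile
#'
#' @param profile a [cfl_profile] data frame (`column, thickness_px,
#'   thickness_um`; missing columns are `NA`).
#' @param path CSV path.
#' @return `path` (write) / the profile data frame (read).
#' @export
write_cfl_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cfl_profile
#' @export
read_cfl_profile <- function(path) {
  d <- read.csv(path)
  structure(d, class = c("cfl_profile", "data.frame"))
}
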