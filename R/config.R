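#' Run configuration
#'
#' Bundles the tunable parameters of the tracking and CFL pipelines with
#' validation. All values have working defaults; any subset can be
#' overridden. A configuration can also be read from a flat `key = value`
#' text file ([read_config()]) whose keys mirror these field names.
#'
#' @param median_kernel odd integer >= 1.
#' @param threshold `"auto"` or a numeric manual override level.
#' @param area_min,area_max inclusive blob area bounds, pixels.
#' @param link_max_displacement linking gate, pixels.
#' @param min_track_length minimum track length, frames (>= 1).
#' @param connectivity 4 or 8.
#' @param roi optional [rect] (or `"x0,y0,width,height"` string).
#' @param pad median border padding, `"replicate"` or `"zero"`.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds per frame.
#' @param mode `"fluorescence"` or `"brightfield"`.
#' @param random_seed integer seed for stochastic steps.
#' @return a validated `run_config` list.
#' @export
run_config <- function(median_kernel = 5L, threshold = "auto",
                       area_min = 5, area_max = Inf,
                       link_max_displacement = 10, min_track_length = 10L,
                       connectivity = 8L, roi = NULL,
                       pad = "replicate", pixel_size = 1,
                       frame_interval = 1, mode = "fluorescence",
                       random_seed = 1L) {
  median_kernel <- as.integer(median_kernel)
  if (median_kernel < 1L || median_kernel %% 2L == 0L)
    stop("median_kernel must be an odd integer >= 1")
  if (area_min > area_max) stop("area_min must be <= area_max")
  if (min_track_length < 1L) stop("min_track_length must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (!pad %in% c("replicate", "zero")) stop("pad must be replicate or zero")
  if (!mode %in% c("fluorescence", "brightfield")) stop("unknown mode")
  if (is.character(roi)) roi <- parse_roi(roi)
  structure(list(median_kernel = median_kernel, threshold = threshold,
                 area_min = area_min, area_max = area_max,
                 link_max_displacement = link_max_displacement,
                 min_track_length = as.integer(min_track_length),
                 connectivity = as.integer(connectivity), roi = roi,
                 pad = pad, pixel_size = pixel_size,
                 frame_interval = frame_interval, mode = mode,
                 random_seed = as.integer(random_seed)),
            class = "run_config")
}

parse_roi <- function(s) {
  v <- as.numeric(strsplit(s, ",")[[1]])
  if (length(v) != 4L || anyNA(v))
    stop("roi must be 'x0,y0,width,height'")
  rect(v[1], v[2], v[3], v[4])
}

#' Read a configuration from a flat key = value file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment;
#' unknown keys are rejected. Numeric-looking values are coerced.
#'
#' @param path text file path.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (!is.na(num) && key != "roi") num else val
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(kv), known)
  if (length(bad) > 0L)
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, kv)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    if (is.null(v)) v <- "NULL"
    if (inherits(v, "rect"))
      v <- sprintf("%d,%d,%d,%d", v$x0, v$y0, v$width, v$height)
    cat(sprintf("  %-22s %s\n", k, paste(format(v), collapse = " ")))
  }
  invisible(x)
}
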