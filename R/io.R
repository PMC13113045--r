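#' Read a fluorescence movie from a multi-page TIFF
#'
#' Pages become frames in page order. Physical units are never guessed: the
#' frame interval and pixel size must come either from the arguments or from
#' a JSON sidecar (`<path>.json` by default) with fields `dt_ms` and
#' `pixel_um`. RGB pages are rejected; convert to grayscale first.
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @param frame_interval,pixel_size Physical scales; override the sidecar.
#' @param sidecar Path to the JSON metadata sidecar; `NULL` looks for
#'   `<path>.json`.
#' @return A [frame_stack].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, frame_interval = NULL, pixel_size = NULL,
                       sidecar = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sidecar)) sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  if (is.null(frame_interval)) frame_interval <- meta$dt_ms
  if (is.null(pixel_size)) pixel_size <- meta$pixel_um
  if (is.null(frame_interval))
    stop("frame interval (dt_ms) missing: supply `frame_interval` or a sidecar; ",
         "it is never defaulted", call. = FALSE)
  if (is.null(pixel_size))
    stop("pixel size (pixel_um) missing: supply `pixel_size` or a sidecar",
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop("RGB/multi-channel TIFF pages are not supported; ",
         "convert the movie to single-channel grayscale", call. = FALSE)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  frame_stack(frames, as.numeric(frame_interval), as.numeric(pixel_size))
}

#' Write a fluorescence movie as a multi-page 16-bit TIFF
#'
#' Intensities are stored as 16-bit unsigned integers (values clamped to
#' `[0, 65535]` and rounded), one page per frame, so integer-valued stacks
#' round-trip bit-identically. A JSON sidecar `<path>.json` records
#' `dt_ms`, `pixel_um` and any extra metadata (e.g. the generator seed).
#'
#' @param stack A [frame_stack].
#' @param path Output TIFF path.
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- n_frames(stack)
  pages <- vector("list", n)
  for (i in seq_len(n)) {
    m <- round(stack$frames[i, , ])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    pages[[i]] <- m / 65535      # writeTIFF expects [0,1]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- c(list(dt_ms = stack$frame_interval, pixel_um = stack$pixel_size),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read / write a binary mask as PNG
#'
#' @param path PNG path.
#' @return `read_mask()`: a logical matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' @rdname read_mask
#' @param mask Logical or 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read / write tidy trace tables
#'
#' Traces and sweeps travel as tidy CSV with columns `id`, `time_ms`,
#' `value` (UTF-8, header row, "." decimal).
#'
#' @param path CSV path.
#' @return A tibble with columns `id`, `time_ms`, `value`.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time_ms", "value")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns id, time_ms, value", call. = FALSE)
  tibble::as_tibble(df)
}

#' @rdname read_traces
#' @param traces Data frame with columns `id`, `time_ms`, `value`.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces[, c("id", "time_ms", "value")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write an activation map to disk
#'
#' The time matrix goes to `<path>.csv` (ms, empty cells for pixels that
#' never activated) and the parameters (`theta`, `beat_index`, `dt_ms`,
#' `pixel_um`, frame span) to `<path>.json`.
#'
#' @param map An [activation_map] result.
#' @param path Output path prefix (no extension).
#' @export
write_activation_map <- function(map, path) {
  stopifnot(inherits(map, "activation_map"))
  utils::write.table(map$times_ms, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, na = "")
  fin <- is.finite(map$frames)
  meta <- list(theta = map$theta, beat_index = map$beat_index,
               dt_ms = map$frame_interval, pixel_um = map$pixel_size,
               frame_span = if (any(fin))
                 diff(range(map$frames[fin])) + 1 else 0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
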