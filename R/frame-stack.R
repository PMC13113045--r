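#' Fluorescence movie container
#'
#' A `frame_stack` holds a time-lapse grayscale fluorescence recording as a
#' 3-D array ordered `(time, y, x)`, together with the two physical scales
#' every downstream operation needs: the frame acquisition interval
#' (milliseconds) and the pixel size (micrometres). Readers refuse to guess
#' either scale; they must be supplied explicitly or via a metadata sidecar.
#'
#' Conventions: frame index is 1-based in R but activation times are reported
#' relative to the earliest event (so the first activated pixel is at 0 ms);
#' pixel coordinates are `(row, col)` with row 1 at the top.
#'
#' @param frames Numeric 3-D array `(time, y, x)` of non-negative intensities.
#' @param frame_interval Frame acquisition interval in ms (> 0).
#' @param pixel_size Pixel edge length in um (> 0).
#' @return An object of class `frame_stack`.
#' @examples
#' stk <- frame_stack(array(100, dim = c(3, 4, 4)), frame_interval = 110,
#'                    pixel_size = 10)
#' n_frames(stk)
#' @export
frame_stack <- function(frames, frame_interval, pixel_size) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array ordered (time, y, x)", call. = FALSE)
  if (any(!is.finite(frames)) || any(frames < 0))
    stop("`frames` must be finite and non-negative", call. = FALSE)
  check_positive_scalar(frame_interval, "frame_interval")
  check_positive_scalar(pixel_size, "pixel_size")
  structure(
    list(frames = frames,
         frame_interval = as.numeric(frame_interval),
         pixel_size = as.numeric(pixel_size)),
    class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px | dt = %g ms | pixel = %g um | %.1f s\n",
    d[1], d[2], d[3], x$frame_interval, x$pixel_size,
    d[1] * x$frame_interval / 1000))
  invisible(x)
}

#' @rdname frame_stack
#' @param x A `frame_stack`.
#' @export
n_frames <- function(x) dim(x$frames)[1]

#' Labelled region-of-interest set
#'
#' A `roi_set` pairs an integer label image (same `(y, x)` shape as the
#' movie frames) with an optional label-to-group-name map, e.g. to mark
#' which regions are MSC-derived cells and which belong to the surrounding
#' monolayer in a co-culture.
#'
#' @param labels Integer matrix; 0 = background, positive integers label rois.
#' @param groups Optional named character vector mapping label (as name or
#'   in order of sorted unique labels) to a group name.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, groups = NULL) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  lab <- as.integer(round(labels))
  if (any(lab < 0L, na.rm = TRUE)) stop("labels must be >= 0", call. = FALSE)
  labels <- matrix(lab, nrow(labels), ncol(labels))
  ids <- sort(unique(labels[labels > 0L]))
  if (!is.null(groups)) {
    if (is.null(names(groups))) {
      if (length(groups) != length(ids))
        stop("unnamed `groups` must have one entry per label", call. = FALSE)
      names(groups) <- as.character(ids)
    }
    miss <- setdiff(names(groups), as.character(ids))
    if (length(miss))
      stop("groups name labels with no pixels: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  structure(list(labels = labels, groups = groups), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  ids <- sort(unique(x$labels[x$labels > 0L]))
  cat(sprintf("<roi_set> %d x %d px, %d roi(s)\n",
              nrow(x$labels), ncol(x$labels), length(ids)))
  invisible(x)
}

#' @rdname roi_set
#' @param x A `roi_set`.
#' @param label A label present in `x`.
#' @return `roi_mask()`: a logical matrix selecting that roi's pixels.
#' @export
roi_mask <- function(x, label) {
  stopifnot(inherits(x, "roi_set"))
  m <- x$labels == as.integer(label)
  if (!any(m)) stop("roi label ", label, " has no pixels", call. = FALSE)
  m
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("`", name, "` must be a single positive finite number", call. = FALSE)
  invisible(x)
}
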