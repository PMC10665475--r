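#' Rectangular region of interest in a video frame
#'
#' Coordinates are 0-based: `x` counts pixels rightward from the left
#' edge, `y` downward from the top; the ROI spans `w` columns and `h`
#' rows. The defaults in [roi_belt()] and [roi_chest()] are the fixed
#' in-cabin positions of the seat-belt and chest rectangles for a
#' 1280x720 camera behind the windscreen.
#'
#' @param x,y Top-left corner (0-based pixels).
#' @param w,h Width and height in pixels, >= 1.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x, y, w, h) {
  x <- as.integer(x); y <- as.integer(y); w <- as.integer(w); h <- as.integer(h)
  if (w < 1L || h < 1L) stop("roi_spec: w and h must be >= 1")
  if (x < 0L || y < 0L) stop("roi_spec: x and y must be >= 0")
  structure(list(x = x, y = y, w = w, h = h), class = "roi_spec")
}

#' @rdname roi_spec
#' @export
roi_belt <- function() roi_spec(701, 550, 10, 190)

#' @rdname roi_spec
#' @export
roi_chest <- function() roi_spec(401, 550, 400, 190)

#' Ordered sequence of video frames
#'
#' @param frames List of frames; each frame is a numeric `h x w x 3` array
#'   (R, G, B planes), all with identical resolution.
#' @param fps Frames per second, > 0.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, fps) {
  if (!is.list(frames) || length(frames) < 1L) {
    stop("frame_sequence: need at least one frame")
  }
  dims <- lapply(frames, dim)
  if (any(vapply(dims, length, integer(1)) != 3L) ||
      any(vapply(dims, function(d) d[3] < 3L, logical(1)))) {
    stop("frame_sequence: frames must be h x w x 3 arrays")
  }
  if (length(unique(vapply(dims, function(d) paste(d[1:2], collapse = "x"),
                           character(1)))) != 1L) {
    stop("frame_sequence: frames differ in resolution")
  }
  if (!is.numeric(fps) || fps <= 0) stop("frame_sequence: fps must be > 0")
  structure(list(frames = frames, fps = fps), class = "frame_sequence")
}

#' Read a directory of PNG frames as a frame sequence
#'
#' Files are taken in lexicographic order; requires the `png` package.
#'
#' @param dir Directory of `.png` files.
#' @param fps Frame rate to attach.
#' @return A [frame_sequence].
#' @export
read_frames <- function(dir, fps = 10) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("read_frames: the 'png' package is required to read PNG frames")
  }
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("read_frames: no .png files in ", dir)
  frames <- lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    a[, , 1:3, drop = FALSE]
  })
  frame_sequence(frames, fps)
}

check_roi_in_frame <- function(frame, roi) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  if (roi$x + roi$w > w || roi$y + roi$h > h) {
    stop(sprintf(
      "ROI (x=%d, y=%d, w=%d, h=%d) exceeds the %dx%d frame; largest fitting ROI at this corner is w=%d, h=%d",
      roi$x, roi$y, roi$w, roi$h, w, h,
      max(0L, w - roi$x), max(0L, h - roi$y)))
  }
}

#' Mean green value over an ROI
#'
#' The scalar respiration sample for one frame: the arithmetic mean of the
#' green-channel values of the `w * h` pixels cut out by the ROI
#' (sum of all values divided by the pixel count).
#'
#' @param frame Numeric `h x w x 3` array.
#' @param roi An [roi_spec] lying fully inside the frame.
#' @return Scalar mean green value.
#' @export
roi_mean_green <- function(frame, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  check_roi_in_frame(frame, roi)
  rows <- (roi$y + 1L):(roi$y + roi$h)
  cols <- (roi$x + 1L):(roi$x + roi$w)
  mean(frame[rows, cols, 2L])
}

#' Convert a frame sequence to a respiration trace
#'
#' One sample per frame — the ROI mean green value — at the sequence's
#' frame rate. Belt or chest movement with breathing shifts which pixels
#' the ROI sees, so this trace oscillates with respiration.
#'
#' @param seq A [frame_sequence].
#' @param roi An [roi_spec].
#' @param name Name of the output trace.
#' @return A [channel_trace] with `fs = fps`.
#' @export
frames_to_trace <- function(seq, roi, name = "video_roi") {
  stopifnot(inherits(seq, "frame_sequence"))
  vals <- vapply(seq$frames, roi_mean_green, numeric(1), roi = roi)
  channel_trace(name, vals, seq$fps)
}

#' Verify and adjust an ROI position against the first frame
#'
#' The nominal ROI is expected to sit over a high-contrast pattern (the
#' chessboard band on the seat belt). The integer shift `(dx, dy)` within
#' `search_radius` that maximizes the intensity variance (local contrast)
#' inside the shifted ROI on the first frame is applied; if even the best
#' shift leaves the contrast below `min_contrast`, the original ROI is
#' returned with a warning.
#'
#' @param seq A [frame_sequence].
#' @param roi Nominal [roi_spec].
#' @param search_radius Maximum |shift| in pixels along each axis.
#' @param min_contrast Minimum acceptable intensity variance.
#' @return The adjusted [roi_spec], with the chosen shift attached as
#'   attribute `"shift"` (`c(dx, dy)`).
#' @export
verify_roi <- function(seq, roi, search_radius = 5L, min_contrast = 1e-6) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(roi, "roi_spec"))
  frame <- seq$frames[[1L]]
  gray <- (frame[, , 1L] + frame[, , 2L] + frame[, , 3L]) / 3
  h <- dim(gray)[1]; w <- dim(gray)[2]
  best <- c(0L, 0L); best_var <- -Inf
  for (dy in -search_radius:search_radius) {
    for (dx in -search_radius:search_radius) {
      x0 <- roi$x + dx; y0 <- roi$y + dy
      if (x0 < 0L || y0 < 0L || x0 + roi$w > w || y0 + roi$h > h) next
      v <- stats::var(as.vector(gray[(y0 + 1L):(y0 + roi$h),
                                     (x0 + 1L):(x0 + roi$w)]))
      better <- v > best_var + 1e-15 ||
        (abs(v - best_var) <= 1e-15 &&
           sum(c(dx, dy)^2) < sum(best^2)) # prefer the smaller shift on ties
      if (better) { best_var <- v; best <- c(dx, dy) }
    }
  }
  if (!is.finite(best_var) || best_var < min_contrast) {
    rf_log("verify_roi: contrast below threshold; keeping nominal ROI",
           force = TRUE)
    out <- roi
    attr(out, "shift") <- c(0L, 0L)
    return(out)
  }
  out <- roi_spec(roi$x + best[1L], roi$y + best[2L], roi$w, roi$h)
  attr(out, "shift") <- best
  out
}
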