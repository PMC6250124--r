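# TimeLapseStack container: a calibrated multi-channel time-lapse held as a
# 5-D array in canonical (t, z, c, y, x) order.

#' Construct a calibrated time-lapse stack
#'
#' @param data numeric array in canonical `(t, z, c, y, x)` order. Arrays of
#'   fewer dimensions are promoted by inserting singleton axes according to
#'   `axes` (e.g. `"TYX"` for a single-channel 2-D movie).
#' @param pixel_size pixel size in micrometres.
#' @param frame_interval frame interval in seconds.
#' @param channels character vector of channel labels (e.g. `"tracer"`).
#' @param axes axis order of `data` as a string over `T`, `Z`, `C`, `Y`, `X`;
#'   default assumes canonical order for 5-D input, `"TYX"` for 3-D,
#'   `"YX"` for 2-D.
#' @return an object of class `papt_stack`.
#' @export
papt_stack <- function(data, pixel_size, frame_interval,
                       channels = "tracer", axes = NULL) {
  stopifnot(is.numeric(data), is.finite(pixel_size), pixel_size > 0,
            is.finite(frame_interval), frame_interval > 0)
  d <- dim(data)
  if (is.null(axes)) {
    axes <- switch(as.character(length(d)),
                   "2" = "YX", "3" = "TYX", "4" = "TCYX", "5" = "TZCYX",
                   stop("cannot infer axes for a ", length(d), "-D array"))
  }
  data <- canonicalize_axes(data, axes)
  if (dim(data)[3] != length(channels)) {
    channels <- paste0("ch", seq_len(dim(data)[3]))
  }
  structure(list(
    data = data,
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    channels = channels,
    time = (seq_len(dim(data)[1]) - 1) * frame_interval
  ), class = "papt_stack")
}

# Permute/promote an array declared with `axes` into (t, z, c, y, x).
canonicalize_axes <- function(data, axes) {
  ax <- strsplit(toupper(axes), "")[[1]]
  if (length(ax) != length(dim(data))) {
    stop("axes string '", axes, "' does not match a ", length(dim(data)),
         "-D array")
  }
  canon <- c("T", "Z", "C", "Y", "X")
  if (anyDuplicated(ax) || !all(ax %in% canon)) {
    stop("axes must be distinct letters among T, Z, C, Y, X; got '", axes, "'")
  }
  if (!all(c("Y", "X") %in% ax)) stop("axes must contain Y and X")
  # insert missing singleton axes at the end, then permute
  missing <- setdiff(canon, ax)
  dim(data) <- c(dim(data), rep(1L, length(missing)))
  ax <- c(ax, missing)
  aperm(data, match(canon, ax))
}

#' @export
print.papt_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "papt_stack: %d frame(s) x %d z x %d channel(s) x %d x %d px\n",
    d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  pixel %.3g um, interval %.3g s, channels: %s\n",
              x$pixel_size, x$frame_interval,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Extract one spatial frame from a stack
#'
#' @param stack a `papt_stack`.
#' @param t,z,c 1-based frame, slice and channel indices.
#' @return numeric matrix `[y, x]`.
#' @export
get_frame <- function(stack, t, z = 1L, c = 1L) {
  stopifnot(inherits(stack, "papt_stack"))
  stack$data[t, z, c, , ]
}

#' Number of frames in a stack
#' @param stack a `papt_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[1]

#' Normalise a stack to its first frame, pixel by pixel
#'
#' Divides every frame element-wise by the first frame plus a small guard
#' offset, the standard visualisation/normalisation for perifusion wash-in
#' movies. Frame 1 of the output is identically 1.
#'
#' @param stack a `papt_stack`.
#' @param offset additive guard against division by zero (same intensity
#'   units as the data; default 0.01).
#' @return a `papt_stack` with normalised intensities.
#' @export
normalize_to_first_frame <- function(stack, offset = 0.01) {
  stopifnot(inherits(stack, "papt_stack"))
  out <- stack
  d <- dim(stack$data)
  for (z in seq_len(d[2])) for (ch in seq_len(d[3])) {
    ref <- stack$data[1, z, ch, , ] + offset
    for (t in seq_len(d[1])) {
      out$data[t, z, ch, , ] <- (stack$data[t, z, ch, , ] + offset) / ref
    }
  }
  out
}
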