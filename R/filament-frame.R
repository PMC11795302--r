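#' Filament frame: an ordered 3D point chain
#'
#' A `filament_frame` is the universal currency of the package: the positions
#' (in nm) of an ordered chain of points describing one filament at one time
#' point. Point order runs from the fixed (barbed) end to the moved (pointed)
#' end. A frame may hold raw bead positions or an already-smoothed axis curve
#' (see [monomers_to_axis()]), distinguished by the `is_axis_curve` flag.
#'
#' @param points numeric matrix with one row per point and columns x, y, z (nm).
#' @param time time of the frame in seconds.
#' @param is_axis_curve logical; `TRUE` if the points are a smoothed centerline
#'   rather than raw bead positions.
#' @return An object of class `filament_frame`.
#' @examples
#' f <- filament_frame(cbind(x = 0:9 * 2.7, y = 0, z = 0))
#' end_to_end(f)
#' @export
filament_frame <- function(points, time = 0, is_axis_curve = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 3L)
    stop("'points' must have 3 columns (x, y, z)")
  if (nrow(points) < 3L)
    stop("a filament frame needs at least 3 points")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    stop("non-finite coordinates in filament frame")
  seglen <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                          points[-nrow(points), , drop = FALSE])^2))
  if (any(seglen == 0)) {
    bad <- which(seglen == 0)[1L]
    stop("consecutive points ", bad, " and ", bad + 1L, " coincide")
  }
  colnames(points) <- c("x", "y", "z")
  structure(
    list(points = points, time = as.numeric(time),
         is_axis_curve = isTRUE(is_axis_curve)),
    class = "filament_frame"
  )
}

#' @export
print.filament_frame <- function(x, ...) {
  cat(sprintf("<filament_frame> %d points, t = %g s%s\n",
              nrow(x$points), x$time,
              if (x$is_axis_curve) " (axis curve)" else ""))
  cat(sprintf("  contour length %.2f nm, end-to-end %.2f nm\n",
              contour_length(x), end_to_end(x)))
  invisible(x)
}

#' @rdname filament_frame
#' @param x object to test or convert.
#' @export
is_filament_frame <- function(x) inherits(x, "filament_frame")

#' @rdname filament_frame
#' @export
as_filament_frame <- function(x, time = 0, is_axis_curve = FALSE) {
  if (is_filament_frame(x)) return(x)
  filament_frame(x, time = time, is_axis_curve = is_axis_curve)
}

frame_points <- function(frame) {
  if (is_filament_frame(frame)) frame$points else as.matrix(frame)
}

#' Basic chain geometry
#'
#' `end_to_end` returns the Euclidean distance between the first and last
#' point; `contour_length` the summed segment lengths; `segment_lengths` the
#' individual segment lengths.
#'
#' @param frame a [filament_frame()] or a numeric n x 3 matrix.
#' @return A numeric scalar (or vector for `segment_lengths`), in nm.
#' @export
end_to_end <- function(frame) {
  p <- frame_points(frame)
  sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
}

#' @rdname end_to_end
#' @export
contour_length <- function(frame) sum(segment_lengths(frame))

#' @rdname end_to_end
#' @export
segment_lengths <- function(frame) {
  p <- frame_points(frame)
  sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
}
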