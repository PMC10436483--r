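# axis-aligned bounding boxes are plain 2 x d matrices with rows "lo","hi"
# and columns named after the coordinate axes

#' Construct an axis-aligned bounding box
#'
#' @param lo,hi Numeric vectors of equal length (2 or 3), in nanometers;
#'   `lo` must be strictly below `hi` on every axis.
#' @return A `2 x d` numeric matrix with rows `lo`, `hi`.
#' @export
#' @examples
#' boundingBox(c(0, 0, 0), c(2000, 2000, 2000))
boundingBox <- function(lo, hi) {
  vcAssert(length(lo) == length(hi) && length(lo) %in% 2:3,
           "bounds must have 2 or 3 axes", "input")
  vcAssert(all(is.finite(lo)) && all(is.finite(hi)), "bounds must be finite",
           "input")
  vcAssert(all(hi > lo), "bounds must have positive extent on every axis",
           "input")
  b <- rbind(lo = as.numeric(lo), hi = as.numeric(hi))
  colnames(b) <- c("x", "y", "z")[seq_along(lo)]
  b
}

#' Measure (area or volume) of a bounding box
#' @param bounds A box from [boundingBox()].
#' @return Scalar measure in nm^2 (2D) or nm^3 (3D).
#' @export
boxMeasure <- function(bounds) prod(bounds["hi", ] - bounds["lo", ])

#' Expand a bounding box by a fraction of its extent per side
#' @param bounds A box from [boundingBox()].
#' @param frac Fraction of each axis extent added on both sides.
#' @return The expanded box.
#' @export
expandBox <- function(bounds, frac = 0.05) {
  ext <- bounds["hi", ] - bounds["lo", ]
  boundingBox(bounds["lo", ] - frac * ext, bounds["hi", ] + frac * ext)
}

tightBox <- function(coords) {
  lo <- apply(coords, 2L, min)
  hi <- apply(coords, 2L, max)
  # degenerate (flat) data still need a usable box for clipping
  flat <- hi <= lo
  if (any(flat)) {
    pad <- pmax(1e-6, 1e-6 * max(abs(c(lo, hi)), 1))
    lo[flat] <- lo[flat] - pad
    hi[flat] <- hi[flat] + pad
  }
  boundingBox(lo, hi)
}

checkBox <- function(bounds, dim) {
  vcAssert(is.matrix(bounds) && nrow(bounds) == 2L && ncol(bounds) == dim,
           sprintf("bounds must be a 2 x %d matrix", dim), "input")
  vcAssert(all(bounds[2L, ] > bounds[1L, ]),
           "bounds must have positive extent on every axis", "input")
  invisible(bounds)
}

boxContains <- function(outer, inner, tol = 0) {
  all(outer[1L, ] <= inner[1L, ] + tol) && all(outer[2L, ] >= inner[2L, ] - tol)
}
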