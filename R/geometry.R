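#' @include accessors.R
NULL

#' Construct a regular electrode-grid geometry
#'
#' Builds electrode positions for a regular subdural grid and places a
#' central sulcus (CS) line across it. Coordinates are in mm with x
#' increasing anterior to posterior and y increasing medial to lateral;
#' channels are numbered row-major.
#'
#' @param nRows,nCols grid dimensions.
#' @param spacingMM electrode pitch in mm (clinical grids: 5 or 10).
#' @param apAxis which grid index runs anterior->posterior: `"column"`
#'   (default: the column index maps onto x) or `"row"`.
#' @param csOffsetMM x position (mm) where the CS line crosses the grid
#'   midline; default halfway across the grid's anterior-posterior extent.
#' @param csAngleDeg tilt of the CS line away from the medial-lateral axis,
#'   in degrees (0 = perpendicular to the anterior-posterior axis).
#' @return a [GridGeometry-class] object.
#' @examples
#' geom <- gridGeometry(8, 8, spacingMM = 5)
#' geom
#' @export
gridGeometry <- function(nRows, nCols, spacingMM = 5, apAxis = "column",
                         csOffsetMM = NULL, csAngleDeg = 0) {
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  idx <- expand.grid(col = seq_len(nCols), row = seq_len(nRows))
  if (apAxis == "column") {
    x <- (idx$col - 1) * spacingMM
    y <- (idx$row - 1) * spacingMM
  } else {
    x <- (idx$row - 1) * spacingMM
    y <- (idx$col - 1) * spacingMM
  }
  pos <- cbind(x = x, y = y)
  if (is.null(csOffsetMM)) csOffsetMM <- mean(range(pos[, 1]))
  yr <- range(pos[, 2]) + c(-0.5, 0.5) * spacingMM
  yMid <- mean(range(pos[, 2]))
  slope <- tan(csAngleDeg * pi / 180)
  cs <- cbind(x = csOffsetMM + slope * (yr - yMid), y = yr)
  new("GridGeometry", nRows = nRows, nCols = nCols, spacingMM = spacingMM,
      apAxis = apAxis, positions = pos, csLine = cs)
}

## x coordinate of the CS line at lateral position y (linear interpolation
## along the polyline; constant extrapolation beyond its ends)
.csXAt <- function(csLine, y) {
  if (nrow(csLine) < 2L) return(rep(csLine[1, 1], length(y)))
  approx(csLine[, 2], csLine[, 1], xout = y, rule = 2)$y
}

#' Label channels by their side of the CS line
#'
#' Channels with x strictly smaller than the CS line's x at their lateral
#' position are anterior (motor side); the rest are posterior (sensory side).
#'
#' @param geometry a [GridGeometry-class].
#' @return character vector, "anterior"/"posterior" per channel.
#' @export
regionsFromGeometry <- function(geometry) {
  pos <- positionsMM(geometry)
  csx <- .csXAt(csLine(geometry), pos[, 2])
  ifelse(pos[, 1] < csx, "anterior", "posterior")
}

#' Row/column index of each channel on the grid
#' @keywords internal
.gridIndex <- function(geometry) {
  n <- geometry@nRows * geometry@nCols
  ch <- seq_len(n) - 1L
  data.frame(row = ch %/% geometry@nCols + 1L,
             col = ch %% geometry@nCols + 1L)
}
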