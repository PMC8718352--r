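#' @include cluster.R
NULL

## node-value matrix (ny x nx lattice) from per-channel values; excluded
## channels become NA and are filled by iterative 4-neighbour averaging so
## the interpolant stays smooth across holes
.latticeValues <- function(values, geometry, excluded = integer()) {
  pos <- positionsMM(geometry)
  sp <- geometry@spacingMM
  ix <- as.integer(round(pos[, 1] / sp)) + 1L
  iy <- as.integer(round(pos[, 2] / sp)) + 1L
  V <- matrix(NA_real_, max(iy), max(ix))
  vals <- values
  vals[excluded] <- NA_real_
  V[cbind(iy, ix)] <- vals
  ## Laplace fill of missing nodes
  for (iter in seq_len(200)) {
    nas <- which(is.na(V), arr.ind = TRUE)
    if (!nrow(nas)) break
    filled <- FALSE
    for (r in seq_len(nrow(nas))) {
      i <- nas[r, 1]; j <- nas[r, 2]
      nb <- c(if (i > 1) V[i - 1, j], if (i < nrow(V)) V[i + 1, j],
              if (j > 1) V[i, j - 1], if (j < ncol(V)) V[i, j + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb)) { V[i, j] <- mean(nb); filled <- TRUE }
    }
    if (!filled) break
  }
  V
}

#' Interpolate the grid amplitude field at arbitrary points
#'
#' Piecewise-bilinear interpolation over the regular electrode lattice:
#' exact at the electrode positions and exact for planar fields
#' `a x + b y + c`. Excluded channels are omitted (their lattice nodes are
#' filled from neighbours). Degenerate 1 x N strips (all electrodes
#' collinear) fall back to 1-D linear interpolation along the strip, with a
#' warning.
#'
#' @param values numeric per-channel values.
#' @param geometry a [GridGeometry-class].
#' @param xq,yq query coordinates in mm (recycled against each other via
#'   [cbind()] semantics; use equal lengths).
#' @param excluded integer channel indices to omit.
#' @return numeric interpolated values at the query points.
#' @export
interpolateGridField <- function(values, geometry, xq, yq,
                                 excluded = integer()) {
  pos <- positionsMM(geometry)
  sp <- geometry@spacingMM
  if (geometry@nRows == 1L || geometry@nCols == 1L) {
    warning("collinear electrodes: falling back to 1-D linear interpolation")
    along <- if (diff(range(pos[, 1])) > 0) 1L else 2L
    q <- if (along == 1L) xq else yq
    keep <- setdiff(seq_len(nrow(pos)), excluded)
    return(approx(pos[keep, along], values[keep], xout = q, rule = 2)$y)
  }
  V <- .latticeValues(values, geometry, excluded)
  nx <- ncol(V); ny <- nrow(V)
  gx <- xq / sp; gy <- yq / sp
  ix <- pmin(pmax(floor(gx), 0), nx - 2L)
  iy <- pmin(pmax(floor(gy), 0), ny - 2L)
  fx <- gx - ix; fy <- gy - iy
  i1 <- cbind(iy + 1L, ix + 1L)
  v00 <- V[i1]
  v01 <- V[cbind(iy + 1L, ix + 2L)]
  v10 <- V[cbind(iy + 2L, ix + 1L)]
  v11 <- V[cbind(iy + 2L, ix + 2L)]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v01 +
    (1 - fx) * fy * v10 + fx * fy * v11
}

#' Render one spatial heat-map frame
#'
#' Interpolates the per-channel trace values at one time point onto a dense
#' raster over the grid bounding box. The amplitude field viewed this way
#' delineates the central sulcus as the zero-crossing line between the
#' anterior and posterior amplitude lobes.
#'
#' @param trace an [SSEPTrace-class].
#' @param geometry a [GridGeometry-class].
#' @param tMs frame time (ms, inside the trace window).
#' @param resolutionMM raster step in mm.
#' @param scaleMode `"symmetric"` (limits +/- max|value|, diverging
#'   palette) or `"asymmetric"`.
#' @param limits optional fixed color limits (used for common scaling
#'   across frames).
#' @return a [HeatMapFrame-class].
#' @export
heatmapFrame <- function(trace, geometry, tMs, resolutionMM = 0.25,
                         scaleMode = c("symmetric", "asymmetric"),
                         limits = NULL) {
  scaleMode <- match.arg(scaleMode)
  tm <- timeAxis(trace)
  if (tMs < min(tm) - 1e-9 || tMs > max(tm) + 1e-9)
    stop("tMs outside the trace window")
  i <- which.min(abs(tm - tMs))
  vals <- traceValues(trace)[, i]
  excl <- excludedChannels(trace)
  pos <- positionsMM(geometry)
  xs <- seq(min(pos[, 1]), max(pos[, 1]), by = resolutionMM)
  ys <- seq(min(pos[, 2]), max(pos[, 2]), by = resolutionMM)
  grid <- expand.grid(x = xs, y = ys)
  z <- interpolateGridField(vals, geometry, grid$x, grid$y, excluded = excl)
  img <- matrix(z, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  if (is.null(limits)) {
    limits <- if (scaleMode == "symmetric")
      c(-1, 1) * max(abs(vals[setdiff(seq_along(vals), excl)]))
    else range(vals[setdiff(seq_along(vals), excl)])
  }
  new("HeatMapFrame", image = img, xMM = xs, yMM = ys, tMs = tm[i],
      limits = as.numeric(limits), scaleMode = scaleMode,
      electrodes = data.frame(x = pos[, 1], y = pos[, 2], value = vals,
                              excluded = seq_along(vals) %in% excl),
      csLine = csLine(geometry))
}

#' Animate the spatiotemporal SSEP propagation
#'
#' Frames at `10, 10 + step, ...` ms (up to but excluding 50 ms) on a
#' common symmetric color scale (the global max absolute value across all
#' channels and frame times), showing the dipole forming at the central
#' sulcus and propagating posteriorly.
#'
#' @param trace an [SSEPTrace-class].
#' @param geometry a [GridGeometry-class].
#' @param stepMs frame interval in ms.
#' @param resolutionMM raster step in mm.
#' @return list of [HeatMapFrame-class], one per frame time.
#' @export
animateTrace <- function(trace, geometry, stepMs = 2, resolutionMM = 0.25) {
  times <- seq(10, 50 - 1e-9, by = stepMs)
  tm <- timeAxis(trace)
  times <- times[times >= min(tm) & times <= max(tm)]
  keep <- setdiff(seq_len(nrow(trace)), excludedChannels(trace))
  lim <- c(-1, 1) * max(abs(traceValues(trace)[keep, ]))
  lapply(times, function(t0)
    heatmapFrame(trace, geometry, t0, resolutionMM = resolutionMM,
                 scaleMode = "symmetric", limits = lim))
}

#' Categorical cluster map over the electrode grid
#'
#' Colors each electrode by its cluster-derived region; with ground truth,
#' misclassified channels get their own category. Excluded (corrupted)
#' channels are marked separately (drawn as a gray cross by the plot
#' method). A k = 1 result yields a single-color map flagged as "no CS
#' crossing detected".
#'
#' @param result a [ClusterResult-class] (after [assignRegions()] when a
#'   region mapping is wanted).
#' @param geometry a [GridGeometry-class].
#' @param trace the clustered [SSEPTrace-class] (for the excluded set).
#' @param groundTruth optional [GroundTruth-class] for misclassification
#'   marking.
#' @return data.frame with channel, x, y, category; attribute
#'   `"no_crossing"` is TRUE for k = 1 results.
#' @export
clusterMap <- function(result, geometry, trace = NULL, groundTruth = NULL) {
  pos <- positionsMM(geometry)
  n <- nrow(pos)
  category <- rep("excluded", n)
  kept <- as.integer(names(clusterLabels(result)))
  labs <- clusterLabels(result)
  if (result@k == 2L && !identical(result@regionMap, "single")) {
    assigned <- result@regionMap[labs]
    category[kept] <- assigned
    if (!is.null(groundTruth)) {
      truth <- regionLabels(groundTruth)[kept]
      category[kept[assigned != truth]] <- "misclassified"
    }
  } else {
    category[kept] <- "single"
  }
  out <- data.frame(channel = seq_len(n), x = pos[, 1], y = pos[, 2],
                    category = category)
  attr(out, "no_crossing") <- result@k == 1L
  out
}

#' @describeIn heatmapFrame draw a frame with base graphics: interpolated
#'   field, electrode dots and the CS line overlay.
#' @param x a HeatMapFrame.
#' @param y ignored.
#' @param ... passed to [graphics::image()].
#' @export
setMethod("plot", signature(x = "HeatMapFrame", y = "missing"),
  function(x, y, ...) {
    pal <- if (x@scaleMode == "symmetric")
      grDevices::hcl.colors(65, "Blue-Red 3") else
      grDevices::hcl.colors(65, "Viridis")
    graphics::image(x@xMM, x@yMM, t(x@image), zlim = x@limits, col = pal,
                    xlab = "anterior - posterior (mm)",
                    ylab = "medial - lateral (mm)",
                    main = sprintf("SSEP field at %.1f ms", x@tMs),
                    useRaster = TRUE, ...)
    ok <- !x@electrodes$excluded
    graphics::points(x@electrodes$x[ok], x@electrodes$y[ok], pch = 21,
                     bg = "white", cex = 0.7)
    if (any(!ok))
      graphics::points(x@electrodes$x[!ok], x@electrodes$y[!ok], pch = 4,
                       col = "gray40", lwd = 2)
    if (nrow(x@csLine))
      graphics::lines(x@csLine[, 1], x@csLine[, 2], col = "gray30", lwd = 2)
    invisible(x)
  })

#' Plot a categorical cluster map
#'
#' @param map data.frame from [clusterMap()].
#' @param csLine optional CS polyline overlay (mm).
#' @export
plotClusterMap <- function(map, csLine = NULL) {
  colors <- c(anterior = "#D55E00", posterior = "#0072B2",
              misclassified = "#E69F00", single = "#009E73",
              excluded = "gray60")
  graphics::plot(map$x, map$y, type = "n",
                 xlab = "anterior - posterior (mm)",
                 ylab = "medial - lateral (mm)",
                 main = if (isTRUE(attr(map, "no_crossing")))
                   "single cluster: no CS crossing detected"
                 else "spectral clustering over the grid")
  excl <- map$category == "excluded"
  graphics::points(map$x[!excl], map$y[!excl], pch = 19, cex = 1.6,
                   col = colors[map$category[!excl]])
  graphics::points(map$x[excl], map$y[excl], pch = 4, col = "gray40", lwd = 2)
  if (!is.null(csLine) && nrow(csLine))
    graphics::lines(csLine[, 1], csLine[, 2], col = "gray30", lwd = 2)
  invisible(map)
}

#' Write heat-map frames as PNG files
#'
#' @param frames list of [HeatMapFrame-class] (from [animateTrace()]).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param widthPx,heightPx device size.
#' @return character vector of the written paths.
#' @export
writeFrames <- function(frames, dir, prefix = "frame", widthPx = 640,
                        heightPx = 560) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(dir, sprintf("%s_%03d_%04.1fms.png", prefix, i,
                                       frames[[i]]@tMs))
    grDevices::png(paths[i], width = widthPx, height = heightPx)
    plot(frames[[i]])
    grDevices::dev.off()
  }
  paths
}
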