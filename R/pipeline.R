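#' @include visualize.R io-edf.R discriminate.R
NULL

## md5 of the serialized config (for the run manifest)
.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full delineation pipeline on one session
#'
#' preprocess -> peaks -> Fisher profiles -> spectral clustering -> grid
#' resampling -> heat maps, writing each stage's outputs plus a
#' machine-readable run manifest into `outDir`. Deterministic given the
#' seed; rerunning with identical inputs reproduces every numeric output.
#'
#' @param input a session: the list returned by [simulateSession()] /
#'   [readSessionBundle()], a fixture-bundle directory, or an EDF file path
#'   (then `geometryPath` must point to a geometry JSON).
#' @param outDir output directory (created).
#' @param geometryPath geometry JSON (only for EDF input).
#' @param flavor trace flavor used for clustering: "raw", "derivative",
#'   "zscored" or "zscored_derivative".
#' @param sigma,kMax,gapFloor,restarts clustering settings.
#' @param seed RNG seed, recorded in the manifest and every sidecar.
#' @param cutoffHz,windowMs,polyorder,windowLengthMs,zThreshold
#'   preprocessing settings, see [preprocessRecording()].
#' @param heatmapStepMs frame step of the animation stage.
#' @param writePNGs render heat-map frames to PNG (slowest stage; off for
#'   programmatic runs keeps outputs numeric-only).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(input, outDir, geometryPath = NULL,
                        flavor = "derivative", sigma = 2, kMax = 4,
                        gapFloor = 0.05, restarts = 50, seed = 1L,
                        cutoffHz = 30, windowMs = c(10, 50), polyorder = 3,
                        windowLengthMs = 5, zThreshold = 3.5,
                        heatmapStepMs = 2, writePNGs = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  config <- list(flavor = flavor, sigma = sigma, k_max = kMax,
                 gap_floor = gapFloor, restarts = restarts, seed = seed,
                 cutoff_hz = cutoffHz, window_ms = windowMs,
                 savgol_polyorder = polyorder,
                 savgol_window_ms = windowLengthMs,
                 corrupted_z_threshold = zThreshold)
  manifest <- list(package = "ssepcs",
                   version = as.character(packageVersion("ssepcs")),
                   seed = seed, config = config,
                   config_hash = .configHash(config),
                   stages = list())
  saveManifest <- function()
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
               file.path(outDir, "manifest.json"))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      saveManifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "complete")
    saveManifest()
    res
  }

  session <- stage("load", {
    if (is.list(input)) input
    else if (dir.exists(input)) readSessionBundle(input)
    else {
      if (is.null(geometryPath))
        stop("EDF input needs a geometry JSON via geometryPath")
      rec <- readEDF(input)
      gj <- readGeometryJSON(geometryPath)
      list(recording = rec, geometry = gj$geometry, truth = gj$truth)
    }
  })
  truth <- session$truth
  labels <- if (!is.null(truth)) regionLabels(truth) else NULL

  traces <- stage("preprocess", {
    raw <- preprocessRecording(session$recording, cutoffHz = cutoffHz,
                               windowMs = windowMs, polyorder = polyorder,
                               windowLengthMs = windowLengthMs,
                               zThreshold = zThreshold)
    tr <- list(raw = raw, derivative = derivativeTrace(raw))
    tr$zscored <- zscoreTrace(tr$raw)
    tr$zscored_derivative <- zscoreTrace(tr$derivative)
    for (fl in names(tr))
      writeTraceCSV(tr[[fl]], file.path(outDir, paste0("trace_", fl, ".csv")))
    tr
  })

  stage("peaks", {
    pk <- detectPeaks(traces$raw, labels = labels)
    write.csv(as.data.frame(pk), file.path(outDir, "peaks.csv"),
              row.names = FALSE)
    pk
  })

  stage("fisher", {
    if (is.null(labels)) {
      message("no region labels: skipping Fisher profiles")
      return(NULL)
    }
    for (fl in c("raw", "derivative")) {
      fp <- fisherProfile(traces[[fl]], labels)
      write.csv(data.frame(t_ms = fp@tMs, F = fp@F, mu_A = fp@muA,
                           mu_P = fp@muP, var_A = fp@varA, var_P = fp@varP),
                file.path(outDir, paste0("fisher_", fl, ".csv")),
                row.names = FALSE)
    }
  })

  clusterRes <- stage("cluster", {
    res <- spectralCluster(traces[[flavor]], sigma = sigma, kMax = kMax,
                           gapFloor = gapFloor, seed = seed,
                           restarts = restarts)
    res <- assignRegions(res, traces[[flavor]], truth)
    kept <- as.integer(names(clusterLabels(res)))
    labs <- clusterLabels(res)
    assigned <- if (res@k == 2L && !identical(res@regionMap, "single"))
      res@regionMap[labs] else rep("single", length(labs))
    lab.df <- data.frame(channel = kept, cluster = labs, region = assigned)
    if (!is.null(truth)) {
      lab.df$truth <- regionLabels(truth)[kept]
      lab.df$correct <- lab.df$region == lab.df$truth
    }
    write.csv(lab.df, file.path(outDir, "cluster_labels.csv"),
              row.names = FALSE)
    write.csv(data.frame(index = seq_along(res@eigenvalues),
                         eigenvalue = res@eigenvalues),
              file.path(outDir, "eigenvalues.csv"), row.names = FALSE)
    writeLines(jsonlite::toJSON(list(
      k = res@k, sigma = sigma, seed = seed,
      accuracy_pct = accuracyPct(res), chl_cl = res@chlCL,
      confusion = if (length(res@confusion)) res@confusion else NULL),
      auto_unbox = TRUE, digits = NA, null = "null"),
      file.path(outDir, "cluster_summary.json"))
    res
  })

  stage("resample", {
    if (is.null(truth) || session$geometry@nRows < 2L ||
        session$geometry@nCols < 2L) {
      message("resampling skipped (needs ground truth and a 2D grid)")
      return(NULL)
    }
    rs <- resampleGrids(traces[[flavor]], session$geometry, truth,
                        sigma = sigma, kMax = kMax, gapFloor = gapFloor,
                        seed = seed, restarts = restarts)
    write.csv(rs$summary, file.path(outDir, "resampling_summary.csv"),
              row.names = FALSE)
    rs
  })

  stage("heatmaps", {
    frames <- animateTrace(traces$raw, session$geometry,
                           stepMs = heatmapStepMs)
    if (writePNGs) writeFrames(frames, file.path(outDir, "frames"))
    ## always keep the peak frame numerically
    pk <- detectPeaks(traces$raw)
    tN <- median(pk$n1_latency_ms)
    fr <- heatmapFrame(traces$raw, session$geometry, tN)
    write.csv(data.frame(x = fr@electrodes$x, y = fr@electrodes$y,
                         value = fr@electrodes$value),
              file.path(outDir, "field_at_n20.csv"), row.names = FALSE)
    length(frames)
  })

  invisible(manifest)
}
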