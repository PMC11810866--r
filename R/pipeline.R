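#' @include AllClasses.R registration.R surface.R
NULL

#' Read a flat key = value configuration file
#'
#' TOML-style flat files: one `key = value` per line, `#` comments,
#' values parsed as numbers or comma-separated numeric vectors when
#' possible, strings otherwise.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    out <- list()
    for (ln in lines) {
        kv <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_.-]*)\\s*=\\s*(.*)$",
                                     ln))[[1]]
        if (length(kv) != 3L) stop("malformed config line: ", ln)
        val <- trimws(gsub("^\"|\"$", "", trimws(kv[3])))
        parts <- strsplit(val, ",")[[1]]
        num <- suppressWarnings(as.numeric(parts))
        out[[kv[2]]] <- if (!anyNA(num)) num else val
    }
    out
}

#' Run the full segment-register-evaluate pipeline
#'
#' Mirrors the clinical acquisition protocol: load the volume, segment
#' and extract the skin, load the camera surface, place the landmark
#' pair, co-register, and write out the artifacts (skin mesh, transform
#' JSON with per-stage diagnostics, error-coloured PLYs for both ROI
#' surfaces, and a run log).
#'
#' @param config named list (see [readRunConfig()]) with entries
#'   `volume`, `iso_value`, `camera`, `landmark_skin`, `landmark_camera`,
#'   `out_dir` and optionally `pad` (default 1), `subsample` (1),
#'   `roi_radius` (100), `trim` (0.8), `anterior` (0,1,0), `error_cap`
#'   (5).
#' @return Invisibly, a list with the [RegistrationResult-class], the
#'   skin mesh, and the paths written.
#' @export
runPipeline <- function(config) {
    need <- function(k) {
        if (is.null(config[[k]]))
            stop("pipeline config misses required entry '", k, "'")
        config[[k]]
    }
    getd <- function(k, dflt) config[[k]] %||% dflt
    outDir <- need("out_dir")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(outDir, "run.log")
    logCon <- file(logPath, "w")
    on.exit(close(logCon))
    logln <- function(...) {
        writeLines(paste0(format(Sys.time(), "%H:%M:%S "), ...), logCon)
    }
    logln("configuration:")
    for (k in names(config))
        logln("  ", k, " = ", paste(config[[k]], collapse = ","))

    logln("stage: volume reading")
    vol <- readVolume(need("volume"))
    cfg <- segmentationConfig(isoValue = need("iso_value"),
                              padWidth = getd("pad", 1L),
                              subsampleFactor = getd("subsample", 1L))
    logln("stage: segmentation (iso-value ", cfg$isoValue, ")")
    t0 <- proc.time()[["elapsed"]]
    grid <- segmentSkin(vol, cfg)
    logln("stage: skin extraction")
    skin <- extractSkinSurface(grid)
    logln(sprintf("  skin mesh: %d vertices, %d triangles (%.1f s)",
                  nVertices(skin), nTriangles(skin),
                  proc.time()[["elapsed"]] - t0))
    skinPath <- file.path(outDir, "skin.ply")
    writeMesh(skin, skinPath)

    logln("stage: co-registration")
    camera <- readMesh(need("camera"))
    regCfg <- registrationConfig(
        roiRadius = getd("roi_radius", 100),
        trimFraction = getd("trim", 0.8),
        anterior = getd("anterior", c(0, 1, 0)))
    pair <- landmarkPair(skin, camera, need("landmark_skin"),
                         need("landmark_camera"))
    t0 <- proc.time()[["elapsed"]]
    res <- coregister(skin, camera, pair, regCfg)
    logln(sprintf("  per-stage RMS (mm): %s",
                  paste(sprintf("%s=%.4f", names(perStageRMS(res)),
                                perStageRMS(res)), collapse = " ")))
    logln(sprintf("  Hausdorff: %.4f mm, ICP iterations %s (%.1f s)",
                  hausdorffValue(res),
                  paste(iterationsUsed(res), collapse = "+"),
                  proc.time()[["elapsed"]] - t0))

    jsonPath <- file.path(outDir, "transform.json")
    jsonlite::write_json(list(
        matrix = as.vector(t(transformToMatrix(transform(res)))),
        per_stage_rms_mm = as.list(perStageRMS(res)),
        hausdorff_mm = hausdorffValue(res),
        iterations = as.list(iterationsUsed(res))),
        jsonPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)

    cap <- getd("error_cap", 5)
    segPath <- file.path(outDir, "segmented_error.ply")
    camPath <- file.path(outDir, "camera_error.ply")
    writeMesh(res@segROI, segPath)
    writeMesh(res@camROI, camPath)
    logln("done")
    invisible(list(result = res, skin = skin,
                   paths = c(skin = skinPath, transform = jsonPath,
                             segmentedError = segPath,
                             cameraError = camPath, log = logPath)))
}
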