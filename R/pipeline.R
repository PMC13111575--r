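#' Pipeline configuration
#'
#' The triple-way preprocessing runs the stages in a fixed, configured order
#' — by default artifact/noise removal (CEAMF), then Z-score normalization
#' (with re-quantization back to integer levels), then context-aware
#' contrast enhancement. Parameters are set once in the config and held
#' constant across all images of a run; no statistic from any image informs
#' another image's parameters.
#'
#' @param side standardized square side in pixels (default 1024; tests and
#'   demos use smaller phantoms).
#' @param stages character vector ordering the stages, a permutation of a
#'   subset of `c("ceamf", "normalize", "enhance")`.
#' @param ceamf list: `kSigma`, `minArea` for spot detection, optional `cap`
#'   overriding the derived window cap.
#' @param enhance list: `d`, `f` for the energy curve.
#' @param levels working gray-level count after normalization (default 256).
#' @param seed run seed (recorded; the preprocessing stages themselves are
#'   deterministic).
#' @param outDir directory for processed images, or `NULL` to keep them in
#'   memory.
#' @return a config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(side = 1024,
                           stages = c("ceamf", "normalize", "enhance"),
                           ceamf = list(kSigma = 2.5, minArea = 16, cap = NULL),
                           enhance = list(d = 1, f = 1),
                           levels = 256, seed = 1, outDir = NULL) {
  stages <- match.arg(stages, c("ceamf", "normalize", "enhance"),
                      several.ok = TRUE)
  if (anyDuplicated(stages)) stop("duplicate stages in config")
  cfg <- list(side = side, stages = stages,
              ceamf = utils::modifyList(list(kSigma = 2.5, minArea = 16,
                                             cap = NULL), ceamf),
              enhance = utils::modifyList(list(d = 1, f = 1), enhance),
              levels = levels, seed = seed, outDir = outDir)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Serialize / restore a pipeline config
#'
#' Round-trips through a flat key-value JSON file so a run can be reproduced
#' exactly from its recorded config.
#'
#' @param config a [pipelineConfig()].
#' @param path file to write / read.
#' @return `writePipelineConfig` returns `path` invisibly;
#'   `readPipelineConfig` returns a `PipelineConfig`.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, x[!vapply(x, is.null, TRUE)])
}

# resolve one manifest row to a GrayImage
.loadRecordImage <- function(row, cohort = NULL) {
  key <- paste(row$case_id, row$laterality, row$view, sep = "_")
  if (!is.null(cohort) && key %in% names(cohort$cases))
    return(cohort$cases[[key]]$image)
  if (!is.null(row$image_path) && !is.na(row$image_path))
    return(readGrayImage(row$image_path))
  stop("no image source for record ", key)
}

#' Run the triple-way preprocessing pipeline over a cohort
#'
#' Every image is standardized to the configured square size and passed
#' through the configured stages in order. Failures are isolated per image:
#' the run continues, the error is recorded in the report, and the caller
#' decides what a nonzero failure count means. Two runs with the same
#' manifest, config and seed produce bit-identical outputs.
#'
#' @param manifest a manifest data.frame (or path to one), or a
#'   `PhantomCohort` (its in-memory images are used directly).
#' @param config a [pipelineConfig()].
#' @return a list of class `PipelineRun`: `report` (one row per image:
#'   identifiers, per-stage flags, spot count, window stats, band
#'   boundaries, error message if any, elapsed seconds), `images` (named
#'   list of processed [GrayImage]s, unless written to `outDir`),
#'   `nFailed`.
#' @export
runPipeline <- function(manifest, config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  cohort <- NULL
  if (inherits(manifest, "PhantomCohort")) {
    cohort <- manifest
    manifest <- cohort$manifest
  } else if (is.character(manifest)) {
    manifest <- readManifest(manifest)
  }
  keep <- is.null(config$outDir)
  if (!keep) dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  images <- list()
  rows <- vector("list", nrow(manifest))
  set.seed(as.integer(config$seed %% .Machine$integer.max))
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    key <- paste(row$case_id, row$laterality, row$view, sep = "_")
    t0 <- proc.time()[["elapsed"]]
    rec <- list(case_id = row$case_id, laterality = row$laterality,
                view = row$view, nSpots = NA_integer_,
                uMin = NA_integer_, uMax = NA_integer_, uMean = NA_real_,
                loLow = NA_real_, loHigh = NA_real_,
                degenerate = FALSE, fallback = FALSE,
                error = NA_character_, elapsed = NA_real_)
    res <- tryCatch({
      img <- .loadRecordImage(row, cohort)
      img <- standardizeImage(img, side = config$side)
      for (stage in config$stages) {
        if (stage == "ceamf") {
          spots <- detectLightSpots(img, config$ceamf$kSigma,
                                    config$ceamf$minArea)
          policy <- if (is.null(config$ceamf$cap)) NULL
                    else WindowPolicy(uMin = 3, sDis = config$ceamf$cap)
          out <- applyCEAMF(img, spots = spots, policy = policy,
                            report = TRUE)
          img <- out$image
          rec$nSpots <- nrow(out$spots)
          rec$uMin <- out$windowStats$min
          rec$uMax <- out$windowStats$max
          rec$uMean <- out$windowStats$mean
        } else if (stage == "normalize") {
          z <- zscoreNormalize(img)
          rec$degenerate <- rec$degenerate || z@degenerate
          img <- requantize(z, levels = config$levels)
        } else if (stage == "enhance") {
          out <- enhanceContrast(img, d = config$enhance$d,
                                 f = config$enhance$f, report = TRUE)
          rec$degenerate <- rec$degenerate || out$flags$degenerate
          rec$fallback <- rec$fallback || out$flags$fallback
          if (!is.null(out$bands)) {
            rec$loLow <- out$bands@loLow
            rec$loHigh <- out$bands@loHigh
          }
          img <- out$image
        }
      }
      img
    }, error = function(e) e)
    rec$elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      rec$error <- conditionMessage(res)
    } else if (keep) {
      images[[key]] <- res
    } else {
      writeGrayImage(res, file.path(config$outDir, paste0(key, ".png")))
    }
    rows[[r]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows)
            else data.frame(case_id = character(0))
  structure(list(report = report, images = images,
                 nFailed = sum(!is.na(report$error))),
            class = "PipelineRun")
}

#' @export
print.PipelineRun <- function(x, ...) {
  cat(sprintf("PipelineRun: %d images, %d failed\n",
              nrow(x$report), x$nFailed))
  invisible(x)
}
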