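## TIFF readers/writers, sidecar metadata, run configuration and reports.
##
## The TIFF writer stores samples in [0, 1]; integer count data are encoded
## as 16-bit (value/65535) and float maps as 32-bit scaled by documented
## per-map factors recorded in a sidecar, with invalid pixels written as 0
## and the validity carried in its own mask file.

.sidecarPath <- function(path)
  file.path(dirname(path),
            paste0(tools::file_path_sans_ext(basename(path)), ".yml"))

#' Run configuration
#'
#' Bundles every tunable of the pipeline; all randomness flows from the
#' single \code{seed}.
#'
#' @param angles angle grid: numeric vector or \code{"start:stop:step"}.
#' @param threshold segmentation threshold on the normalized mean image.
#' @param smoothRadius neighbor-averaging radius in pixels (window
#'   \code{(2r+1)^2}).
#' @param ratioBin,angleBin mode-histogram bin widths.
#' @param fiberFactor mean-relative fiber-mask threshold.
#' @param seed integer seed.
#' @param outdir output directory.
#' @return a list of class \code{"RunConfig"}.
#' @export
runConfig <- function(angles = "0:170:10", threshold = 0.2,
                      smoothRadius = 1, ratioBin = 0.01, angleBin = 0.25,
                      fiberFactor = 0.45, seed = 1L, outdir = ".") {
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  if (fiberFactor <= 0) stop("fiberFactor must be positive", call. = FALSE)
  .parseAngleSpec(angles)   # validates
  structure(list(angles = angles, threshold = threshold,
                 smoothRadius = as.integer(smoothRadius),
                 ratioBin = ratioBin, angleBin = angleBin,
                 fiberFactor = fiberFactor, seed = as.integer(seed),
                 outdir = outdir),
            class = "RunConfig")
}

#' @rdname runConfig
#' @param config a \code{RunConfig}.
#' @param path YAML file path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(runConfig, x)
}

#' Read a polarization stack from TIFF
#'
#' Accepts a multi-page TIFF (one page per angle) or a directory of
#' single-page TIFFs in angle order. Angles come from \code{angles} (numeric
#' or \code{"start:stop:step"}) or, when \code{NULL}, from a sidecar YAML
#' (same basename, \code{.yml} extension) with an \code{angles} field. The
#' page count must equal the angle count.
#'
#' @param path TIFF file or directory.
#' @param angles angle specification or \code{NULL} for sidecar lookup.
#' @return a [PolarizationStack-class].
#' @export
readStack <- function(path, angles = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L)
      stop("directory contains no TIFF files: ", path, call. = FALSE)
    pages <- lapply(files, function(f)
      tiff::readTIFF(f, as.is = TRUE))
    sidecar <- .sidecarPath(file.path(path, "stack.tif"))
  } else {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                        stop("cannot read TIFF: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
    sidecar <- .sidecarPath(path)
  }
  if (is.null(angles)) {
    if (!file.exists(sidecar))
      stop("no angles given and no sidecar metadata at ", sidecar,
           call. = FALSE)
    meta <- yaml::read_yaml(sidecar)
    if (is.null(meta$angles))
      stop("sidecar metadata lacks an 'angles' field", call. = FALSE)
    angles <- unlist(meta$angles)
  }
  angles <- .parseAngleSpec(angles)
  if (length(pages) != length(angles))
    stop(sprintf("page count (%d) does not match angle count (%d)",
                 length(pages), length(angles)), call. = FALSE)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("stack pages must be single-channel (grayscale) images",
         call. = FALSE)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  data <- array(0, c(H, W, length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    ## integer TIFFs come back as stored counts; float TIFFs as [0,1] floats
    data[, , k] <- p
  }
  PolarizationStack(data, angles)
}

#' Write a polarization stack to a multi-page TIFF
#'
#' Integer count data are written as uncompressed 16-bit pages (lossless for
#' counts up to 65535; the round trip with [readStack()] is bit-identical).
#' A sidecar YAML with the angle list (plus any extra metadata) is written
#' alongside.
#'
#' @param stack a [PolarizationStack-class] with integer-valued counts in
#'   \code{[0, 65535]}.
#' @param path output TIFF path.
#' @param metadata optional named list merged into the sidecar.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, metadata = list()) {
  stopifnot(is(stack, "PolarizationStack"))
  d <- stack@data
  if (max(d) > 65535)
    stop("counts exceed 65535; rescale before writing 16-bit TIFF",
         call. = FALSE)
  if (max(abs(d - round(d))) > 1e-6)
    warning("non-integer intensities are rounded to counts on write",
            call. = FALSE)
  d <- round(d)
  pages <- lapply(seq_len(dim(d)[3]), function(k) d[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none")
  meta <- c(list(angles = as.numeric(stack@angles),
                 pages = dim(d)[3], height = dim(d)[1], width = dim(d)[2],
                 encoding = "uint16 counts"),
            metadata)
  yaml::write_yaml(meta, .sidecarPath(path))
  invisible(path)
}

#' Write phantom ground truth as sidecar metadata
#'
#' Records the scenario label, geometry and truth anchors of a phantom in a
#' YAML file alongside a rendered stack, so downstream recovery can be
#' compared against the generating truth.
#'
#' @param phantom a [Phantom-class].
#' @param path path of the rendered stack TIFF (the sidecar name is derived
#'   from it, suffix \code{_truth.yml}).
#' @return the sidecar path, invisibly.
#' @export
writePhantomTruth <- function(phantom, path) {
  stopifnot(is(phantom, "Phantom"))
  out <- file.path(dirname(path),
                   paste0(tools::file_path_sans_ext(basename(path)),
                          "_truth.yml"))
  geo <- phantom@geometry
  geo <- geo[vapply(geo, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), logical(1))]
  yaml::write_yaml(c(list(scenario = phantom@scenario,
                          foregroundFraction = mean(phantom@foreground)),
                     geo), out)
  invisible(out)
}

## scale factors taking each map into [0,1] for the 32-bit float writer
.mapScales <- c(alpha = 180, chi15 = 10, chi33 = 10, theta = 90,
                residual = 10)

.writeFloatMap <- function(map, path, scale) {
  m <- map / scale
  m[!is.finite(m)] <- 0
  m <- pmin(pmax(m, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 32L, compression = "none")
}

#' Write the full result set of a run
#'
#' Writes one 32-bit float TIFF per parameter map (orientation, chi15/chi31,
#' chi33/chi31, pitch angle, residual; values scaled into \code{[0, 1]} by
#' per-map factors recorded in \code{maps.yml} and the run report, invalid
#' pixels written as 0), 8-bit mask TIFFs (validity, isotropy, fiber mask),
#' the one-row summary statistics CSV, and a structured-text run report
#' (package version, configuration, seed, pixel counts).
#'
#' @param fit a [FitMaps-class].
#' @param mol a [MolecularMaps-class].
#' @param stats one-row data frame from [summaryStats()].
#' @param outdir output directory (created if needed).
#' @param config optional \code{RunConfig} echoed into the report.
#' @param fiberMask optional logical matrix from [fiberDensity()].
#' @return character vector of the files written, invisibly.
#' @export
writeOutputs <- function(fit, mol, stats, outdir, config = NULL,
                         fiberMask = NULL) {
  stopifnot(is(fit, "FitMaps"), is(mol, "MolecularMaps"),
            is.data.frame(stats))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("cannot create output directory: ", outdir, call. = FALSE)

  maps <- list(alpha = fit@alphaMap, chi15 = mol@chi15Map,
               chi33 = mol@chi33Map, theta = mol@thetaMap,
               residual = fit@residualMap)
  files <- character(0)
  for (nm in names(maps)) {
    f <- file.path(outdir, paste0(nm, ".tif"))
    m <- maps[[nm]]
    m[!fit@validMask] <- NA_real_
    .writeFloatMap(m, f, .mapScales[[nm]])
    files <- c(files, f)
  }
  yaml::write_yaml(list(scales = as.list(.mapScales),
                        note = paste("map value = stored sample * scale;",
                                     "invalid pixels stored as 0, see",
                                     "valid_mask.tif")),
                   file.path(outdir, "maps.yml"))

  masks <- list(valid_mask = fit@validMask,
                isotropic_mask = fit@isotropicMask)
  if (!is.null(fiberMask)) masks$fiber_mask <- fiberMask
  for (nm in names(masks)) {
    f <- file.path(outdir, paste0(nm, ".tif"))
    tiff::writeTIFF(masks[[nm]] * 1.0, f, bits.per.sample = 8L,
                    compression = "none")
    files <- c(files, f)
  }

  csv <- file.path(outdir, "summary.csv")
  utils::write.csv(format(stats, digits = 17, scientific = FALSE,
                          trim = TRUE),
                   csv, row.names = FALSE, quote = FALSE)
  files <- c(files, csv)

  rpt <- file.path(outdir, "report.txt")
  lines <- c(
    "PSHG run report",
    paste0("package: PSHGtools ",
           as.character(utils::packageVersion("PSHGtools"))),
    paste0("R: ", R.version.string),
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "",
    paste0("pixels: ", length(fit@validMask)),
    paste0("valid: ", sum(fit@validMask)),
    paste0("invalid: ", sum(!fit@validMask)),
    paste0("isotropic: ", sum(fit@isotropicMask)),
    if (sum(fit@validMask) == 0L)
      "note: empty valid mask; all map files are zero-filled sentinels",
    "",
    "map encoding (value = sample * scale):",
    paste0("  ", names(.mapScales), ": ", .mapScales))
  if (!is.null(config)) {
    lines <- c(lines, "", "config:",
               paste0("  ", names(config), ": ",
                      vapply(config, function(x)
                        paste(x, collapse = " "), character(1))))
  }
  writeLines(lines[!vapply(lines, is.null, logical(1))], rpt)
  files <- c(files, rpt, file.path(outdir, "maps.yml"))
  invisible(files)
}

#' Run the whole analysis on a stack
#'
#' Segmentation, per-pixel fitting with neighbor averaging, molecular maps
#' and summary statistics in one call; the composition used by the
#' command-line pipeline.
#'
#' @param stack a [PolarizationStack-class].
#' @param config a \code{RunConfig} (defaults used when \code{NULL}).
#' @return list with \code{foreground}, \code{fit}, \code{mol},
#'   \code{stats}, \code{fiberMask}.
#' @export
analyzeStack <- function(stack, config = NULL) {
  if (is.null(config)) config <- runConfig()
  fg <- normalizeAndSegment(stack, config$threshold)
  fit <- fitStack(stack, smoothRadius = config$smoothRadius,
                  foreground = fg)
  mol <- ratioMaps(fit)
  d <- dim(stack@data)
  m <- stack@data
  dim(m) <- c(d[1] * d[2], d[3])
  meanImg <- matrix(rowMeans(m), d[1], d[2])
  fd <- fiberDensity(meanImg, config$fiberFactor)
  stats <- summaryStats(stack, fit, mol, foreground = fg,
                        ratioBin = config$ratioBin,
                        angleBin = config$angleBin,
                        fiberFactor = config$fiberFactor)
  list(foreground = fg, fit = fit, mol = mol, stats = stats,
       fiberMask = fd$mask)
}
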