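# Per-image pipeline: projection -> grayscale -> normalization ->
# thresholding -> gap filling -> watershed labeling -> focus adjustment ->
# substructures -> morphometry records.

#' Analyze one image field end to end
#'
#' Runs the complete per-image pipeline on a [SpheroidStack-class]: average
#' intensity projection per channel, weighted grayscale conversion,
#' percentile normalization, optional denoising, histogram-valley
#' thresholding, gap filling, watershed structure labeling, per-structure
#' focus-plane threshold adjustment (3D input only), substructural cell
#' segmentation on the red and green channels, body/appendage decomposition,
#' and assembly of the full morphometry record table.
#'
#' @param stack a [SpheroidStack-class] (or a plain H x W matrix, treated as
#'   a single-channel field).
#' @param params a [SegmentationParams-class].
#' @param imageId identifier stored with the results.
#' @param weights grayscale channel weights (default equal across present
#'   channels).
#' @param normalize apply 5/95 percentile normalization before thresholding
#'   (default TRUE).
#' @param denoise optional denoising method passed to [denoiseImage()]
#'   (NULL = none).
#' @param phaseContrast treat the input as a phase-contrast image: the
#'   single channel receives large-kernel background flattening before
#'   thresholding.
#' @return a [SpheroidField-class].
#' @examples
#' sim <- makeField(phenotypeSpec(nStructures = 4, fieldSize = c(128, 128),
#'                                seed = 7))
#' fld <- analyzeField(sim$stack, imageId = "demo")
#' nStructures(fld)
#' head(records(fld))
#' @export
analyzeField <- function(stack, params = segmentationParams(),
                         imageId = "image", weights = NULL,
                         normalize = TRUE, denoise = NULL,
                         phaseContrast = FALSE) {
  if (is.matrix(stack))
    stack <- new("SpheroidStack",
                 channels = list(gray = asStack3d(stack)),
                 bitDepth = if (max(stack) > 255) 16 else 8)
  stopifnot(is(stack, "SpheroidStack"))
  fullScale <- 2^stack@bitDepth - 1
  color <- averageProjection(stack)
  gray <- toGrayscale(color, weights)
  if (phaseContrast) gray <- flattenBackground(gray)
  if (normalize) gray <- percentileNormalize(gray, fullScale = fullScale)
  if (!is.null(denoise)) gray <- denoiseImage(gray, method = denoise)
  mask <- suppressWarnings(valleyThreshold(gray, params@thresholdLevel,
                                           params@smoothSigma,
                                           fullScale = fullScale))
  globalCut <- attr(mask, "threshold")
  mask <- fillGaps(mask, params@gapFillMax)
  labels <- segmentStructures(mask, params)
  maxPlanes <- max(vapply(stack@channels, function(a) dim(a)[3], 1))
  if (maxPlanes > 1 && max(labels) > 0) {
    fa <- suppressMessages(focusAdjust(stack, labels, mask, params))
    labels <- labels * (fa$mask > 0)
    labels <- matrix(as.integer(labels), nrow(labels))
  }
  assembleField(stack, color, gray, labels, params, imageId)
}

# Build the SpheroidField: per-structure detail + record table.
assembleField <- function(stack, color, gray, labels, params, imageId) {
  n <- max(labels)
  h <- nrow(labels); w <- ncol(labels)
  chR <- color[[params@apoptosisChannel]]
  chG <- color[[params@structureChannel]]
  if (is.null(chG)) chG <- gray
  structures <- vector("list", n)
  centers <- matrix(0, n, 2)
  featRows <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- which(labels == i)
    py <- (idx - 1L) %% h + 1L
    px <- (idx - 1L) %/% h + 1L
    y0 <- max(1L, min(py) - 1L); y1 <- min(h, max(py) + 1L)
    x0 <- max(1L, min(px) - 1L); x1 <- min(w, max(px) + 1L)
    cmask <- matrix(0, y1 - y0 + 1L, x1 - x0 + 1L)
    cmask[cbind(py - y0 + 1L, px - x0 + 1L)] <- 1
    geom <- structureGeometry(cmask, params@radiusQuantile)
    geom$center <- geom$center + c(x0 - 1L, y0 - 1L)  # field coordinates
    centers[i, ] <- geom$center
    geomLocal <- geom
    geomLocal$center <- geom$center - c(x0 - 1L, y0 - 1L)
    ba <- bodyAppendages(cmask, params)
    shp <- shapeFeatures(cmask, geomLocal, ba$body, params)
    app <- appendageFeatures(ba$body, ba$appendages)
    cropR <- if (!is.null(chR)) chR[y0:y1, x0:x1] else NULL
    cropG <- chG[y0:y1, x0:x1]
    cellsR <- if (!is.null(cropR)) segmentCells(cmask, cropR, params)
              else matrix(0L, nrow(cmask), ncol(cmask))
    cellsG <- segmentCells(cmask, cropG, params)
    fR <- if (!is.null(cropR)) channelFeatures(cmask, cropR, cellsR,
                                               geomLocal)
          else c(Density = 0, Deviation = 0, AreaRatio = 0, Hollowness = 0,
                 CellNumber = 0, AveArea = 0)
    fG <- channelFeatures(cmask, cropG, cellsG, geomLocal)
    featRows[[i]] <- c(shp, app,
      Deviation = unname(fG["Deviation"]),
      DensityR = unname(fR["Density"]), DensityG = unname(fG["Density"]),
      AreaRatioR = unname(fR["AreaRatio"]),
      AreaRatioG = unname(fG["AreaRatio"]),
      HollownessR = unname(fR["Hollowness"]),
      HollownessG = unname(fG["Hollowness"]),
      CellNumberR = unname(fR["CellNumber"]),
      CellNumberG = unname(fG["CellNumber"]),
      AveAreaR = unname(fR["AveArea"]), AveAreaG = unname(fG["AveArea"]))
    structures[[i]] <- list(label = i, pixels = idx,
      bbox = c(y0 = y0, y1 = y1, x0 = x0, x1 = x1), mask = cmask,
      geometry = geom, body = ba$body, appendages = ba$appendages,
      bodyFlagged = ba$flagged, cellsR = cellsR, cellsG = cellsG)
  }
  nb <- neighborFeatures(labels, centers)
  if (n > 0) {
    feat <- as.data.frame(do.call(rbind, featRows))
    rec <- cbind(data.frame(ImageId = imageId, StructureId = seq_len(n)),
                 feat, nb)
    rec <- rec[, c("ImageId", "StructureId", recordColumns())]
  } else {
    rec <- emptyRecords(imageId)
  }
  rownames(rec) <- NULL
  new("SpheroidField", imageId = imageId,
      labels = matrix(as.integer(labels), h, w),
      structures = structures, records = rec, params = params)
}

emptyRecords <- function(imageId = character(0)) {
  cols <- c("ImageId", "StructureId", recordColumns())
  rec <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  rec$ImageId <- character(0)
  rec
}

#' Write / read morphometry records
#'
#' CSV writers and readers for the per-structure result table, with a
#' schema-version header comment. Coordinates and all features are in the
#' documented column order; CSV is the canonical diffable format.
#'
#' @param records data.frame of morphometry records (possibly annotated).
#' @param path output file path.
#' @return \code{writeRecords}: the path, invisibly. \code{readRecords}:
#'   the records data.frame.
#' @export
writeRecords <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# spheromorph records schema 1.0", con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecords
#' @export
readRecords <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write a label-map overlay for visual QC
#'
#' Writes a PNG with the grayscale image in the background and structure
#' labels in rotating colors, for quick visual inspection of segmentation
#' quality.
#'
#' @param field a [SpheroidField-class].
#' @param gray background grayscale matrix (raw gray levels).
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
writeOverlay <- function(field, gray, path) {
  lab <- labelMap(field)
  g <- gray / max(gray, 1)
  pal <- grDevices::hcl.colors(max(8, max(lab)), "Dark 3")
  rgbArr <- array(rep(g, 3), dim = c(nrow(g), ncol(g), 3))
  nz <- lab > 0
  colmat <- grDevices::col2rgb(pal[(lab[nz] - 1) %% length(pal) + 1]) / 255
  for (k in 1:3) {
    plane <- rgbArr[, , k]
    plane[nz] <- 0.5 * plane[nz] + 0.5 * colmat[k, ]
    rgbArr[, , k] <- plane
  }
  png::writePNG(rgbArr, path)
  invisible(path)
}
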