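#' @import methods
#' @importFrom stats quantile median sd var cor wilcox.test hclust dist
#'   as.dendrogram rnorm runif rpois setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

#' Multi-channel image stack
#'
#' Container for raw image data: one 3D intensity array (height x width x
#' planes) per channel. 2D inputs are stored as depth-1 stacks. Channels are
#' named (conventionally \code{"R"}, \code{"G"}, \code{"B"} for fluorescence,
#' or \code{"gray"} for single-channel / phase-contrast input) and must share
#' the lateral (height, width) dimensions; the number of planes may differ per
#' channel. Intensities are gray levels in \code{[0, 2^bitDepth - 1]}.
#'
#' @slot channels named list of 3D numeric arrays (H x W x planes).
#' @slot bitDepth integer, 8 or 16.
#'
#' @seealso [readSpheroidStack()], [averageProjection()], [makeField()]
#' @export
setClass("SpheroidStack",
  representation(channels = "list", bitDepth = "numeric"),
  prototype(channels = list(), bitDepth = 8))

setValidity("SpheroidStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("stack has no channels")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  dims <- lapply(ch, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("each channel must be a 3D array (H x W x planes)")
  hw <- vapply(dims, function(d) d[1:2], numeric(2))
  if (any(hw[1, ] != hw[1, 1]) || any(hw[2, ] != hw[2, 1]))
    return("all channels must share height and width")
  if (any(vapply(dims, function(d) d[3], 1) < 1))
    return("each channel needs at least one plane")
  if (!object@bitDepth %in% c(8, 16))
    return("bitDepth must be 8 or 16")
  full <- 2^object@bitDepth - 1
  rng <- range(unlist(lapply(ch, range)))
  if (rng[1] < 0 || rng[2] > full)
    return(sprintf("intensities must lie in [0, %d]", full))
  TRUE
})

#' Segmentation and morphometry parameters
#'
#' The two user-facing knobs are \code{sensitivity} (the pixel distance used
#' by the watershed seed merging: larger values give fewer, larger structures)
#' and \code{thresholdLevel} (stringency of the histogram valley cut-off,
#' integer levels 1..5; higher levels shrink the foreground). The remaining
#' slots have defaults matching routine use and rarely need adjustment.
#'
#' @slot sensitivity numeric > 0, watershed seed-merging distance in pixels
#'   (default 20).
#' @slot thresholdLevel histogram cut-off stringency, levels 1..5 (default 1);
#'   level L places the cut at valley + (L - 1) x 2\% of the dynamic range.
#' @slot gapFillMax holes strictly smaller than this pixel count are filled
#'   (default 1000).
#' @slot minStructureSize objects below this area are discarded (default 100).
#' @slot openingRadius disc radius (px) of the preliminary structuring element
#'   (default 3).
#' @slot bodyKernelScale adaptive opening radius for body/appendage
#'   extraction, as a fraction of the structure equivalent diameter
#'   (default 0.1).
#' @slot cellKernelScale adaptive opening radius for cell-level segmentation,
#'   fraction of equivalent diameter, minimum 1 px (default 0.02).
#' @slot cellKernelMax cap on the cell-level opening radius in px (default
#'   1): substructures such as nuclei and apoptotic bodies have a fixed
#'   physical size at fixed magnification, so the cleaning kernel must not
#'   grow with the host structure.
#' @slot radiusQuantile quantile m of the edge-distance set that defines the
#'   structure radius (default 0.25).
#' @slot smoothSigma Gaussian sigma, in histogram bins, used to smooth the
#'   256-bin histogram before valley search (default 3).
#' @slot minAppendageSize appendage components below this pixel count are
#'   treated as outline ripple (default 5).
#' @slot structureChannel channel used for structural segmentation
#'   (default "G", the viability stain).
#' @slot apoptosisChannel channel carrying the dead/apoptotic-cell signal
#'   (default "R").
#' @slot cellContrastMin minimum between-class contrast for cell-level Otsu
#'   segmentation, as a fraction of the in-structure intensity range
#'   (default 0.35); structures whose channel is noise-like yield zero cells
#'   instead of a spurious noise partition.
#' @slot roundnessMethod "cv" (edge-distance coefficient of variation, the
#'   default) or "isoperimetric" (4 pi A / P^2).
#' @export
setClass("SegmentationParams",
  representation(sensitivity = "numeric", thresholdLevel = "numeric",
    gapFillMax = "numeric", minStructureSize = "numeric",
    openingRadius = "numeric", bodyKernelScale = "numeric",
    cellKernelScale = "numeric", cellKernelMax = "numeric",
    radiusQuantile = "numeric",
    smoothSigma = "numeric", minAppendageSize = "numeric",
    cellContrastMin = "numeric",
    structureChannel = "character", apoptosisChannel = "character",
    roundnessMethod = "character"),
  prototype(sensitivity = 20, thresholdLevel = 1, gapFillMax = 1000,
    minStructureSize = 100, openingRadius = 3, bodyKernelScale = 0.1,
    cellKernelScale = 0.02, cellKernelMax = 1, radiusQuantile = 0.25,
    smoothSigma = 3,
    minAppendageSize = 5, cellContrastMin = 0.35,
    structureChannel = "G", apoptosisChannel = "R",
    roundnessMethod = "cv"))

setValidity("SegmentationParams", function(object) {
  if (object@sensitivity <= 0) return("sensitivity must be > 0")
  if (object@gapFillMax < 0) return("gapFillMax must be >= 0")
  if (object@minStructureSize < 0) return("minStructureSize must be >= 0")
  if (object@radiusQuantile <= 0 || object@radiusQuantile >= 1)
    return("radiusQuantile must lie strictly between 0 and 1")
  if (object@thresholdLevel < 1)
    return("thresholdLevel must be >= 1")
  if (!object@roundnessMethod %in% c("cv", "isoperimetric"))
    return("roundnessMethod must be 'cv' or 'isoperimetric'")
  TRUE
})

#' @describeIn SegmentationParams-class constructor with defaults.
#' @param ... slot values overriding the defaults.
#' @return a validated \code{SegmentationParams} object.
#' @examples
#' p <- segmentationParams(sensitivity = 30)
#' @export
segmentationParams <- function(...) new("SegmentationParams", ...)

#' Segmented and measured image field
#'
#' The per-image result of [analyzeField()]: the integer label map (0 =
#' background, 1..N = structures, 8-connected), the per-structure geometry and
#' substructure detail, and the assembled morphometry table.
#'
#' @slot imageId character identifier of the source image.
#' @slot labels integer H x W matrix of structure labels.
#' @slot structures list of per-structure detail lists (pixel sets, body and
#'   appendage masks, per-channel cell label maps, geometry).
#' @slot records data.frame, one row per structure (see
#'   [morphometryCatalog()]).
#' @slot params the \code{SegmentationParams} used.
#' @export
setClass("SpheroidField",
  representation(imageId = "character", labels = "matrix",
    structures = "list", records = "data.frame",
    params = "SegmentationParams"))

setValidity("SpheroidField", function(object) {
  lab <- object@labels
  if (length(lab) && any(lab < 0)) return("labels must be >= 0")
  n <- max(0, lab)
  if (n != length(object@structures))
    return("max label must equal the number of structure entries")
  if (nrow(object@records) != length(object@structures))
    return("records must have one row per structure")
  TRUE
})

#' Standardized median-difference heatmap result
#'
#' Treatments x features matrix of control-subtracted median differences,
#' standardized column-wise (per feature, across treatments) to unit variance,
#' together with the raw and Bonferroni-corrected Mann-Whitney p-value
#' matrices and the p < 0.05 significance mask.
#'
#' @slot differences standardized median-difference matrix (treatments x
#'   features).
#' @slot rawDifferences unstandardized median differences.
#' @slot pValues raw two-sided Mann-Whitney p-values.
#' @slot pAdjusted Bonferroni-corrected p-values, min(1, p x T).
#' @slot significant logical matrix, pAdjusted < 0.05.
#' @slot control name of the control level.
#' @slot nTreatments number of treatments T used for the correction.
#' @slot rowOrder,colOrder complete-linkage orderings (may be empty).
#' @export
setClass("ScreenHeatmap",
  representation(differences = "matrix", rawDifferences = "matrix",
    pValues = "matrix", pAdjusted = "matrix", significant = "matrix",
    control = "character", nTreatments = "numeric",
    rowOrder = "integer", colOrder = "integer"))

#' Well/position variance components
#'
#' REML estimates from the robustness model: feature value = grand mean +
#' well effect + position-within-well effect + residual, with wells and
#' positions as random effects.
#'
#' @slot feature name of the modelled feature.
#' @slot sigmaWell,sigmaPosition,sigmaResidual standard-deviation estimates
#'   (feature units).
#' @slot nWells,nPositions,nObs design counts.
#' @export
setClass("VarianceComponents",
  representation(feature = "character", sigmaWell = "numeric",
    sigmaPosition = "numeric", sigmaResidual = "numeric",
    nWells = "integer", nPositions = "integer", nObs = "integer"))

setValidity("VarianceComponents", function(object) {
  if (any(c(object@sigmaWell, object@sigmaPosition, object@sigmaResidual) < 0))
    return("variance components must be >= 0")
  TRUE
})
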