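# Accessor generics and show methods for the core classes.

#' @rdname SpheroidStack-class
#' @param x,object a \code{SpheroidStack}.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname SpheroidStack-class
#' @export
setMethod("channelNames", "SpheroidStack", function(x) names(x@channels))

#' @rdname SpheroidStack-class
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname SpheroidStack-class
#' @export
setMethod("bitDepth", "SpheroidStack", function(x) x@bitDepth)

#' @rdname SpheroidStack-class
#' @param channel channel name.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname SpheroidStack-class
#' @export
setMethod("getChannel", "SpheroidStack", function(x, channel) {
  if (!channel %in% names(x@channels))
    stop("no such channel: ", channel)
  x@channels[[channel]]
})

#' @rdname SpheroidStack-class
#' @export
setGeneric("stackDim", function(x) standardGeneric("stackDim"))

#' @rdname SpheroidStack-class
#' @export
setMethod("stackDim", "SpheroidStack", function(x) {
  d <- dim(x@channels[[1]])
  planes <- vapply(x@channels, function(a) dim(a)[3], 1)
  list(height = d[1], width = d[2], planes = planes)
})

setMethod("show", "SpheroidStack", function(object) {
  d <- stackDim(object)
  cat("SpheroidStack:", d$height, "x", d$width, "px,",
      object@bitDepth, "bit\n")
  for (ch in names(object@channels))
    cat("  channel", ch, ":", dim(object@channels[[ch]])[3], "plane(s)\n")
})

setMethod("show", "SegmentationParams", function(object) {
  cat("SegmentationParams\n")
  cat("  sensitivity      :", object@sensitivity, "px\n")
  cat("  thresholdLevel   :", object@thresholdLevel, "\n")
  cat("  gapFillMax       :", object@gapFillMax, "px\n")
  cat("  minStructureSize :", object@minStructureSize, "px\n")
  cat("  radiusQuantile   :", object@radiusQuantile, "\n")
  cat("  channels (structure/apoptosis):", object@structureChannel, "/",
      object@apoptosisChannel, "\n")
})

#' @rdname SpheroidField-class
#' @param x,object a \code{SpheroidField}.
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname SpheroidField-class
#' @export
setMethod("labelMap", "SpheroidField", function(x) x@labels)

#' @rdname SpheroidField-class
#' @export
setGeneric("nStructures", function(x) standardGeneric("nStructures"))

#' @rdname SpheroidField-class
#' @export
setMethod("nStructures", "SpheroidField", function(x) length(x@structures))

#' @rdname SpheroidField-class
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname SpheroidField-class
#' @export
setMethod("records", "SpheroidField", function(x) x@records)

#' @rdname SpheroidField-class
#' @export
setGeneric("structureDetail", function(x) standardGeneric("structureDetail"))

#' @rdname SpheroidField-class
#' @export
setMethod("structureDetail", "SpheroidField", function(x) x@structures)

setMethod("show", "SpheroidField", function(object) {
  cat("SpheroidField", sQuote(object@imageId), ":",
      nrow(object@labels), "x", ncol(object@labels), "px,",
      nStructures(object), "structure(s)\n")
  if (nStructures(object) > 0) {
    cat("  area range:", paste(range(object@records$Area), collapse = " - "),
        "px\n")
  }
})

setMethod("show", "ScreenHeatmap", function(object) {
  cat("ScreenHeatmap:", nrow(object@differences), "treatment(s) x",
      ncol(object@differences), "feature(s), control =",
      sQuote(object@control), "\n")
  cat("  significant cells (Bonferroni p < 0.05):",
      sum(object@significant), "/", length(object@significant), "\n")
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents for", sQuote(object@feature), "\n")
  cat(sprintf("  sigma_well     = %.4f\n", object@sigmaWell))
  cat(sprintf("  sigma_position = %.4f\n", object@sigmaPosition))
  cat(sprintf("  sigma_residual = %.4f\n", object@sigmaResidual))
  cat(sprintf("  well/residual = %.3f, position/residual = %.3f\n",
      object@sigmaWell / object@sigmaResidual,
      object@sigmaPosition / object@sigmaResidual))
})
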