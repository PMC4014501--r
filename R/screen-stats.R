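# Screen statistics: annotation, QC filtering, standardized median-difference
# heatmaps with Bonferroni-corrected Mann-Whitney filtering, Spearman
# correlation maps, complete-linkage clustering, and well/position variance
# components.

#' Annotate morphometry records with plate information
#'
#' Joins the per-structure records to a plate map (one row per image:
#' ImageId plus experimental annotation such as Well, Position, Treatment,
#' Concentration, CellLine). Every image in the records must map to exactly
#' one plate-map row.
#'
#' @param records data.frame of morphometry records (column \code{ImageId}).
#' @param plateMap data.frame with \code{ImageId} and annotation columns.
#' @return annotated data.frame (records columns first).
#' @export
annotateRecords <- function(records, plateMap) {
  stopifnot("ImageId" %in% names(records), "ImageId" %in% names(plateMap))
  dup <- unique(plateMap$ImageId[duplicated(plateMap$ImageId)])
  if (length(dup))
    stop("duplicate plate-map rows for image(s): ",
         paste(dup, collapse = ", "))
  missing <- setdiff(unique(records$ImageId), plateMap$ImageId)
  if (length(missing))
    stop("no plate-map entry for image(s): ",
         paste(missing, collapse = ", "))
  out <- merge(records, plateMap, by = "ImageId", sort = FALSE)
  out[order(match(out$ImageId, unique(records$ImageId)), out$StructureId), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Quality-control rules
#'
#' @param minSize minimum structure area in pixels (rows with
#'   \code{Area < minSize} are rejected; default 0 = no size filter).
#' @param excluded character vector of \code{"ImageId:StructureId"} keys to
#'   discard (the manually generated excluded-features list).
#' @param ranges named list of \code{c(lower, upper)} feature limits.
#' @return list of class \code{"qcRules"}.
#' @export
qcRules <- function(minSize = 0, excluded = character(), ranges = list()) {
  stopifnot(minSize >= 0)
  if (length(ranges))
    stopifnot(!is.null(names(ranges)),
              all(vapply(ranges, length, 1L) == 2L))
  structure(list(minSize = minSize, excluded = excluded, ranges = ranges),
            class = "qcRules")
}

#' Apply QC filtering to an annotated record table
#'
#' Removes erroneously segmented structures, debris and flagged rows: a row
#' is rejected when its Area is below the minimum size, when any feature
#' falls outside a configured range, or when its \code{ImageId:StructureId}
#' key appears on the excluded list. Rejected rows are returned with a
#' reason code.
#'
#' @param table annotated records.
#' @param rules a [qcRules()] object.
#' @return list with \code{clean} (kept rows) and \code{rejected} (dropped
#'   rows with a \code{Reason} column).
#' @export
qcFilter <- function(table, rules = qcRules()) {
  stopifnot(inherits(rules, "qcRules"))
  reason <- rep(NA_character_, nrow(table))
  if (rules$minSize > 0)
    reason[is.na(reason) & table$Area < rules$minSize] <- "min_size"
  for (feat in names(rules$ranges)) {
    v <- table[[feat]]
    if (is.null(v)) stop("range rule for unknown feature: ", feat)
    bad <- v < rules$ranges[[feat]][1] | v > rules$ranges[[feat]][2]
    reason[is.na(reason) & bad] <- paste0("range_", feat)
  }
  if (length(rules$excluded)) {
    key <- paste(table$ImageId, table$StructureId, sep = ":")
    reason[is.na(reason) & key %in% rules$excluded] <- "excluded_list"
  }
  keep <- is.na(reason)
  rejected <- table[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$Reason <- reason[!keep]
  else rejected$Reason <- character(0)
  rownames(rejected) <- NULL
  clean <- table[keep, , drop = FALSE]
  rownames(clean) <- NULL
  list(clean = clean, rejected = rejected)
}

# Mann-Whitney U test p-value: exact for small tie-free samples, normal
# approximation with continuity and tie correction otherwise.
mannWhitneyP <- function(x, y, exactMax = 8) {
  exact <- length(x) <= exactMax && length(y) <= exactMax &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
}

#' Standardized median-difference heatmap with Mann-Whitney filtering
#'
#' For every (treatment, feature) cell, the difference in medians between
#' the treatment and the control is computed; each feature column is then
#' standardized to unit variance across treatments so the color scales of
#' features with different units are comparable. Statistical significance
#' is assessed per cell with the two-sided Mann-Whitney U test against the
#' control, Bonferroni-corrected by multiplication with the number of
#' treatments T; the significance mask applies the p < 0.05 cut after
#' correction. Standardization happens before the p-filtering mask is
#' applied.
#'
#' @param table annotated, QC-filtered record table.
#' @param features character vector of feature columns.
#' @param control name of the control level in \code{treatmentCol}.
#' @param treatmentCol treatment column name (default "Treatment").
#' @param cluster also compute complete-linkage row/column orders.
#' @return a [ScreenHeatmap-class]. Zero-variance feature columns are
#'   standardized to 0 and listed in the \code{flaggedFeatures} attribute.
#' @export
medianDiffHeatmap <- function(table, features, control,
                              treatmentCol = "Treatment", cluster = FALSE) {
  tr <- table[[treatmentCol]]
  if (is.null(tr)) stop("missing treatment column: ", treatmentCol)
  if (!control %in% tr)
    stop("control level ", sQuote(control), " not present in ",
         treatmentCol)
  ctrl <- table[tr == control, , drop = FALSE]
  if (nrow(ctrl) < 2) stop("control needs at least 2 observations")
  treatments <- setdiff(unique(tr), control)
  Tn <- length(treatments)
  if (Tn < 1) stop("need at least one non-control treatment")
  stopifnot(all(features %in% names(table)))
  d <- matrix(NA_real_, Tn, length(features),
              dimnames = list(treatments, features))
  p <- d
  for (ti in seq_len(Tn)) {
    grp <- table[tr == treatments[ti], , drop = FALSE]
    for (fi in seq_along(features)) {
      xv <- grp[[features[fi]]]
      yv <- ctrl[[features[fi]]]
      d[ti, fi] <- stats::median(xv) - stats::median(yv)
      p[ti, fi] <- mannWhitneyP(xv, yv)
    }
  }
  flagged <- character(0)
  z <- d
  for (fi in seq_along(features)) {
    s <- if (Tn > 1) stats::sd(d[, fi]) else abs(d[1, fi])
    if (!is.finite(s) || s == 0) {
      z[, fi] <- 0
      flagged <- c(flagged, features[fi])
    } else {
      z[, fi] <- d[, fi] / s
    }
  }
  padj <- p
  padj[] <- pmin(1, p * Tn)
  ro <- integer(0); co <- integer(0)
  if (cluster && Tn > 1) ro <- clusterMatrix(z, "rows")$order
  if (cluster && length(features) > 1) co <- clusterMatrix(z, "cols")$order
  sig <- padj
  sig[] <- padj < 0.05
  mode(sig) <- "logical"
  out <- new("ScreenHeatmap", differences = z, rawDifferences = d,
             pValues = p, pAdjusted = padj, significant = sig,
             control = control, nTreatments = Tn,
             rowOrder = as.integer(ro), colOrder = as.integer(co))
  attr(out, "flaggedFeatures") <- flagged
  out
}

#' Spearman parameter-correlation map
#'
#' Pairwise Spearman rank correlation (average ranks on ties) between
#' feature columns; symmetric with unit diagonal. Constant features yield
#' undefined correlations, recorded as 0 and flagged.
#'
#' @param table record table.
#' @param features feature columns (default: all catalogue columns present).
#' @return correlation matrix with attribute \code{flaggedFeatures}.
#' @export
spearmanMap <- function(table, features = intersect(recordColumns(),
                                                    names(table))) {
  m <- as.matrix(table[, features, drop = FALSE])
  if (nrow(m) < 3) stop("need at least 3 observations")
  constant <- apply(m, 2, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(stats::cor(m, method = "spearman"))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 1
  attr(rho, "flaggedFeatures") <- features[constant]
  rho
}

#' Complete-linkage clustering of a heatmap matrix
#'
#' Agglomerative clustering with complete linkage of Euclidean distances
#' over rows or columns, as used to order heatmap axes. stats::hclust
#' merges are deterministic (ties broken by lower index).
#'
#' @param m numeric matrix.
#' @param axis \code{"rows"} or \code{"cols"}.
#' @return list with \code{order} (permutation), \code{hclust} (the tree),
#'   \code{height} (merge heights).
#' @export
clusterMatrix <- function(m, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  if (axis == "cols") m <- t(m)
  if (!all(is.finite(m))) stop("matrix must be finite")
  if (nrow(m) == 1)
    return(list(order = 1L, hclust = NULL, height = numeric(0)))
  hc <- stats::hclust(stats::dist(m), method = "complete")
  list(order = hc$order, hclust = hc, height = hc$height)
}

#' Well/position variance components (robustness QC)
#'
#' Fits the reproducibility model — feature = grand mean + random well
#' effect + random position-within-well effect + residual — by REML
#' (\pkg{lme4}) and reports the three standard deviations. A screen is
#' considered robust when the well and position components are consistently
#' smaller than the residual error.
#'
#' @param table annotated record table.
#' @param feature feature column to model.
#' @param wellCol,positionCol annotation column names.
#' @return a [VarianceComponents-class].
#' @export
varianceComponents <- function(table, feature, wellCol = "Well",
                               positionCol = "Position") {
  y <- table[[feature]]
  if (is.null(y)) stop("unknown feature: ", feature)
  well <- factor(table[[wellCol]])
  pos <- factor(paste(well, table[[positionCol]], sep = "/"))
  if (nlevels(well) < 3)
    stop("need at least 3 wells (got ", nlevels(well), ")")
  posPerWell <- tapply(pos, well, function(p) length(unique(p)))
  if (any(posPerWell < 2))
    stop("need at least 2 positions per well")
  obsPerPos <- table(pos)
  if (any(obsPerPos < 2))
    stop("need at least 2 observations per position")
  mk <- function(sw, sp, se) new("VarianceComponents", feature = feature,
    sigmaWell = sw, sigmaPosition = sp, sigmaResidual = se,
    nWells = nlevels(well), nPositions = nlevels(pos),
    nObs = length(y))
  if (stats::var(y) == 0) return(mk(0, 0, 0))
  df <- data.frame(y = y, well = well, pos = pos)
  fit <- lme4::lmer(y ~ 1 + (1 | well) + (1 | pos), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sdOf <- function(g) vc$sdcor[vc$grp == g]
  mk(sdOf("well"), sdOf("pos"), sdOf("Residual"))
}

#' @rdname varianceComponents
#' @param x a \code{VarianceComponents} object.
#' @return \code{varianceRatios}: named vector of well/residual and
#'   position/residual sd ratios.
#' @export
varianceRatios <- function(x) {
  stopifnot(is(x, "VarianceComponents"))
  c(wellToResidual = x@sigmaWell / x@sigmaResidual,
    positionToResidual = x@sigmaPosition / x@sigmaResidual)
}
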