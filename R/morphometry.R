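# Per-structure parameter catalogue: geometry (center of mass, edge-distance
# set, quantile radius), shape, appendage, neighborhood and per-channel
# features. Coordinates are x = column, y = row (reported 0-based in output
# files, 1-based internally).

#' Structure geometry: center of mass, edge-distance set, radius
#'
#' The center of mass is the mean of the structure's pixel coordinates; edge
#' pixels are foreground pixels with at least one background 4-neighbor
#' (image borders count as background); the edge-distance set D holds the
#' Euclidean distances from the center to every edge pixel; the radius is
#' the empirical m-quantile of D (default m = 0.25).
#'
#' @param structureMask binary matrix of one structure.
#' @param m radius quantile in (0, 1).
#' @return list with \code{center} (c(x, y)), \code{edge} (matrix of y, x),
#'   \code{D} (distances), \code{radius}.
#' @export
structureGeometry <- function(structureMask, m = 0.25) {
  idx <- which(structureMask == 1)
  if (length(idx) == 0) stop("empty structure")
  h <- nrow(structureMask)
  py <- (idx - 1L) %% h + 1L
  px <- (idx - 1L) %/% h + 1L
  cx <- mean(px); cy <- mean(py)
  edge <- idx[isEdgePixel(structureMask)[idx]]
  ey <- (edge - 1L) %% h + 1L
  ex <- (edge - 1L) %/% h + 1L
  D <- sqrt((ex - cx)^2 + (ey - cy)^2)
  list(center = c(x = cx, y = cy), edge = cbind(y = ey, x = ex), D = D,
       radius = unname(stats::quantile(D, m, names = FALSE)))
}

# foreground pixels with >= 1 background 4-neighbor (borders are background)
isEdgePixel <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  up <- rbind(0, mask[-h, , drop = FALSE])
  dn <- rbind(mask[-1, , drop = FALSE], 0)
  lf <- cbind(0, mask[, -w, drop = FALSE])
  rt <- cbind(mask[, -1, drop = FALSE], 0)
  mask == 1 & (up == 0 | dn == 0 | lf == 0 | rt == 0)
}

#' Shape features: Area, Roundness, FiltRound, RoundDiff, Roughness
#'
#' Area is the pixel count. Roundness (percent) is the edge-distance
#' coefficient-of-variation form 100 x max(0, 1 - sd(D)/mean(D)); a perfect
#' disk scores near 100. FiltRound is the Roundness of the opened body mask
#' (outline features filtered away); RoundDiff = FiltRound - Roundness, so
#' appendaged structures whose body is rounder than the whole score positive.
#' Roughness (percent) is 100 x mean(|D - Ds|)/mean(D), where Ds is the
#' edge-distance sequence ordered by polar angle and smoothed with a
#' circular moving average (window 15): small-scale contour ripple distinct
#' from appendages. An isoperimetric Roundness (4 pi A / P^2) is available
#' via \code{roundnessMethod = "isoperimetric"} in the parameters.
#'
#' @param structureMask binary matrix of one structure.
#' @param geom its [structureGeometry()].
#' @param body body mask from [bodyAppendages()] (NULL to skip FiltRound).
#' @param params a [SegmentationParams-class].
#' @return named numeric vector (Area, Roundness, FiltRound, RoundDiff,
#'   Roughness).
#' @export
shapeFeatures <- function(structureMask, geom, body = NULL,
                          params = segmentationParams()) {
  area <- sum(structureMask)
  rnd <- roundnessOf(structureMask, geom, params)
  if (is.null(body) || sum(body) == 0 ||
      identical(sum(body), area) && all(body == structureMask)) {
    filt <- rnd
  } else {
    bg <- structureGeometry(body, params@radiusQuantile)
    filt <- roundnessOf(body, bg, params)
  }
  c(Area = area, Roundness = rnd, FiltRound = filt,
    RoundDiff = filt - rnd, Roughness = roughnessOf(geom))
}

roundnessOf <- function(mask, geom, params) {
  if (params@roundnessMethod == "isoperimetric") {
    P <- nrow(geom$edge)
    if (P == 0) return(100)
    return(min(100, 100 * 4 * pi * sum(mask) / P^2))
  }
  D <- geom$D
  mu <- mean(D)
  if (!is.finite(mu) || mu <= 0) return(100)  # single-pixel structure
  100 * max(0, 1 - stats::sd(D) / mu)
}

roughnessOf <- function(geom, window = 15) {
  D <- geom$D
  n <- length(D)
  mu <- mean(D)
  if (n < 3 || mu <= 0) return(0)
  ang <- atan2(geom$edge[, "y"] - geom$center["y"],
               geom$edge[, "x"] - geom$center["x"])
  D <- D[order(ang)]
  w <- min(window, n)
  if (w %% 2 == 0) w <- w - 1
  r <- (w - 1) / 2
  ext <- c(D[(n - r + 1):n], D, D[1:r])
  Ds <- vapply(seq_len(n), function(i) mean(ext[i:(i + w - 1)]), numeric(1))
  100 * mean(abs(D - Ds)) / mu
}

#' Appendage features: AppIndex, MaxApp, MedApp, AppNumber
#'
#' Each appendage's length is the maximum over its pixels of the Euclidean
#' distance to the nearest body pixel. AppNumber counts the appendage
#' components, MaxApp/MedApp summarize their lengths (0 when none), and
#' AppIndex is the total appendage area divided by the body area — the
#' severity-of-invasion index.
#'
#' @param body binary body mask.
#' @param appendages list of pixel-index vectors (column-major into the same
#'   matrix), from [bodyAppendages()].
#' @return named numeric vector (AppIndex, MaxApp, MedApp, AppNumber).
#' @export
appendageFeatures <- function(body, appendages) {
  nApp <- length(appendages)
  if (nApp == 0 || sum(body) == 0)
    return(c(AppIndex = 0, MaxApp = 0, MedApp = 0, AppNumber = 0))
  dToBody <- EBImage::distmap(1 - body)
  lens <- vapply(appendages, function(pix) max(dToBody[pix]), numeric(1))
  appArea <- sum(lengths(appendages))
  c(AppIndex = appArea / sum(body), MaxApp = max(lens),
    MedApp = stats::median(lens), AppNumber = nApp)
}

#' Neighborhood features: Closest, Neighbors, SharedBound, CellRatio
#'
#' Closest is the center-to-center Euclidean distance to the nearest other
#' structure (-1 when the field holds a single structure); Neighbors counts
#' the distinct labels 8-adjacent to the structure; SharedBound counts the
#' structure's pixels that are 8-adjacent to any neighboring label;
#' CellRatio is the global foreground fraction, 100 x (sum of structure
#' areas) / (W x H), identical for every row of a field.
#'
#' @param labels integer label matrix.
#' @param centers N x 2 matrix of structure centers (x, y).
#' @return data.frame with one row per structure (Closest, Neighbors,
#'   SharedBound, CellRatio).
#' @export
neighborFeatures <- function(labels, centers) {
  n <- max(labels)
  if (n == 0)
    return(data.frame(Closest = numeric(0), Neighbors = numeric(0),
                      SharedBound = numeric(0), CellRatio = numeric(0)))
  if (n == 1) {
    closest <- -1
  } else {
    dm <- as.matrix(stats::dist(centers))
    diag(dm) <- Inf
    closest <- apply(dm, 1, min)
  }
  shared <- matrix(FALSE, nrow(labels), ncol(labels))
  pairs <- NULL
  h <- nrow(labels); w <- ncol(labels)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    B <- shiftMat(labels, s[1], s[2])
    touch <- labels > 0 & B > 0 & labels != B
    shared <- shared | touch
    if (any(touch))
      pairs <- rbind(pairs, unique(cbind(labels[touch], B[touch])))
  }
  neighbors <- integer(n)
  sharedBound <- integer(n)
  if (!is.null(pairs)) {
    pairs <- unique(pairs)
    tb <- table(factor(pairs[, 1], levels = seq_len(n)))
    neighbors <- as.integer(tb)
  }
  if (any(shared)) {
    tb <- table(factor(labels[shared], levels = seq_len(n)))
    sharedBound <- as.integer(tb)
  }
  data.frame(Closest = as.numeric(closest), Neighbors = neighbors,
             SharedBound = sharedBound,
             CellRatio = 100 * sum(labels > 0) / (h * w))
}

shiftMat <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Channel features: Density, Deviation, AreaRatio, Hollowness, CellNumber,
#' AveArea
#'
#' Density is the mean channel intensity over the structure (gray levels per
#' pixel) and Deviation its standard deviation (reported unitless). AreaRatio
#' is the percentage of the structure area covered by segmented cells in the
#' channel — for the red (dead/apoptotic) channel this is the cytotoxicity
#' readout AreaRatioR. CellNumber and AveArea count and size the channel's
#' cells. Hollowness contrasts the structure core against its rim:
#' 100 x max(0, 1 - mean(core)/mean(rim)), with the core the pixels within
#' half the structure radius of the center of mass — high for polarized,
#' lumen-forming structures, near 0 for filled ones.
#'
#' @param structureMask binary matrix of one structure.
#' @param channelImage matching matrix of channel gray levels.
#' @param cells cell label matrix from [segmentCells()].
#' @param geom the structure's [structureGeometry()].
#' @return named numeric vector (Density, Deviation, AreaRatio, Hollowness,
#'   CellNumber, AveArea).
#' @export
channelFeatures <- function(structureMask, channelImage, cells, geom) {
  idx <- which(structureMask == 1)
  vals <- channelImage[idx]
  area <- length(idx)
  dens <- mean(vals)
  dev <- if (area > 1) stats::sd(vals) else 0
  cellArea <- sum(cells > 0)
  cellNumber <- max(cells, 0)
  aveArea <- if (cellNumber > 0) cellArea / cellNumber else 0
  # core/rim split at 50% of the quantile radius
  h <- nrow(structureMask)
  py <- (idx - 1L) %% h + 1L
  px <- (idx - 1L) %/% h + 1L
  r2 <- (px - geom$center["x"])^2 + (py - geom$center["y"])^2
  core <- r2 <= (0.5 * geom$radius)^2
  if (!any(core) || all(core) || mean(vals[!core]) <= 0) {
    hollow <- 0
  } else {
    hollow <- 100 * max(0, 1 - mean(vals[core]) / mean(vals[!core]))
  }
  c(Density = dens, Deviation = dev, AreaRatio = 100 * cellArea / area,
    Hollowness = hollow, CellNumber = cellNumber, AveArea = aveArea)
}

#' The morphometric parameter catalogue
#'
#' The 19 named parameters written to the result file, with the per-channel
#' ones ({R, G}) expanded into suffixed columns (e.g. \code{AreaRatioR}),
#' giving 24 feature columns per structure. The center of mass and the
#' quantile radius are computed internally but not part of the result file.
#'
#' @return data.frame with columns \code{name}, \code{perChannel},
#'   \code{unit}.
#' @examples
#' nrow(morphometryCatalog())  # 19 named parameters
#' @export
morphometryCatalog <- function() {
  data.frame(
    name = c("Area", "Roundness", "FiltRound", "RoundDiff", "AppIndex",
             "MaxApp", "MedApp", "Roughness", "AppNumber", "Deviation",
             "Closest", "Neighbors", "SharedBound", "CellRatio",
             "Density", "AreaRatio", "Hollowness", "CellNumber", "AveArea"),
    perChannel = c(rep(FALSE, 14), rep(TRUE, 5)),
    unit = c("px", "%", "%", "%", "ratio", "px", "px", "%", "count",
             "unitless", "px", "count", "px", "%",
             "gray/px", "%", "%", "count", "px"))
}

#' @rdname morphometryCatalog
#' @return \code{recordColumns()}: the ordered feature column names of a
#'   morphometry record.
#' @export
recordColumns <- function() {
  cat_ <- morphometryCatalog()
  common <- cat_$name[!cat_$perChannel]
  perch <- cat_$name[cat_$perChannel]
  c(common, as.vector(t(outer(perch, c("R", "G"), paste0))))
}
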