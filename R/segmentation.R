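# Two-phase segmentation: preliminary structure labeling
# (threshold -> gap fill -> opening -> EDT -> watershed) and substructural
# cell/appendage segmentation per channel.
#
# Masks are H x W matrices in {0,1}; label maps are integer H x W matrices
# with 0 = background and contiguous labels 1..N. Foreground labels are
# 8-connected; background holes are 4-connected (standard duality).

discBrush <- function(radius) EBImage::makeBrush(2 * radius + 1, "disc")

binOpen <- function(mask, radius) {
  if (radius < 1) return(mask)
  EBImage::opening(mask, discBrush(radius))
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so diagonal-adjacent
# label pairs are merged with a small union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  k <- max(lab)
  if (k <= 1) return(matrix(as.integer(lab), nrow(mask)))
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]     # \ diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]     # / diagonal
  sel1 <- a1 > 0 & b1 > 0 & a1 != b1
  sel2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[i]; i }
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(k), find, 1L)
  # contiguous relabeling ordered by first pixel (column-major) of each group
  first <- vapply(split(seq_along(lab)[lab > 0], root[lab[lab > 0]]), min, 1)
  ord <- order(first)
  newId <- integer(k)
  newId[as.integer(names(first))[ord]] <- seq_along(ord)
  out <- matrix(0L, h, w)
  nz <- lab > 0
  out[nz] <- newId[root[lab[nz]]]
  out
}

# Otsu threshold on a 256-bin histogram of the supplied values; returns the
# gray level maximizing between-class variance (first maximum on ties).
otsuThreshold <- function(values, nbins = 256, range = base::range(values)) {
  if (diff(range) <= 0) return(range[1])
  br <- seq(range[1], range[2], length.out = nbins + 1)
  cnt <- tabulate(findInterval(values, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins)
  p <- cnt / sum(cnt)
  mids <- (br[-1] + br[-(nbins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  bcv <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- 0
  br[which.max(bcv) + 1L] - diff(br)[1] / 2
}

#' Histogram-valley threshold
#'
#' Global thresholding for fluorescence fields with dark background: the
#' 256-bin intensity histogram is smoothed with a Gaussian (sigma in bins),
#' the two dominant peaks are located, and the cut is placed at the deepest
#' valley between them (middle of the minimal run when the valley is flat).
#' The \code{thresholdLevel} stringency shifts the cut upward: level L puts
#' it at valley + (L - 1) x 2\% of the dynamic range, so higher levels give
#' a more stringent (smaller) foreground. If the histogram is unimodal the
#' function falls back to Otsu's method with a warning; a constant image
#' yields an empty mask with a warning.
#'
#' @param gray H x W numeric matrix of gray levels.
#' @param thresholdLevel stringency level, >= 1 (default 1).
#' @param smoothSigma Gaussian sigma in histogram bins (default 3).
#' @param nbins number of histogram bins (default 256; 16-bit data are
#'   binned, not truncated).
#' @param fullScale dynamic range ceiling; default 255 for data within
#'   8 bits, 65535 otherwise.
#' @return binary H x W matrix (1 = foreground) with attributes
#'   \code{threshold} (the effective cut in gray levels) and \code{method}
#'   (\code{"valley"}, \code{"otsu"} or \code{"constant"}).
#' @export
valleyThreshold <- function(gray, thresholdLevel = 1, smoothSigma = 3,
                            nbins = 256, fullScale = NULL) {
  if (is.null(fullScale)) fullScale <- if (max(gray) > 255) 65535 else 255
  rng <- range(gray)
  empty <- function(method) {
    m <- matrix(0, nrow(gray), ncol(gray))
    attr(m, "threshold") <- NA_real_; attr(m, "method") <- method
    m
  }
  if (diff(rng) <= 0) {
    warning("constant image: returning empty mask")
    return(empty("constant"))
  }
  br <- seq(0, fullScale, length.out = nbins + 1)
  cnt <- tabulate(findInterval(gray, br, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins)
  # mode method: smooth repeatedly until the histogram is bimodal, so the
  # valley is searched between genuine modes rather than between noise
  # wiggles of a broad background hump; zero-height plateau artifacts at
  # the range ends are not peaks
  s1 <- gaussSmooth(cnt, smoothSigma)
  win <- 3 * max(1, smoothSigma)
  # a mode must carry real mass: isolated outlier bins are not peaks
  minPeak <- 0.1 * mean(cnt)
  sigPeaks <- function(s) {
    pk <- histPeaks(s)
    pk[vapply(pk, function(i)
      max(s1[max(1, i - win):min(nbins, i + win)]), numeric(1)) > minPeak]
  }
  s <- s1
  pk <- sigPeaks(s)
  iter <- 0L
  while (length(pk) > 2 && iter < 60L) {
    s <- gaussSmooth(s, smoothSigma)
    pk <- sigPeaks(s)
    iter <- iter + 1L
  }
  cut <- NA_real_
  otsuFallback <- function() {
    warning("histogram not bimodal: falling back to Otsu threshold")
    otsuThreshold(as.vector(gray), nbins, range = c(0, fullScale))
  }
  if (length(pk) >= 2) {
    # deepest valley between adjacent surviving peaks; clipping spikes at
    # the range ends then cannot displace the background/foreground gap,
    # which is always the deepest (often exactly empty) valley
    best <- NULL
    for (q in seq_len(length(pk) - 1)) {
      between <- seq(pk[q], pk[q + 1])
      vmin <- min(s[between])
      score <- c(vmin, -(s[pk[q]] + s[pk[q + 1]]))
      if (is.null(best) || score[1] < best$score[1] ||
          (score[1] == best$score[1] && score[2] < best$score[2]))
        best <- list(score = score, between = between, vmin = vmin)
    }
    # significance of the dip, judged on the lightly smoothed histogram
    # (iterated smoothing flattens narrow foreground spikes)
    p1 <- best$between[1]; p2 <- best$between[length(best$between)]
    ph <- c(max(s1[max(1, p1 - win):min(nbins, p1 + win)]),
            max(s1[max(1, p2 - win):min(nbins, p2 + win)]))
    vmin1 <- min(s1[best$between])
    if (vmin1 > 0.5 * min(ph)) {
      cut <- otsuFallback()
      method <- "otsu"
    } else {
      run <- best$between[s[best$between] == best$vmin]
      valleyBin <- run[ceiling(length(run) / 2)]
      cut <- (br[valleyBin] + br[valleyBin + 1]) / 2
      method <- "valley"
    }
  } else {
    cut <- otsuFallback()
    method <- "otsu"
  }
  cut <- cut + (thresholdLevel - 1) * 0.02 * fullScale
  m <- (gray > cut) * 1
  attr(m, "threshold") <- cut
  attr(m, "method") <- method
  m
}

# interior local maxima (left-strict, right-slack so plateaus count once)
histPeaks <- function(s) {
  which(diff(c(-Inf, s)) > 0 & diff(c(s, -Inf)) <= 0)
}

gaussSmooth <- function(counts, sigma) {
  if (sigma <= 0) return(counts)
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  n <- length(counts)
  padded <- c(rep(0, r), counts, rep(0, r))
  out <- numeric(n)
  # normalize by in-range kernel mass so edge bins are not deflated
  for (i in seq_len(n)) {
    win <- padded[i:(i + 2 * r)]
    inr <- (i - r):(i + r) >= 1 & (i - r):(i + r) <= n
    out[i] <- sum(win * k) / sum(k[inr])
  }
  out
}

#' Fill small background gaps inside foreground structures
#'
#' Low-intensity interior regions (e.g. hollow lumens) appear as background
#' holes after thresholding. Background connected components (4-connected)
#' that are fully enclosed by foreground and strictly smaller than
#' \code{maxGap} pixels are set to foreground; a hole of exactly
#' \code{maxGap} pixels is retained.
#'
#' @param mask binary H x W matrix.
#' @param maxGap hole-size bound in pixels (default 1000).
#' @return binary matrix with qualifying holes filled.
#' @export
fillGaps <- function(mask, maxGap = 1000) {
  if (maxGap < 0) stop("maxGap must be >= 0")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  bg <- EBImage::bwlabel(1 - mask)          # 4-connected background
  k <- max(bg)
  if (k == 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  borderLabs <- unique(c(bg[1, ], bg[h, ], bg[, 1], bg[, w]))
  sizes <- tabulate(bg[bg > 0], k)
  fill <- setdiff(which(sizes < maxGap), borderLabs)
  if (length(fill)) mask[bg %in% fill] <- 1
  mask
}

# Regional maxima of a distance map: positive pixels equal to their 3x3
# grayscale dilation (plateaus included).
regionalMaxima <- function(d) {
  dil <- EBImage::dilate(d, EBImage::makeBrush(3, "box"))
  d > 0 & d >= dil
}

#' Watershed labeling by merged distance-map seeds
#'
#' Labels the foreground of a binary mask: within each 8-connected component
#' the Euclidean distance transform of the (optionally opened) component is
#' computed, its regional maxima are merged by single linkage whenever closer
#' than \code{sensitivity} pixels, and every component pixel is assigned to
#' the nearest resulting seed (Euclidean distance, ties to the lower seed
#' label). The \code{sensitivity} knob thus directly controls over- versus
#' under-splitting of touching structures. When \code{openingRadius >= 1}
#' the seeds are derived from the morphologically opened component, so thin
#' protrusions do not seed spurious splits, while the labels still cover the
#' full (unopened) mask.
#'
#' @param mask binary H x W matrix.
#' @param sensitivity seed-merging distance in pixels (> 0).
#' @param openingRadius disc radius for the pre-seeding opening (0 disables).
#' @return integer label matrix (0 background, labels 1..N) with attribute
#'   \code{seeds}: a data.frame of seed label, y and x (1-based rows/cols).
#' @export
watershedLabel <- function(mask, sensitivity = 20, openingRadius = 0) {
  stopifnot(sensitivity > 0)
  comps <- label8(mask)
  ncomp <- max(comps)
  out <- matrix(0L, nrow(mask), ncol(mask))
  seedList <- list()
  nextLab <- 0L
  h <- nrow(mask)
  for (ci in seq_len(ncomp)) {
    idx <- which(comps == ci)
    py <- (idx - 1L) %% h + 1L
    px <- (idx - 1L) %/% h + 1L
    y0 <- min(py); y1 <- max(py); x0 <- min(px); x1 <- max(px)
    cmask <- matrix(0, y1 - y0 + 3, x1 - x0 + 3)  # 1-px pad
    cmask[cbind(py - y0 + 2L, px - x0 + 2L)] <- 1
    seeds <- componentSeeds(cmask, sensitivity, openingRadius)
    sy <- seeds[, 1] + y0 - 2L; sx <- seeds[, 2] + x0 - 2L
    k <- nrow(seeds)
    if (k == 1L) {
      assign <- rep.int(1L, length(idx))
    } else {
      D <- outer(py, sy, "-")^2 + outer(px, sx, "-")^2
      assign <- max.col(-D, ties.method = "first")
    }
    out[idx] <- nextLab + assign
    seedList[[ci]] <- cbind(label = nextLab + seq_len(k), y = sy, x = sx)
    nextLab <- nextLab + k
  }
  attr(out, "seeds") <- as.data.frame(do.call(rbind, seedList))
  out
}

# Seeds for one padded component mask: EDT regional maxima of the opened
# mask, single-linkage clustered at the sensitivity distance; seed = cluster
# centroid. Falls back to the EDT maximum of the unopened mask when opening
# empties the component. Returns a matrix of (y, x) rows ordered by first
# member pixel, so labels are deterministic.
componentSeeds <- function(cmask, sensitivity, openingRadius) {
  op <- if (openingRadius >= 1) binOpen(cmask, openingRadius) else cmask
  if (sum(op) == 0) {
    d <- EBImage::distmap(cmask)
    i <- which.max(d)
    return(cbind((i - 1L) %% nrow(d) + 1L, (i - 1L) %/% nrow(d) + 1L))
  }
  d <- EBImage::distmap(op)
  rm <- which(regionalMaxima(d))
  my <- (rm - 1L) %% nrow(d) + 1L
  mx <- (rm - 1L) %/% nrow(d) + 1L
  if (length(rm) == 1L) return(cbind(my, mx))
  cl <- stats::cutree(stats::hclust(stats::dist(cbind(my, mx)), "single"),
                      h = sensitivity - 1e-9)
  groups <- split(seq_along(cl), cl)
  # prominence filter: a cluster whose distance-map peak is thinner than the
  # opening scale is ridge residue (e.g. a surviving thin protrusion), not a
  # structure center; keep at least the most prominent cluster
  if (openingRadius >= 1) {
    peak <- vapply(groups, function(g) max(d[rm[g]]), numeric(1))
    ok <- peak >= openingRadius + 1
    if (!any(ok)) ok <- peak == max(peak)
    groups <- groups[ok]
  }
  ord <- order(vapply(groups, min, 1))
  groups <- groups[ord]
  t(vapply(groups, function(g)
    c(round(mean(my[g])), round(mean(mx[g]))), numeric(2)))
}

#' Preliminary structure segmentation
#'
#' Full preliminary phase on a gap-filled binary mask: morphological opening
#' (disc, \code{openingRadius}) to separate touching structures, Euclidean
#' distance transform, watershed labeling with seed merging at the
#' \code{sensitivity} distance, and removal of objects smaller than
#' \code{minStructureSize} pixels. Labels are contiguous 1..N.
#'
#' @param mask binary H x W matrix (from [fillGaps()]).
#' @param params a [SegmentationParams-class].
#' @return integer label matrix.
#' @export
segmentStructures <- function(mask, params = segmentationParams()) {
  if (sum(mask) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- watershedLabel(mask, params@sensitivity, params@openingRadius)
  relabelBySize(lab, params@minStructureSize)
}

relabelBySize <- function(lab, minSize) {
  k <- max(lab)
  if (k == 0) return(lab)
  sizes <- tabulate(lab[lab > 0], k)
  keep <- which(sizes >= minSize)
  newId <- integer(k)
  newId[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- newId[lab[nz]]
  out
}

#' Per-structure focus-plane threshold adjustment
#'
#' For 3D input, each structure's focus plane is the z-plane maximizing the
#' intensity variance over the structure's pixels. The structure's threshold
#' is then recomputed on that plane's histogram restricted to the structure's
#' bounding box, and the structure's foreground pixels re-evaluated against
#' the local cut. Structures are only ever shrunk, never split or removed
#' (an empty re-evaluation keeps the original pixels), so the label count is
#' preserved. Depth-1 stacks are returned unchanged with a notice.
#'
#' @param stack the [SpheroidStack-class] the mask came from.
#' @param labels integer label matrix from [segmentStructures()].
#' @param baseMask the global binary mask.
#' @param params a [SegmentationParams-class].
#' @return list with elements \code{mask} (adjusted binary mask),
#'   \code{focusPlanes} (per-structure plane index) and \code{thresholds}
#'   (per-structure local cut in gray levels).
#' @export
focusAdjust <- function(stack, labels, baseMask,
                        params = segmentationParams()) {
  ch <- params@structureChannel
  if (!ch %in% channelNames(stack)) ch <- channelNames(stack)[1]
  a <- stack@channels[[ch]]
  n <- max(labels)
  if (dim(a)[3] == 1L) {
    message("depth-1 stack: focus adjustment is the identity")
    return(list(mask = baseMask, focusPlanes = rep(1L, n),
                thresholds = rep(NA_real_, n)))
  }
  h <- nrow(labels)
  fullScale <- if (max(a) > 255) 65535 else 255
  focusPlanes <- integer(n)
  thresholds <- numeric(n)
  mask <- baseMask
  for (i in seq_len(n)) {
    idx <- which(labels == i)
    py <- (idx - 1L) %% h + 1L; px <- (idx - 1L) %/% h + 1L
    planeVar <- vapply(seq_len(dim(a)[3]), function(z)
      stats::var(a[cbind(py, px, z)]), numeric(1))
    fp <- which.max(planeVar)
    focusPlanes[i] <- fp
    box <- a[min(py):max(py), min(px):max(px), fp]
    lm <- suppressWarnings(
      valleyThreshold(box, params@thresholdLevel, params@smoothSigma,
                      fullScale = fullScale))
    cut <- attr(lm, "threshold")
    thresholds[i] <- cut
    if (is.na(cut)) next
    keep <- a[cbind(py, px, fp)] > cut
    if (!any(keep)) next                    # never erase a structure
    mask[idx[!keep]] <- 0
  }
  list(mask = mask, focusPlanes = focusPlanes, thresholds = thresholds)
}

#' Substructural (cell-level) segmentation within one structure
#'
#' Otsu's threshold is computed on the 256-bin histogram of the channel
#' intensities inside the structure only, the resulting cell mask is cleaned
#' by an adaptive opening whose disc radius scales with the structure
#' equivalent diameter (\code{cellKernelScale}, minimum 1 px), and touching
#' cells are split by the same distance-transform watershed used for
#' structures, with a cell-scale merge distance. Applied to the green and
#' red channels separately.
#'
#' @param structureMask binary matrix (a single structure; may be a
#'   bounding-box crop).
#' @param channelImage matching matrix of channel gray levels.
#' @param params a [SegmentationParams-class].
#' @return integer label matrix of cells inside the structure, with
#'   attribute \code{flagged} = TRUE when the channel is uniform inside the
#'   structure (zero cells).
#' @export
segmentCells <- function(structureMask, channelImage,
                         params = segmentationParams()) {
  idx <- structureMask == 1
  vals <- channelImage[idx]
  zero <- function(flag) {
    z <- matrix(0L, nrow(structureMask), ncol(structureMask))
    attr(z, "flagged") <- flag
    z
  }
  if (length(vals) == 0) return(zero(TRUE))
  if (diff(range(vals)) <= 0 || stats::sd(vals) < 1e-12) return(zero(TRUE))
  cut <- otsuThreshold(vals)
  # noise guard: Otsu partitions any histogram, so only accept the partition
  # as cells when the between-class contrast is a real fraction of the
  # in-structure intensity range
  hi <- vals[vals > cut]; lo <- vals[vals <= cut]
  if (!length(hi) || !length(lo) ||
      (mean(hi) - mean(lo)) < params@cellContrastMin * diff(range(vals)))
    return(zero(FALSE))
  cells <- (channelImage > cut) * structureMask
  if (sum(cells) == 0) return(zero(TRUE))
  equivDiam <- 2 * sqrt(sum(structureMask) / pi)
  r <- min(params@cellKernelMax,
           max(1, round(params@cellKernelScale * equivDiam)))
  op <- binOpen(cells, r)
  if (sum(op) == 0) return(zero(FALSE))
  lab <- watershedLabel(op, sensitivity = max(4, 2 * r))
  attr(lab, "flagged") <- FALSE
  lab
}

#' Body/appendage decomposition of a structure
#'
#' The structure body is the adaptive morphological opening of its mask
#' (disc radius = \code{bodyKernelScale} x equivalent diameter); invasive
#' appendages are the 8-connected components of the remainder that touch the
#' body and contain at least \code{minAppendageSize} pixels. Sub-kernel
#' boundary ripple is thereby absorbed into the body rather than counted as
#' appendages. If the opening empties the mask entirely (thin, all-appendage
#' structures) the body falls back to the whole structure and the result is
#' flagged.
#'
#' @param structureMask binary matrix of one structure.
#' @param params a [SegmentationParams-class].
#' @return list with \code{body} (binary matrix), \code{appendages} (list of
#'   pixel-index vectors, column-major), and \code{flagged}.
#' @export
bodyAppendages <- function(structureMask, params = segmentationParams()) {
  area <- sum(structureMask)
  if (area == 0)
    return(list(body = structureMask, appendages = list(), flagged = TRUE))
  equivDiam <- 2 * sqrt(area / pi)
  r <- max(1, round(params@bodyKernelScale * equivDiam))
  body <- binOpen(structureMask, r)
  flagged <- FALSE
  if (sum(body) == 0) {
    body <- structureMask
    flagged <- TRUE
  }
  rest <- structureMask * (1 - body)
  apps <- list()
  if (sum(rest) > 0) {
    lab <- label8(rest)
    touch <- EBImage::dilate(body, EBImage::makeBrush(3, "box"))
    for (i in seq_len(max(lab))) {
      pix <- which(lab == i)
      if (length(pix) >= params@minAppendageSize && any(touch[pix] > 0))
        apps[[length(apps) + 1L]] <- pix
    }
  }
  list(body = body, appendages = apps, flagged = flagged)
}
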