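# Image input, projection, grayscale conversion, normalization, denoising.
# Internal convention: images are H x W numeric matrices (row = y, col = x);
# stacks are H x W x planes arrays. Gray levels are kept native (0..255 or
# 0..65535); nothing is rescaled to [0, 1] except transiently inside EBImage
# calls.

#' Read an image file into a SpheroidStack
#'
#' Reads multi-page TIFF (native bit depth), PNG or JPEG. Multi-page TIFFs
#' are interpreted according to \code{layout}: RGB pages become one plane per
#' channel; grayscale pages either all belong to one channel
#' (\code{layout = "gray"}) or are distributed over named channels. Page
#' ordering for multi-channel grayscale files defaults to plane-major
#' (plane 1: R, G, B; plane 2: R, G, B; ...) because vendor dialects differ;
#' pass \code{interleave = "channel"} for channel-major files (all planes of
#' R, then G, then B). 2D inputs become depth-1 stacks.
#'
#' @param path file path (.tif/.tiff, .png, .jpg/.jpeg).
#' @param layout either \code{"gray"} (all pages are planes of one channel)
#'   or a character vector of channel names, e.g. \code{c("R","G","B")}.
#' @param interleave page ordering for multi-channel grayscale TIFFs:
#'   \code{"plane"} (default, plane-major) or \code{"channel"}.
#' @return a [SpheroidStack-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(runif(64), 8, 8), f)
#' stk <- readSpheroidStack(f)
#' stackDim(stk)
#' @export
readSpheroidStack <- function(path, layout = "auto",
                              interleave = c("plane", "channel")) {
  interleave <- match.arg(interleave)
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    # read normalized and rescale by the file's declared bit depth (the
    # native-value path is unreliable for multi-sample pages)
    res <- tryCatch({
      meta <- tiff::readTIFF(path, payload = FALSE)
      bits <- if (is.data.frame(meta)) meta$bits.per.sample[1]
              else meta$bits.per.sample
      list(pages = tiff::readTIFF(path, all = TRUE), bits = bits)
    }, error = function(e) stop("unreadable TIFF file: ", path, " (",
                                conditionMessage(e), ")", call. = FALSE))
    bits <- if (is.null(res$bits)) 8L else res$bits
    pages <- res$pages
    if (!is.list(pages)) pages <- list(pages)
    bitDepth <- if (bits > 8) 16L else 8L
    pages <- lapply(pages, function(p) round(p * (2^bits - 1)))
    dims <- lapply(pages, function(p) dim(p)[1:2])
    if (length(unique(dims)) != 1L)
      stop("inconsistent plane sizes in multi-page TIFF: ", path)
    if (length(dim(pages[[1]])) == 3L) {
      # RGB pages: one plane per channel per page
      nc <- dim(pages[[1]])[3]
      chn <- c("R", "G", "B", "A")[seq_len(nc)]
      channels <- lapply(seq_len(nc), function(k)
        simplify2array(lapply(pages, function(p) p[, , k])))
      names(channels) <- chn
      channels <- channels[names(channels) != "A"]
      channels <- lapply(channels, asStack3d)
    } else {
      chn <- if (identical(layout, "auto") || identical(layout, "gray"))
        "gray" else layout
      np <- length(pages)
      if (length(chn) > 1L) {
        if (np %% length(chn) != 0L)
          stop("page count (", np, ") is not a multiple of the channel ",
               "count (", length(chn), ")")
        s <- np %/% length(chn)
        idx <- if (interleave == "plane")
          split(seq_len(np), rep(seq_along(chn), times = s))
        else
          split(seq_len(np), rep(seq_along(chn), each = s))
        channels <- lapply(idx, function(i)
          asStack3d(simplify2array(pages[i])))
        names(channels) <- chn
      } else {
        channels <- list(asStack3d(simplify2array(pages)))
        names(channels) <- chn
      }
    }
  } else if (ext %in% c("png", "jpg", "jpeg")) {
    img <- tryCatch(
      if (ext == "png") png::readPNG(path) else jpeg::readJPEG(path),
      error = function(e) stop("unreadable image file: ", path, " (",
                               conditionMessage(e), ")", call. = FALSE))
    bitDepth <- 8L
    img <- round(img * 255)
    if (length(dim(img)) == 3L) {
      nc <- dim(img)[3]
      chn <- c("R", "G", "B", "A")[seq_len(nc)]
      channels <- lapply(seq_len(nc), function(k) asStack3d(img[, , k]))
      names(channels) <- chn
      channels <- channels[names(channels) != "A"]
    } else {
      channels <- list(gray = asStack3d(img))
    }
  } else {
    stop("unsupported image format: .", ext)
  }
  new("SpheroidStack", channels = channels, bitDepth = as.numeric(bitDepth))
}

asStack3d <- function(a) {
  if (length(dim(a)) == 2L || is.null(dim(a)))
    a <- array(a, dim = c(dim(as.matrix(a)), 1L))
  a
}

#' Average (AIP) and maximum intensity projection
#'
#' Collapses each channel's z-stack to a 2D image: per-pixel arithmetic mean
#' over the planes (average intensity projection) or per-pixel maximum.
#' Applied to each channel separately. On depth-1 stacks both projections are
#' the identity.
#'
#' @param stack a [SpheroidStack-class].
#' @return named list of H x W matrices, one per channel.
#' @examples
#' stk <- makeField(phenotypeSpec(nStructures = 3, fieldSize = c(96, 96),
#'                                seed = 1))$stack
#' color <- averageProjection(stk)
#' @export
averageProjection <- function(stack) {
  stopifnot(is(stack, "SpheroidStack"))
  lapply(stack@channels, function(a) {
    if (dim(a)[3] == 1L) a[, , 1] else rowMeans(a, dims = 2L)
  })
}

#' @rdname averageProjection
#' @export
maxProjection <- function(stack) {
  stopifnot(is(stack, "SpheroidStack"))
  lapply(stack@channels, function(a) {
    if (dim(a)[3] == 1L) a[, , 1] else apply(a, c(1, 2), max)
  })
}

#' Weighted grayscale conversion
#'
#' Per-pixel weighted sum of the projected channels. Weights are normalized
#' to sum to one; the default weights all present channels equally.
#'
#' @param color named list of H x W matrices (one per channel), as returned
#'   by [averageProjection()], or a single matrix.
#' @param weights nonnegative per-channel weights, recycled by channel name
#'   when named; default equal.
#' @return H x W matrix of gray levels.
#' @export
toGrayscale <- function(color, weights = NULL) {
  if (is.matrix(color)) color <- list(gray = color)
  nc <- length(color)
  if (is.null(weights)) weights <- rep(1, nc)
  if (!is.null(names(weights)) && !is.null(names(color)))
    weights <- weights[names(color)]
  if (length(weights) != nc)
    stop("need one weight per channel")
  if (any(weights < 0) || any(is.na(weights)))
    stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  weights <- weights / s
  out <- 0
  for (k in seq_len(nc)) out <- out + weights[k] * color[[k]]
  out
}

#' Percentile normalization
#'
#' Background normalization by excluding the tails of the image intensity
#' distribution: intensities at or below the \code{low}-th percentile map to
#' 0, at or above the \code{high}-th percentile to \code{fullScale}, with a
#' linear rescale in between. Defaults exclude the 5th and 95th percentiles.
#' A constant image is returned unchanged.
#'
#' @param image H x W numeric matrix.
#' @param low,high percentiles in \code{[0, 100]}, \code{low < high}.
#' @param fullScale output full-scale gray level (default 255).
#' @return matrix with range \code{[0, fullScale]} (input spread permitting).
#' @export
percentileNormalize <- function(image, low = 5, high = 95, fullScale = 255) {
  if (low >= high) stop("low percentile must be smaller than high")
  if (low < 0 || high > 100) stop("percentiles must lie in [0, 100]")
  v <- range(image)
  if (v[1] == v[2]) return(image)  # degenerate distribution
  q <- stats::quantile(image, c(low, high) / 100, names = FALSE)
  if (q[2] <= q[1]) {
    # pathological spread (mass concentrated at one value): hard split
    return(matrix(ifelse(image > q[1], fullScale, 0), nrow(image)))
  }
  out <- (image - q[1]) / (q[2] - q[1]) * fullScale
  pmin(pmax(out, 0), fullScale)
}

#' Image denoising filters
#'
#' Optional pre-processing to reduce intensity noise before thresholding:
#' Gaussian smoothing, median filtering, or edge enhancement (3x3 Laplacian
#' sharpening). A Gaussian with \code{sigma = 0} and a median with
#' \code{size = 1} are the identity.
#'
#' @param image H x W numeric matrix.
#' @param method one of \code{"gaussian"}, \code{"median"},
#'   \code{"edge_enhance"}.
#' @param size odd window size in pixels for the median filter (default 3).
#' @param sigma Gaussian standard deviation in pixels (default 2).
#' @return filtered matrix, same dimensions and intensity range.
#' @export
denoiseImage <- function(image, method = c("gaussian", "median",
                                           "edge_enhance"),
                         size = 3, sigma = 2) {
  method <- match.arg(method)
  switch(method,
    gaussian = {
      if (sigma <= 0) return(image)
      EBImage::gblur(image, sigma = sigma)
    },
    median = {
      if (size %% 2 != 1 || size < 1) stop("median size must be odd and >= 1")
      if (size == 1) return(image)
      r <- max(abs(image))
      if (r == 0) return(image)
      EBImage::medianFilter(image / r, size = (size - 1) / 2) * r
    },
    edge_enhance = {
      k <- matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)
      out <- EBImage::filter2(image, k)
      pmin(pmax(out, min(image)), max(image))
    })
}

#' Flatten uneven background (phase-contrast pre-processing)
#'
#' Large-kernel median estimate of the slowly varying background, subtracted
#' from the image (clipped at zero). Phase-contrast fields enter the pipeline
#' as single-channel stacks and receive this flattening so the histogram
#' valley thresholding sees a dark, even background.
#'
#' @param image H x W numeric matrix.
#' @param size odd background-window size in pixels (default 101; should be
#'   much larger than the structures of interest).
#' @return background-subtracted matrix (minimum 0).
#' @export
flattenBackground <- function(image, size = 101) {
  if (size %% 2 != 1 || size < 3) stop("size must be odd and >= 3")
  r <- max(abs(image))
  if (r == 0) return(image)
  bg <- EBImage::medianFilter(image / r, size = (size - 1) / 2) * r
  pmax(image - bg, 0)
}
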