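# Seeded synthetic spheroid-field generator with exhaustive ground truth,
# and multi-well screen simulation with planted treatment effects. This is
# the package's test surface: every rendered structure's center, radius,
# appendages, hollowness and red-dot content are known by construction.

#' Phenotype specification for the synthetic generator
#'
#' Describes a field of fluorescent spheroid-like structures: bright,
#' radially deformed disks on dark background, with optional invasive
#' appendages (stellate phenotype), hollow dimmed cores (acinar phenotype)
#' and a sparse red-channel "apoptotic dot" signal, plus additive Gaussian
#' noise. The same seed always renders a bit-identical field.
#'
#' Defaults emulate a routine low-magnification (5x) confocal field:
#' 672 x 512 px, ~20 well-separated structures of radius ~25 px, moderate
#' lobed deformation, dark background at gray level 20 and structure rim at
#' 200 with noise sd 5 (8-bit).
#'
#' @param nStructures number of structures to render.
#' @param fieldSize c(height, width) in pixels.
#' @param depth number of z-planes (1 = pre-projected 2D field).
#' @param radiusMean,radiusSd structure radius distribution (px; truncated
#'   at 2.5 sd and at 5 px).
#' @param deformAmplitude low-order radial deformation amplitude (fraction
#'   of radius; 0 = perfect disks).
#' @param roughnessAmplitude high-frequency contour ripple amplitude.
#' @param appendageCountRange integer range of appendages per structure.
#' @param appendageLengthRange appendage length range (px).
#' @param appendageWidth appendage width (px).
#' @param hollowFraction fraction of structures rendered hollow.
#' @param coreDimFactor intensity multiplier of the hollow core.
#' @param redDotRate Poisson mean of red dots per structure.
#' @param dotRadius red dot radius (px).
#' @param textureAmplitude multiplicative intensity texture inside
#'   structures (fraction; gives structures internal contrast so defocus
#'   visibly lowers in-structure variance).
#' @param background,rimLevel,dotLevel,redBackground intensity levels (gray).
#' @param noiseSd additive Gaussian noise sd (gray levels).
#' @param focusBlurStep per-plane defocus blur sigma increment (px), used
#'   when \code{depth > 1}.
#' @param minSpacing minimum center-to-center spacing (px); default keeps
#'   bodies well separated so segmentation correctness is checkable
#'   independently of watershed splitting.
#' @param margin minimum center-to-border distance (px).
#' @param seed RNG seed; same seed, same field.
#' @return a validated list of class \code{"phenotypeSpec"}.
#' @export
phenotypeSpec <- function(nStructures = 10, fieldSize = c(512, 672),
                          depth = 1, radiusMean = 25, radiusSd = 5,
                          deformAmplitude = 0.08, roughnessAmplitude = 0.03,
                          appendageCountRange = c(0, 2),
                          appendageLengthRange = c(15, 35),
                          appendageWidth = 6, hollowFraction = 0,
                          coreDimFactor = 0.3, redDotRate = 0,
                          dotRadius = 2.5, textureAmplitude = 0.1,
                          background = 20, rimLevel = 200,
                          dotLevel = 220, redBackground = 12, noiseSd = 5,
                          focusBlurStep = 1.5, minSpacing = NULL,
                          margin = NULL, seed = 1L) {
  rMax <- radiusMean + 2.5 * radiusSd
  appMax <- if (max(appendageCountRange) > 0) max(appendageLengthRange) else 0
  # bodies never overlap at this spacing; appendages may touch a neighbor,
  # which the seed-based split resolves without changing structure counts
  if (is.null(minSpacing))
    minSpacing <- 2 * rMax * (1 + 1.5 * (deformAmplitude +
                                         roughnessAmplitude)) + 2
  if (is.null(margin))
    margin <- ceiling(rMax * (1 + 1.5 * (deformAmplitude +
                                         roughnessAmplitude)) + appMax + 4)
  spec <- list(nStructures = nStructures, fieldSize = fieldSize,
    depth = depth, radiusMean = radiusMean, radiusSd = radiusSd,
    deformAmplitude = deformAmplitude,
    roughnessAmplitude = roughnessAmplitude,
    appendageCountRange = appendageCountRange,
    appendageLengthRange = appendageLengthRange,
    appendageWidth = appendageWidth, hollowFraction = hollowFraction,
    coreDimFactor = coreDimFactor, redDotRate = redDotRate,
    dotRadius = dotRadius, textureAmplitude = textureAmplitude,
    background = background, rimLevel = rimLevel,
    dotLevel = dotLevel, redBackground = redBackground, noiseSd = noiseSd,
    focusBlurStep = focusBlurStep, minSpacing = minSpacing, margin = margin,
    seed = as.integer(seed))
  stopifnot(nStructures >= 1, all(fieldSize >= 32), depth >= 1,
            radiusMean > 0, radiusSd >= 0, appendageWidth > 0,
            hollowFraction >= 0, hollowFraction <= 1, redDotRate >= 0,
            noiseSd >= 0,
            all(c(background, rimLevel, dotLevel) >= 0),
            all(c(background, rimLevel, dotLevel) <= 255))
  class(spec) <- "phenotypeSpec"
  spec
}

# evaluate an expression under a local RNG seed, restoring global RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Render a synthetic spheroid field with ground truth
#'
#' Renders the field described by a [phenotypeSpec()]: structure centers are
#' placed by rejection sampling at the spec's minimum spacing, each
#' structure is a radially deformed disk with optional appendages, hollow
#' core and Poisson-placed red dots, and additive Gaussian noise is applied.
#' With \code{depth > 1}, each structure is assigned a focus plane and
#' rendered progressively defocused (Gaussian blur) on the other planes.
#'
#' @param spec a [phenotypeSpec()].
#' @return list with \code{stack} (a [SpheroidStack-class] with R and G
#'   channels), \code{truth} (list: \code{table} — one row per structure
#'   with center, radius, appendage count/lengths, hollow flag, planted
#'   and rendered (connected-component) red-dot counts and dot area, focus plane; \code{labels} — the true label mask;
#'   \code{appendageLengths} — per-structure length vectors), and
#'   \code{spec}.
#' @examples
#' sim <- makeField(phenotypeSpec(nStructures = 3, fieldSize = c(128, 128),
#'                                seed = 42))
#' sim$truth$table
#' @export
makeField <- function(spec) {
  stopifnot(inherits(spec, "phenotypeSpec"))
  withSeed(spec$seed, renderField(spec))
}

renderField <- function(spec) {
  h <- spec$fieldSize[1]; w <- spec$fieldSize[2]
  n <- spec$nStructures
  centers <- placeCenters(n, h, w, spec$margin, spec$minSpacing)
  green <- matrix(0, h, w)
  red <- matrix(0, h, w)
  labels <- matrix(0L, h, w)
  rows <- vector("list", n)
  appLens <- vector("list", n)
  patches <- vector("list", n)
  for (i in seq_len(n)) {
    st <- renderStructure(spec, centers[i, ])
    pix <- st$pixels         # field-coordinate index + intensity
    free <- labels[pix$idx] == 0L
    labels[pix$idx[free]] <- i
    green[pix$idx[free]] <- pix$green[free]
    red[pix$idx[free]] <- pmax(red[pix$idx[free]], pix$red[free])
    rows[[i]] <- data.frame(Structure = i, cx = centers[i, 2],
      cy = centers[i, 1], radius = st$radius, nAppendages = st$nApp,
      hollow = st$hollow, nDots = st$nDots,
      nDotComponents = st$nDotComponents, dotArea = st$dotArea,
      focusPlane = if (spec$depth > 1) sample.int(spec$depth, 1) else 1L)
    appLens[[i]] <- st$appLengths
    patches[[i]] <- st
  }
  truthTable <- do.call(rbind, rows)
  if (spec$depth == 1) {
    G <- clamp8(green + spec$background +
                stats::rnorm(h * w, 0, spec$noiseSd))
    R <- clamp8(red + spec$redBackground +
                stats::rnorm(h * w, 0, spec$noiseSd))
    channels <- list(R = asStack3d(R), G = asStack3d(G))
  } else {
    Ga <- array(0, c(h, w, spec$depth))
    Ra <- array(0, c(h, w, spec$depth))
    for (z in seq_len(spec$depth)) {
      gz <- matrix(0, h, w); rz <- matrix(0, h, w)
      for (i in seq_len(n)) {
        sig <- spec$focusBlurStep * abs(z - truthTable$focusPlane[i])
        st <- patches[[i]]
        gp <- st$patchG; rp <- st$patchR
        if (sig > 0) {
          # defocus = blur + pinhole dimming, so in-structure variance
          # peaks at the focus plane; sigma capped so the kernel fits the
          # patch
          sig <- min(sig, (min(dim(gp)) - 1) / 7)
          dimf <- 1 / (1 + 0.8 * sig)
          gp <- EBImage::gblur(gp, sig) * dimf
          rp <- EBImage::gblur(rp, sig) * dimf
        }
        ys <- st$py0:st$py1; xs <- st$px0:st$px1
        gz[ys, xs] <- gz[ys, xs] + gp
        rz[ys, xs] <- rz[ys, xs] + rp
      }
      Ga[, , z] <- clamp8(gz + spec$background +
                          stats::rnorm(h * w, 0, spec$noiseSd))
      Ra[, , z] <- clamp8(rz + spec$redBackground +
                          stats::rnorm(h * w, 0, spec$noiseSd))
    }
    channels <- list(R = Ra, G = Ga)
  }
  stack <- new("SpheroidStack", channels = channels, bitDepth = 8)
  list(stack = stack,
       truth = list(table = truthTable, labels = labels,
                    appendageLengths = appLens),
       spec = spec)
}

clamp8 <- function(x) round(pmin(pmax(x, 0), 255))

placeCenters <- function(n, h, w, margin, minSpacing) {
  if (2 * margin >= h || 2 * margin >= w)
    stop("infeasible packing: margin ", margin, " leaves no room in a ",
         h, " x ", w, " field")
  centers <- matrix(0, 0, 2)
  tries <- 0L
  while (nrow(centers) < n) {
    tries <- tries + 1L
    if (tries > 4000L * n)
      stop("infeasible packing: cannot place ", n, " structures with ",
           "spacing ", minSpacing, " in a ", h, " x ", w, " field")
    cand <- c(stats::runif(1, margin, h - margin),
              stats::runif(1, margin, w - margin))
    if (nrow(centers) == 0 ||
        all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= minSpacing))
      centers <- rbind(centers, cand)
  }
  centers
}

# Render one structure around center (y, x); returns field-coordinate pixel
# sets with intensity contributions plus a local patch for z-stack blurring.
renderStructure <- function(spec, center) {
  R <- max(5, min(spec$radiusMean + 2.5 * spec$radiusSd,
                  max(spec$radiusMean - 2.5 * spec$radiusSd,
                      stats::rnorm(1, spec$radiusMean, spec$radiusSd))))
  nAngles <- 1024L
  theta <- seq(0, 2 * pi, length.out = nAngles + 1L)[-1L]
  rfun <- rep(R, nAngles)
  if (spec$deformAmplitude > 0) {
    for (k in 2:4) {
      amp <- spec$deformAmplitude / 3 * stats::runif(1, 0.5, 1.5)
      rfun <- rfun + R * amp * cos(k * theta + stats::runif(1, 0, 2 * pi))
    }
  }
  if (spec$roughnessAmplitude > 0) {
    for (k in sample(8:15, 3)) {
      amp <- spec$roughnessAmplitude / 3 * stats::runif(1, 0.5, 1.5)
      rfun <- rfun + R * amp * cos(k * theta + stats::runif(1, 0, 2 * pi))
    }
  }
  nApp <- if (max(spec$appendageCountRange) > 0)
    sample(spec$appendageCountRange[1]:spec$appendageCountRange[2], 1)
  else 0L
  appAng <- if (nApp > 0)
    (stats::runif(1, 0, 2 * pi) + 2 * pi * seq_len(nApp) / nApp) %% (2 * pi)
  else numeric(0)
  appLen <- if (nApp > 0)
    stats::runif(nApp, spec$appendageLengthRange[1],
                 spec$appendageLengthRange[2])
  else numeric(0)
  hollow <- stats::runif(1) < spec$hollowFraction
  ext <- max(rfun) + (if (nApp > 0) max(appLen) else 0) + 2
  cy <- center[1]; cx <- center[2]
  h <- spec$fieldSize[1]; w <- spec$fieldSize[2]
  py0 <- max(1L, floor(cy - ext)); py1 <- min(h, ceiling(cy + ext))
  px0 <- max(1L, floor(cx - ext)); px1 <- min(w, ceiling(cx + ext))
  ys <- py0:py1; xs <- px0:px1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  rad <- sqrt(dy^2 + dx^2)
  ang <- (atan2(dy, dx) %% (2 * pi))
  angIdx <- pmin(nAngles, pmax(1L, round(ang / (2 * pi) * nAngles)))
  body <- rad <= matrix(rfun[angIdx], nrow(rad))
  inside <- body
  if (nApp > 0) {
    for (a in seq_len(nApp)) {
      ux <- cos(appAng[a]); uy <- sin(appAng[a])
      aIdx <- pmin(nAngles, pmax(1L, round(appAng[a] / (2 * pi) * nAngles)))
      r0 <- rfun[aIdx] - 2
      r1 <- rfun[aIdx] + appLen[a]
      tproj <- dx * ux + dy * uy          # along-ray coordinate
      perp <- abs(dx * uy - dy * ux)      # across-ray distance
      inside <- inside |
        (tproj >= r0 & tproj <= r1 & perp < spec$appendageWidth / 2)
    }
  }
  gI <- matrix(0, nrow(rad), ncol(rad))
  gI[inside] <- spec$rimLevel - spec$background
  if (hollow) {
    core <- body & rad <= 0.5 * R
    gI[core] <- (spec$rimLevel * spec$coreDimFactor) - spec$background
  }
  if (spec$textureAmplitude > 0) {
    # intrinsic cellular texture, rendered once per structure: defocus
    # (blur) washes it out, so in-structure variance peaks at the focus
    # plane
    tex <- matrix(stats::runif(length(gI), 1 - spec$textureAmplitude,
                               1 + spec$textureAmplitude), nrow(gI))
    gI <- gI * tex
  }
  nDots <- if (spec$redDotRate > 0) stats::rpois(1, spec$redDotRate) else 0L
  rI <- matrix(0, nrow(rad), ncol(rad))
  dotArea <- 0
  if (nDots > 0) {
    # dots are placed non-overlapping (bounded retries) so the planted
    # count equals the rendered component count
    dotMask <- matrix(FALSE, nrow(rad), ncol(rad))
    placed <- matrix(0, 0, 2)
    minSep <- 2 * spec$dotRadius + 2
    for (d in seq_len(nDots)) {
      for (try in 1:50) {
        dr <- sqrt(stats::runif(1)) * 0.6 * R
        da <- stats::runif(1, 0, 2 * pi)
        cand <- c(dr * sin(da), dr * cos(da))
        if (nrow(placed) == 0 ||
            all(sqrt(rowSums(sweep(placed, 2, cand)^2)) >= minSep)) {
          placed <- rbind(placed, cand)
          break
        }
      }
    }
    nDots <- nrow(placed)
    for (d in seq_len(nDots))
      dotMask <- dotMask |
        ((dy - placed[d, 1])^2 + (dx - placed[d, 2])^2 <= spec$dotRadius^2)
    rI[dotMask] <- spec$dotLevel - spec$redBackground
    dotArea <- sum(dotMask)
    nDotComponents <- max(label8(dotMask * 1))
  } else nDotComponents <- 0L
  sel <- which(inside)
  ph <- length(ys)
  selY <- (sel - 1L) %% ph + 1L
  selX <- (sel - 1L) %/% ph + 1L
  idx <- (px0 + selX - 2L) * nrowField(spec) + (py0 + selY - 1L)
  list(pixels = list(idx = idx, green = gI[sel], red = rI[sel]),
       radius = R, nApp = nApp, appLengths = appLen, hollow = hollow,
       nDots = nDots, nDotComponents = nDotComponents, dotArea = dotArea,
       patchG = gI, patchR = rI, py0 = py0, py1 = py1, px0 = px0, px1 = px1)
}

nrowField <- function(spec) spec$fieldSize[1]

#' Simulate a multi-well screen with planted treatment effects
#'
#' Generates one synthetic field per (treatment, well, position), a matching
#' plate map, and the true effect table. Treatment effects are multiplicative
#' modifiers of [phenotypeSpec()] fields (e.g. a cytotoxic treatment raises
#' \code{redDotRate}; an anti-invasive one lowers the appendage count range;
#' a growth inhibitor lowers \code{radiusMean}). Optional well and position
#' random offsets (log-normal, on \code{radiusMean}) support
#' variance-component testing.
#'
#' @param treatments named list of effect vectors: each element is a named
#'   numeric vector of multipliers applied to the base spec (an empty vector
#'   means no effect). A \code{control} element is required.
#' @param baseSpec the control [phenotypeSpec()].
#' @param wellsPerTreatment,positionsPerWell design counts.
#' @param sigmaWell,sigmaPosition sd of the log-normal radius offsets.
#' @param seed RNG seed.
#' @param dir optional directory: when given, fields are written as 8-bit
#'   RGB TIFFs plus \code{plate_map.csv} and \code{truth.csv} so the batch
#'   front end can run on the files.
#' @return list with \code{fields} (named list of [makeField()] results;
#'   NULL when \code{dir} is given), \code{plateMap} (data.frame: ImageId,
#'   Well, Position, Treatment), \code{truth} (per-image true effect table),
#'   and \code{dir}.
#' @export
makeScreen <- function(treatments, baseSpec = phenotypeSpec(),
                       wellsPerTreatment = 3, positionsPerWell = 4,
                       sigmaWell = 0, sigmaPosition = 0, seed = 1L,
                       dir = NULL) {
  stopifnot(is.list(treatments), "control" %in% names(treatments))
  withSeed(seed, {
    plateRows <- list()
    fields <- list()
    truthRows <- list()
    wellId <- 0L
    for (tr in names(treatments)) {
      spec <- applyEffect(baseSpec, treatments[[tr]])
      for (wl in seq_len(wellsPerTreatment)) {
        wellId <- wellId + 1L
        wellOff <- if (sigmaWell > 0) exp(stats::rnorm(1, 0, sigmaWell)) else 1
        for (po in seq_len(positionsPerWell)) {
          posOff <- if (sigmaPosition > 0)
            exp(stats::rnorm(1, 0, sigmaPosition)) else 1
          sp <- spec
          sp$radiusMean <- sp$radiusMean * wellOff * posOff
          sp$seed <- sample.int(.Machine$integer.max, 1)
          imageId <- sprintf("%s_w%02d_p%d", tr, wellId, po)
          sim <- makeField(sp)
          plateRows[[imageId]] <- data.frame(ImageId = imageId,
            Well = sprintf("W%02d", wellId), Position = po, Treatment = tr)
          truthRows[[imageId]] <- cbind(ImageId = imageId, sim$truth$table)
          if (is.null(dir)) {
            fields[[imageId]] <- sim
          } else {
            writeFieldTIFF(sim$stack, file.path(dir,
                                                paste0(imageId, ".tif")))
          }
        }
      }
    }
    plateMap <- do.call(rbind, plateRows)
    rownames(plateMap) <- NULL
    truth <- do.call(rbind, truthRows)
    rownames(truth) <- NULL
    if (!is.null(dir)) {
      utils::write.csv(plateMap, file.path(dir, "plate_map.csv"),
                       row.names = FALSE)
      utils::write.csv(truth, file.path(dir, "truth.csv"),
                       row.names = FALSE)
      fields <- NULL
    }
    list(fields = fields, plateMap = plateMap, truth = truth, dir = dir)
  })
}

applyEffect <- function(spec, effect) {
  if (length(effect) == 0) return(spec)
  stopifnot(!is.null(names(effect)), all(names(effect) %in% names(spec)))
  for (nm in names(effect))
    spec[[nm]] <- spec[[nm]] * effect[[nm]]
  spec
}

#' Write a SpheroidStack as an 8-bit RGB multi-page TIFF
#'
#' One page per z-plane; absent channels are written as zeros. The file can
#' be read back with [readSpheroidStack()].
#'
#' @param stack a [SpheroidStack-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFieldTIFF <- function(stack, path) {
  d <- stackDim(stack)
  planes <- max(d$planes)
  getPlane <- function(ch, z) {
    a <- stack@channels[[ch]]
    if (is.null(a)) matrix(0, d$height, d$width)
    else a[, , min(z, dim(a)[3])]
  }
  pages <- lapply(seq_len(planes), function(z) {
    arr <- array(0, c(d$height, d$width, 3))
    arr[, , 1] <- getPlane("R", z)
    arr[, , 2] <- getPlane("G", z)
    arr[, , 3] <- getPlane("B", z)
    arr / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Simulate nested well/position data for variance-component testing
#'
#' Draws observations from the robustness model directly: value = mean +
#' well effect + position-within-well effect + residual, all Gaussian.
#'
#' @param nWells,positionsPerWell,obsPerPosition design counts.
#' @param mean grand mean.
#' @param sigmaWell,sigmaPosition,sigmaResidual true standard deviations.
#' @param seed RNG seed.
#' @return data.frame with Well, Position, value.
#' @export
simulateNestedData <- function(nWells = 20, positionsPerWell = 4,
                               obsPerPosition = 25, mean = 0,
                               sigmaWell = 2, sigmaPosition = 1,
                               sigmaResidual = 1, seed = 1L) {
  withSeed(seed, {
    rows <- list()
    for (wl in seq_len(nWells)) {
      we <- stats::rnorm(1, 0, sigmaWell)
      for (po in seq_len(positionsPerWell)) {
        pe <- stats::rnorm(1, 0, sigmaPosition)
        rows[[length(rows) + 1L]] <- data.frame(
          Well = sprintf("W%02d", wl), Position = po,
          value = mean + we + pe +
            stats::rnorm(obsPerPosition, 0, sigmaResidual))
      }
    }
    do.call(rbind, rows)
  })
}
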