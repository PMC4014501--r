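# Fixture builders: exact rasterized shapes with known geometry, built in
# code at test time.

# disk of radius r centered in a (2r + 2*pad + 1)^2 mask
diskMask <- function(r, pad = 2) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  xy <- expand.grid(y = 1:n, x = 1:n)
  m <- matrix(0, n, n)
  m[(xy$y - c0)^2 + (xy$x - c0)^2 <= r^2] <- 1
  m
}

# rectangle h x w centered in a padded mask
rectMask <- function(h, w, pad = 2) {
  m <- matrix(0, h + 2 * pad, w + 2 * pad)
  m[pad + (1:h), pad + (1:w)] <- 1
  m
}

# place a small mask inside a larger empty field at (y, x) top-left
placeIn <- function(field, shape, y, x) {
  sel <- shape == 1
  ys <- y + row(shape)[sel] - 1
  xs <- x + col(shape)[sel] - 1
  field[cbind(ys, xs)] <- 1
  field
}

# disk with nApp rectangular protrusions of given lengths (px) and width,
# at equally spaced angles; returns the mask
diskWithProtrusions <- function(r, lengths, width = 6, pad = NULL) {
  if (is.null(pad)) pad <- max(lengths) + 4
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  xy <- expand.grid(y = 1:n, x = 1:n)
  dy <- xy$y - c0; dx <- xy$x - c0
  m <- matrix(0, n, n)
  m[dy^2 + dx^2 <= r^2] <- 1
  angs <- 2 * pi * seq_along(lengths) / length(lengths)
  for (k in seq_along(lengths)) {
    ux <- cos(angs[k]); uy <- sin(angs[k])
    tproj <- dx * ux + dy * uy
    perp <- abs(dx * uy - dy * ux)
    m[tproj >= r - 2 & tproj <= r + lengths[k] & perp < width / 2] <- 1
  }
  m
}

# brute-force nearest-seed assignment (Euclidean, ties to lower label),
# restricted per 8-connected component: the watershed oracle
bruteForceAssign <- function(mask, seeds) {
  comps <- spheromorph:::label8(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  for (i in which(mask == 1)) {
    py <- (i - 1) %% nrow(mask) + 1
    px <- (i - 1) %/% nrow(mask) + 1
    ci <- comps[i]
    best <- 0L; bestD <- Inf
    for (s in seq_len(nrow(seeds))) {
      if (comps[seeds$y[s], seeds$x[s]] != ci) next
      d <- (py - seeds$y[s])^2 + (px - seeds$x[s])^2
      if (d < bestD) { bestD <- d; best <- seeds$label[s] }
    }
    out[i] <- best
  }
  out
}

# match found structures to planted centers by nearest center of mass;
# returns the truth-row index for each label
matchToTruth <- function(field, truthTable) {
  cen <- t(vapply(structureDetail(field),
                  function(s) s$geometry$center, numeric(2)))
  truthC <- cbind(truthTable$cx, truthTable$cy)
  apply(cen, 1, function(p)
    which.min((truthC[, 1] - p[1])^2 + (truthC[, 2] - p[2])^2))
}
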