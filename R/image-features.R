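#' Gray-level discretization specification
#'
#' Radiomics texture features are computed on discretized gray levels.
#' Two standard modes are supported: fixed bin width (level =
#' `floor((x - min) / width) + 1`, the common default with width 25
#' intensity units) and fixed bin count (equal-width bins over the observed
#' `[min, max]`, with the maximum assigned to the top bin). Levels always
#' start at 1.
#'
#' @param mode `"width"` or `"count"`.
#' @param width bin width in intensity units (width mode), > 0.
#' @param bins number of bins (count mode), >= 2.
#' @return object of class `disc_spec`.
#' @export
disc_spec <- function(mode = c("width", "count"), width = 25, bins = 32) {
  mode <- match.arg(mode)
  if (mode == "width") stopifnot(width > 0) else stopifnot(bins >= 2)
  structure(list(mode = mode, width = width, bins = bins),
            class = "disc_spec")
}

#' Discretize a volume's masked intensities to integer gray levels
#'
#' @param vm a `volume_mask` (see [generate_lesion_volume()]).
#' @param spec a [disc_spec()].
#' @return integer array of the volume's dimensions, levels (starting at 1)
#'   inside the mask and `NA` outside.
#' @export
discretize <- function(vm, spec = disc_spec()) {
  stopifnot(inherits(vm, "volume_mask"), sum(vm$mask) >= 1)
  x <- vm$intensities
  inside <- vm$mask == 1
  v <- x[inside]
  lev <- discretize_values(v, spec)
  out <- array(NA_integer_, dim = dim(x))
  out[inside] <- lev
  out
}

discretize_values <- function(v, spec) {
  if (spec$mode == "width") {
    as.integer(floor((v - min(v)) / spec$width) + 1)
  } else {
    rng <- range(v)
    if (rng[1] == rng[2]) return(rep.int(1L, length(v)))
    lev <- floor((v - rng[1]) / (rng[2] - rng[1]) * spec$bins) + 1
    as.integer(pmin(lev, spec$bins))  # max value goes in the top bin
  }
}

#' First-order (histogram) features
#'
#' The 18 standard intensity statistics of the IBSI first-order family:
#' mean, median, minimum, maximum, range, variance (population), skewness,
#' kurtosis (Pearson, i.e. 3 for a Gaussian), energy, total energy
#' (energy times voxel volume), entropy and uniformity (base-2, on the
#' discretized histogram), 10th and 90th percentiles, interquartile range,
#' mean absolute deviation, robust mean absolute deviation (over the
#' 10-90 percentile core) and root mean square. On a constant region the
#' standardized moments are undefined and returned as `NA` (flagged, not
#' propagated from a division by zero).
#'
#' @param values numeric vector of in-mask voxel intensities.
#' @param spec [disc_spec()] used for the histogram-based entropy/uniformity.
#' @param voxel_volume voxel volume in mm^3 for total energy (default 1).
#' @return named numeric vector of 18 features.
#' @export
first_order_features <- function(values, spec = disc_spec(),
                                 voxel_volume = 1) {
  stopifnot(length(values) >= 1)
  n <- length(values)
  m <- mean(values)
  cen <- values - m
  m2 <- mean(cen^2)
  skew <- if (m2 > 0) mean(cen^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean(cen^4) / m2^2 else NA_real_

  p <- tabulate(discretize_values(values, spec))
  p <- p[p > 0] / n
  entropy <- -sum(p * log2(p))
  uniformity <- sum(p^2)

  q <- stats::quantile(values, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  core <- values[values >= q[1] & values <= q[4]]

  c(mean = m,
    median = stats::median(values),
    minimum = min(values),
    maximum = max(values),
    range = max(values) - min(values),
    variance = m2,
    skewness = skew,
    kurtosis = kurt,
    energy = sum(values^2),
    total_energy = sum(values^2) * voxel_volume,
    entropy = entropy,
    uniformity = uniformity,
    p10 = q[1],
    p90 = q[4],
    iqr = q[3] - q[2],
    mad = mean(abs(cen)),
    rmad = mean(abs(core - mean(core))),
    rms = sqrt(mean(values^2)))
}

# the 13 unique 3D direction vectors (half of the 26-neighborhood)
glcm_offsets <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  keep <- d$dz > 0 | (d$dz == 0 & d$dy > 0) |
    (d$dz == 0 & d$dy == 0 & d$dx > 0)
  as.matrix(d[keep, ])
}

glcm_feature_names <- function() {
  c("joint_energy", "contrast", "correlation", "joint_entropy",
    "inverse_difference", "inverse_difference_moment", "dissimilarity",
    "cluster_shade", "cluster_prominence", "autocorrelation",
    "sum_average", "sum_entropy", "difference_entropy", "sum_squares")
}

# features of one symmetric, normalized co-occurrence matrix
glcm_matrix_features <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  mu <- sum(i * P)                 # symmetric: mu_x = mu_y
  sigma2 <- sum((i - mu)^2 * P)
  pos <- P > 0
  ent <- -sum(P[pos] * log2(P[pos]))

  s <- i + j
  d <- abs(i - j)
  psum <- tapply(P, s, sum)
  pdiff <- tapply(P, d, sum)
  ent_of <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }

  corr <- if (sigma2 > 0) sum((i - mu) * (j - mu) * P) / sigma2 else NA_real_

  stats::setNames(c(
    sum(P^2),
    sum((i - j)^2 * P),
    corr,
    ent,
    sum(P / (1 + d)),
    sum(P / (1 + (i - j)^2)),
    sum(d * P),
    sum((i + j - 2 * mu)^3 * P),
    sum((i + j - 2 * mu)^4 * P),
    sum(i * j * P),
    sum(s * P),
    ent_of(psum),
    ent_of(pdiff),
    sigma2
  ), glcm_feature_names())
}

#' Gray-level co-occurrence matrix features
#'
#' Builds one co-occurrence matrix per direction from all voxel pairs that
#' are both inside the mask at the given voxel distance, symmetrizes and
#' normalizes it, computes a documented IBSI-consistent feature core from
#' each direction's matrix, and averages the features over the 13 unique
#' 3D directions (directions with no in-mask pair are skipped).
#'
#' The 14 features, with `P` the normalized symmetric matrix over levels
#' `i, j`, `mu = sum(i P)` and `sigma2 = sum((i - mu)^2 P)`:
#' joint energy `sum(P^2)`; contrast `sum((i-j)^2 P)`; correlation
#' `sum((i-mu)(j-mu) P) / sigma2` (undefined when `sigma2 = 0`); joint
#' entropy `-sum(P log2 P)`; inverse difference `sum(P / (1 + |i-j|))`;
#' inverse difference moment `sum(P / (1 + (i-j)^2))`; dissimilarity
#' `sum(|i-j| P)`; cluster shade `sum((i+j-2mu)^3 P)`; cluster prominence
#' `sum((i+j-2mu)^4 P)`; autocorrelation `sum(i j P)`; sum average
#' `sum((i+j) P)`; sum entropy (entropy of the `i+j` distribution);
#' difference entropy (entropy of the `|i-j|` distribution); sum of squares
#' `sigma2`.
#'
#' @param levels integer gray-level array as returned by [discretize()]
#'   (`NA` outside the mask).
#' @param mask binary array of the same dimensions.
#' @param distance voxel distance multiplying each direction vector.
#' @param offsets matrix of direction vectors (default the 13 unique ones).
#' @return named numeric vector of 14 direction-averaged features; all `NA`
#'   when fewer than 2 in-mask voxel pairs exist.
#' @export
glcm_features <- function(levels, mask, distance = 1L,
                          offsets = glcm_offsets()) {
  stopifnot(all(dim(levels) == dim(mask)))
  dims <- dim(mask)
  levels[mask != 1] <- NA_integer_
  L <- max(levels[mask == 1], na.rm = TRUE)
  per_dir <- list()
  total_pairs <- 0L
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ] * distance
    src <- lapply(1:3, function(k)
      seq_len(dims[k]) [seq_len(dims[k]) + off[k] >= 1 &
                        seq_len(dims[k]) + off[k] <= dims[k]])
    if (any(lengths(src) == 0)) next
    dst <- lapply(1:3, function(k) src[[k]] + off[k])
    a <- levels[src[[1]], src[[2]], src[[3]], drop = FALSE]
    b <- levels[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    total_pairs <- total_pairs + sum(ok)
    counts <- matrix(0, L, L)
    tab <- table(factor(a[ok], levels = 1:L), factor(b[ok], levels = 1:L))
    counts <- counts + tab + t(tab)    # symmetrize
    per_dir[[length(per_dir) + 1L]] <- glcm_matrix_features(counts / sum(counts))
  }
  if (total_pairs < 2L || length(per_dir) == 0L)
    return(stats::setNames(rep(NA_real_, length(glcm_feature_names())),
                           glcm_feature_names()))
  colMeans(do.call(rbind, per_dir))
}

#' Shape features of a binary mask
#'
#' A bounded subset of the IBSI shape family: mesh-free voxel volume
#' (`count * voxel volume`), surface area by exposed-face counting (the sum
#' of areas of mask-voxel faces adjoining a non-mask voxel or the volume
#' boundary), sphericity `pi^(1/3) (6 V)^(2/3) / A`, and maximum 3D
#' diameter as the largest spacing-aware center-to-center distance between
#' mask voxels. The face-counting surface area slightly overestimates a
#' smooth surface, so digitized-ball sphericities stay below 1.
#'
#' @param mask binary 3D array.
#' @param spacing voxel spacing (mm), length 3.
#' @return named numeric vector: `volume_mm3`, `surface_mm2`, `sphericity`,
#'   `max_diameter_mm`.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(sum(mask) >= 1, length(spacing) == 3, all(spacing > 0))
  dims <- dim(mask)
  vol <- sum(mask) * prod(spacing)
  face_area <- c(spacing[2] * spacing[3],  # faces normal to x
                 spacing[1] * spacing[3],  # normal to y
                 spacing[1] * spacing[2])  # normal to z
  padded <- array(0L, dims + 2L)
  padded[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask
  surf <- 0
  exposed_any <- array(FALSE, dims)
  for (axis in 1:3) {
    for (s in c(-1L, 1L)) {
      idx <- lapply(1:3, function(k) (2:(dims[k] + 1)) +
                      if (k == axis) s else 0L)
      nb <- padded[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      exposed <- mask == 1L & nb == 0L
      surf <- surf + sum(exposed) * face_area[axis]
      exposed_any <- exposed_any | exposed
    }
  }
  sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / surf
  # max diameter is attained between boundary (exposed-face) voxels
  bidx <- which(exposed_any, arr.ind = TRUE)
  pts <- sweep(bidx, 2, spacing, `*`)
  maxd <- if (nrow(pts) == 1L) 0 else {
    dd <- stats::dist(pts)
    max(dd)
  }
  c(volume_mm3 = vol, surface_mm2 = surf, sphericity = sph,
    max_diameter_mm = maxd)
}

#' Single-level orthonormal 3D Haar wavelet decomposition
#'
#' Tensor-product Haar transform: along each axis, adjacent pairs `(a, b)`
#' map to the lowpass `(a + b)/sqrt(2)` and highpass `(a - b)/sqrt(2)`
#' coefficients, giving eight half-size sub-bands `LLL` ... `HHH` (letter k
#' is the filter on axis k). Odd dimensions are padded by edge replication
#' to the next even size, which keeps the transform orthonormal on the
#' padded array (Parseval holds for the padded volume).
#'
#' @param volume numeric 3D array.
#' @return named list of eight 3D arrays.
#' @export
haar3d <- function(volume) {
  stopifnot(length(dim(volume)) == 3)
  v <- pad_even(volume)
  step <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    odd <- m[seq(1, d[axis], 2), , drop = FALSE]
    even <- m[seq(2, d[axis], 2), , drop = FALSE]
    lo <- (odd + even) / sqrt(2)
    hi <- (odd - even) / sqrt(2)
    newd <- d[perm]; newd[1] <- newd[1] / 2
    list(L = aperm(array(lo, dim = newd), order(perm)),
         H = aperm(array(hi, dim = newd), order(perm)))
  }
  s1 <- step(v, 1)
  out <- list()
  for (f1 in c("L", "H")) {
    s2 <- step(s1[[f1]], 2)
    for (f2 in c("L", "H")) {
      s3 <- step(s2[[f2]], 3)
      for (f3 in c("L", "H"))
        out[[paste0(f1, f2, f3)]] <- s3[[f3]]
    }
  }
  out[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' Inverse of [haar3d()]
#'
#' Reconstructs the (even-padded) volume from its eight sub-bands.
#'
#' @param bands named list as returned by [haar3d()].
#' @return numeric 3D array with even dimensions.
#' @export
ihaar3d <- function(bands) {
  istep <- function(lo, hi, axis) {
    d <- dim(lo)
    perm <- c(axis, setdiff(1:3, axis))
    lom <- matrix(aperm(lo, perm), nrow = d[axis])
    him <- matrix(aperm(hi, perm), nrow = d[axis])
    m <- matrix(0, 2 * d[axis], ncol(lom))
    m[seq(1, 2 * d[axis], 2), ] <- (lom + him) / sqrt(2)
    m[seq(2, 2 * d[axis], 2), ] <- (lom - him) / sqrt(2)
    newd <- d[perm]; newd[1] <- 2 * newd[1]
    aperm(array(m, dim = newd), order(perm))
  }
  s3 <- list()
  for (f1 in c("L", "H")) for (f2 in c("L", "H"))
    s3[[paste0(f1, f2)]] <- istep(bands[[paste0(f1, f2, "L")]],
                                  bands[[paste0(f1, f2, "H")]], 3)
  s2 <- list()
  for (f1 in c("L", "H"))
    s2[[f1]] <- istep(s3[[paste0(f1, "L")]], s3[[paste0(f1, "H")]], 2)
  istep(s2$L, s2$H, 1)
}

pad_even <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) if (n %% 2 == 1) c(seq_len(n), n) else seq_len(n))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Extract the full bounded feature vector from a lesion volume
#'
#' Concatenates, for the original image, the 18 first-order features, the
#' 14 direction-averaged GLCM features and the 4 shape features, and for
#' each of the eight single-level Haar sub-bands the first-order and GLCM
#' features recomputed on the sub-band coefficients (shape is geometry-only
#' and computed once). Sub-band features use a mask downsampled by 2 (a
#' sub-band voxel is inside if any of its parent voxels is). Names are
#' prefixed `original_` or `wavelet-XXX_`.
#'
#' @param vm a `volume_mask`.
#' @param spec a [disc_spec()].
#' @return named numeric vector of `18 + 14 + 4 + 8 * (18 + 14) = 292`
#'   features; undefined features are `NA`.
#' @export
extract_all <- function(vm, spec = disc_spec()) {
  stopifnot(inherits(vm, "volume_mask"))
  voxvol <- prod(vm$spacing)
  vals <- vm$intensities[vm$mask == 1]
  lev <- discretize(vm, spec)

  out <- c(
    prefixed("original_firstorder_",
             first_order_features(vals, spec, voxvol)),
    prefixed("original_glcm_", glcm_features(lev, vm$mask)),
    prefixed("original_shape_", shape_features(vm$mask, vm$spacing))
  )

  bands <- haar3d(vm$intensities)
  submask <- downsample_mask(pad_even(vm$mask))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    bvals <- b[submask == 1]
    bvm <- structure(list(intensities = b, mask = submask,
                          spacing = 2 * vm$spacing), class = "volume_mask")
    blev <- discretize(bvm, spec)
    out <- c(out,
             prefixed(paste0("wavelet-", nm, "_firstorder_"),
                      first_order_features(bvals, spec, voxvol * 8)),
             prefixed(paste0("wavelet-", nm, "_glcm_"),
                      glcm_features(blev, submask)))
  }
  out
}

prefixed <- function(prefix, x) stats::setNames(x, paste0(prefix, names(x)))

# a sub-band voxel is in the mask if any of its 2x2x2 parents is
downsample_mask <- function(mask) {
  d <- dim(mask)
  i1 <- seq(1, d[1], 2); i2 <- seq(1, d[2], 2); i3 <- seq(1, d[3], 2)
  acc <- array(0L, c(length(i1), length(i2), length(i3)))
  for (o1 in 0:1) for (o2 in 0:1) for (o3 in 0:1)
    acc <- acc + mask[i1 + o1, i2 + o2, i3 + o3, drop = FALSE]
  array(as.integer(acc > 0), dim = dim(acc))
}
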