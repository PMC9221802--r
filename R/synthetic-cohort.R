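#' Configuration for a synthetic radiomics cohort
#'
#' The generator emulates the statistical structure the modelling pipelines
#' assume: a patients-by-features radiomics table with strong within-family
#' correlation, a small set of clinical variables (skewed positive labs plus
#' categorical covariates), binary LI-RADS qualitative features, and a binary
#' treatment-response endpoint at a fixed prevalence. Defaults mirror the
#' reference cohort: 51 patients, 854 radiomics features, 12 clinical
#' variables, 19 LI-RADS features, and complete-response prevalence 14/51.
#'
#' Radiomics features are drawn from equicorrelated Gaussian blocks
#' (correlation `rho` within a block of `block_size` consecutive features,
#' independence across blocks), standing in for the redundancy of wavelet
#' feature families. A planted feature has class-conditional means separated
#' by `delta` pooled standard deviations, so its population AUC is
#' `pnorm(delta / sqrt(2))`.
#'
#' @param n_patients number of patients (>= 2).
#' @param n_radiomics number of radiomics features.
#' @param n_clinical,n_lirads numbers of clinical and LI-RADS variables.
#' @param prevalence endpoint prevalence in (0, 1); the positive count is
#'   exactly `round(prevalence * n_patients)`.
#' @param endpoint which binary endpoint the labels represent: `"cr"`
#'   (complete response) or `"or"` (objective response). This only affects
#'   how mRECIST categories are allocated consistently with the labels.
#' @param planted data.frame with columns `index` (1-based radiomics feature
#'   index) and `delta` (standardized effect size), or NULL for pure noise.
#' @param block_size size of the equicorrelated feature blocks.
#' @param rho within-block correlation in [0, 1).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   full configuration.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 51, n_radiomics = 854,
                          n_clinical = 12, n_lirads = 19,
                          prevalence = 14 / 51, endpoint = c("cr", "or"),
                          planted = NULL, block_size = 8, rho = 0.6,
                          seed = 1L) {
  endpoint <- match.arg(endpoint)
  stopifnot(n_patients >= 2, n_radiomics >= 1,
            prevalence > 0, prevalence < 1,
            block_size >= 1, rho >= 0, rho < 1)
  if (round(prevalence * n_patients) < 1) stop("degenerate class")
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("index", "delta") %in% names(planted)))
    if (anyDuplicated(planted$index)) stop("duplicate planted indices")
    if (any(planted$index < 1 | planted$index > n_radiomics))
      stop("planted index out of range")
    if (any(!is.finite(planted$delta))) stop("planted delta must be finite")
  }
  structure(list(n_patients = n_patients, n_radiomics = n_radiomics,
                 n_clinical = n_clinical, n_lirads = n_lirads,
                 prevalence = prevalence, endpoint = endpoint,
                 planted = planted, block_size = block_size, rho = rho,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# exact positive placement: round(prevalence * n) positives at random rows
generate_binary_labels <- function(n, prevalence) {
  n_pos <- round(prevalence * n)
  y <- integer(n)
  y[sample.int(n, n_pos)] <- 1L
  y
}

# allocate mRECIST categories consistent with the binary endpoint, using
# the reference cohort's category mix (14 CR : 15 PR : 19 SD : 3 PD)
allocate_categories <- function(y, endpoint) {
  fill <- function(idx, props, cats) {
    m <- length(idx)
    cnt <- floor(props / sum(props) * m)
    rem <- m - sum(cnt)
    if (rem > 0) {
      frac <- props / sum(props) * m - cnt
      cnt[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        cnt[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    rep(cats, cnt)
  }
  out <- character(length(y))
  if (endpoint == "cr") {
    out[y == 1] <- "CR"
    out[y == 0] <- fill(which(y == 0), c(15, 19, 3), c("PR", "SD", "PD"))
  } else {
    out[y == 1] <- fill(which(y == 1), c(14, 15), c("CR", "PR"))
    out[y == 0] <- fill(which(y == 0), c(19, 3), c("SD", "PD"))
  }
  out
}

# family-tagged names matching the reference feature-family census
radiomics_feature_names <- function(p) {
  fams <- c(firstorder = 18, glcm = 24, gldm = 14, glrlm = 16, glzlm = 16,
            ngtdm = 5, shape = 17)
  nm <- unlist(lapply(names(fams), function(f)
    paste0("original_", f, "_f", seq_len(fams[[f]]))), use.names = FALSE)
  if (p > length(nm)) {
    subbands <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
    k <- p - length(nm)
    wav <- paste0("wavelet-", rep_len(subbands, k), "_tex_f", seq_len(k))
    nm <- c(nm, wav)
  }
  nm[seq_len(p)]
}

#' Generate a synthetic cohort dataset
#'
#' Draws the radiomics feature table from the correlated Gaussian model of
#' [cohort_config()], plants the configured class-conditional mean shifts,
#' attaches clinical and LI-RADS tables and exact-count response labels.
#' Identical configurations (including seed) yield bit-identical datasets.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort_dataset`: list with `features` (numeric
#'   matrix, named columns), `clinical` (data.frame), `lirads` (data.frame),
#'   `labels` (data.frame from [response_labels()]) and the `config`.
#' @export
#' @examples
#' d <- generate_feature_table(cohort_config(n_patients = 20, n_radiomics = 30,
#'                                           prevalence = 0.3, seed = 7))
#' dim(d$features); sum(d$labels$complete_response)
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  p <- config$n_radiomics

  y <- generate_binary_labels(n, config$prevalence)
  labels <- response_labels(allocate_categories(y, config$endpoint))

  # equicorrelated blocks via a shared block factor:
  # x = sqrt(rho) * z_block + sqrt(1 - rho) * e  has unit variance and
  # within-block correlation rho
  n_blocks <- ceiling(p / config$block_size)
  block_of <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(p)]
  z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  e <- matrix(stats::rnorm(n * p), n, p)
  x <- sqrt(config$rho) * z[, block_of, drop = FALSE] +
    sqrt(1 - config$rho) * e

  if (!is.null(config$planted)) {
    for (i in seq_len(nrow(config$planted))) {
      j <- config$planted$index[i]
      x[y == 1, j] <- x[y == 1, j] + config$planted$delta[i]
    }
  }
  colnames(x) <- radiomics_feature_names(p)

  aux <- generate_clinical_lirads(config, reseed = FALSE)
  structure(list(features = x, clinical = aux$clinical, lirads = aux$lirads,
                 labels = labels, config = config),
            class = "cohort_dataset")
}

# lognormal parameterization from a target median and IQR:
# median m -> meanlog = log(m); IQR (q25, q75) -> sdlog from the normal
# quantile spread of log(q75/q25)
lognormal_params <- function(median, q25, q75) {
  list(meanlog = log(median),
       sdlog = log(q75 / q25) / (2 * stats::qnorm(0.75)))
}

# default clinical generator settings, loosely matched to the reference
# cohort's medians/IQRs (labs) and rates (categoricals)
default_clinical_spec <- function() {
  list(
    age = list(kind = "lognormal", median = 73, q25 = 66, q75 = 78),
    sex_male = list(kind = "bernoulli", rate = 37 / 51),
    etiology = list(kind = "categorical",
                    levels = c("HCV", "HBV", "NAFLD"),
                    probs = c(43, 6, 2) / 51),
    albumin = list(kind = "lognormal", median = 3.5, q25 = 3.2, q75 = 3.9),
    creatinine = list(kind = "lognormal", median = 0.8, q25 = 0.7, q75 = 1.0),
    bilirubin = list(kind = "lognormal", median = 0.8, q25 = 0.6, q75 = 1.2),
    platelet_count = list(kind = "lognormal", median = 115.1, q25 = 97.0,
                          q75 = 170.7),
    inr = list(kind = "lognormal", median = 1.0, q25 = 1.0, q75 = 1.15),
    afp = list(kind = "lognormal", median = 6.0, q25 = 3.0, q75 = 60.0),
    child_pugh_b = list(kind = "bernoulli", rate = 6 / 51),
    ascites = list(kind = "bernoulli", rate = 8 / 51),
    varices = list(kind = "bernoulli", rate = 39 / 51)
  )
}

default_lirads_rates <- function() {
  c(nonrim_aphe = 49 / 51, nonperipheral_washout = 43 / 51,
    enhancing_capsule = 23 / 51, threshold_growth = 4 / 51,
    us_visibility = 9 / 51, subthreshold_growth = 14 / 51,
    corona_enhancement = 3 / 51, fat_sparing = 4 / 51,
    restricted_diffusion = 33 / 51, mild_moderate_t2 = 27 / 51,
    iron_sparing = 0.02, transitional_hypointensity = 42 / 51,
    hbp_hypointensity = 44 / 51, nonenhancing_capsule = 1 / 51,
    nodule_in_nodule = 4 / 51, mosaic_architecture = 4 / 51,
    fat_in_mass = 9 / 51, blood_products = 1 / 51)
}

#' Generate synthetic clinical and LI-RADS tables
#'
#' Continuous laboratory variables are log-normal (strictly positive and
#' right-skewed, like platelet count and alpha-fetoprotein in real cohorts),
#' parameterized by a target median and interquartile range; categorical and
#' binary variables are Bernoulli/multinomial at configurable rates. LI-RADS
#' qualitative features are binary plus a continuous lesion size (mm).
#'
#' @param config a [cohort_config()]; `n_clinical`/`n_lirads` column counts
#'   are taken from it (extra generic columns are appended if larger than
#'   the default variable sets; the default sets provide 12 and 19 columns).
#' @param clinical_spec named list of per-variable generator settings; see
#'   the default in the source for the accepted kinds (`lognormal`,
#'   `bernoulli`, `categorical`).
#' @param lirads_rates named vector of Bernoulli rates in [0, 1] for the
#'   binary LI-RADS features.
#' @param reseed set the seed from `config$seed` (TRUE when called
#'   standalone; [generate_feature_table()] manages the stream itself).
#' @return list with data.frames `clinical` and `lirads`.
#' @export
generate_clinical_lirads <- function(config,
                                     clinical_spec = default_clinical_spec(),
                                     lirads_rates = default_lirads_rates(),
                                     reseed = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(lirads_rates < 0 | lirads_rates > 1))
    stop("LI-RADS rates must be in [0, 1]")
  if (reseed) set.seed(config$seed + 1L)
  n <- config$n_patients

  gen_one <- function(sp) {
    switch(sp$kind,
      lognormal = {
        pr <- lognormal_params(sp$median, sp$q25, sp$q75)
        stats::rlnorm(n, pr$meanlog, pr$sdlog)
      },
      bernoulli = {
        if (sp$rate < 0 || sp$rate > 1) stop("rate outside [0, 1]")
        stats::rbinom(n, 1L, sp$rate)
      },
      categorical = sample(sp$levels, n, replace = TRUE, prob = sp$probs),
      stop("unknown generator kind: ", sp$kind))
  }
  clinical <- as.data.frame(lapply(clinical_spec, gen_one),
                            stringsAsFactors = FALSE)
  while (ncol(clinical) < config$n_clinical) {
    clinical[[paste0("clinical_extra_", ncol(clinical) + 1L)]] <-
      stats::rnorm(n)
  }
  clinical <- clinical[, seq_len(config$n_clinical), drop = FALSE]

  lirads <- data.frame(size_mm = stats::rlnorm(
    n, lognormal_params(20, 16, 30)$meanlog, lognormal_params(20, 16, 30)$sdlog))
  for (nm in names(lirads_rates))
    lirads[[nm]] <- stats::rbinom(n, 1L, lirads_rates[[nm]])
  while (ncol(lirads) < config$n_lirads)
    lirads[[paste0("lirads_extra_", ncol(lirads) + 1L)]] <-
      stats::rbinom(n, 1L, 0.3)
  lirads <- lirads[, seq_len(config$n_lirads), drop = FALSE]

  list(clinical = clinical, lirads = lirads)
}

#' Generate a synthetic 3D lesion volume with mask
#'
#' Builds an ellipsoidal (default spherical) lesion mask centered in the
#' volume and fills the image with `mean` plus spatially smoothed Gaussian
#' noise, a simple stand-in for a segmented enhancing lesion on a single MRI
#' phase. Smoothing is an isotropic Gaussian kernel of standard deviation
#' `scale` millimetres applied to the noise field, giving the texture a
#' controllable correlation length.
#'
#' @param shape integer voxel dimensions, length 3.
#' @param spacing voxel spacing in mm, length 3, all positive.
#' @param radius lesion radius in mm; must fit inside the volume.
#' @param texture list with `mean`, `sd` (intensity units) and `scale`
#'   (smoothing, mm; 0 disables smoothing).
#' @param seed integer seed.
#' @return object of class `volume_mask`: list with 3D arrays `intensities`
#'   and `mask` (0/1) plus `spacing`.
#' @export
generate_lesion_volume <- function(shape = c(32, 32, 32),
                                   spacing = c(1, 1, 1), radius = 10,
                                   texture = list(mean = 100, sd = 10,
                                                  scale = 2),
                                   seed = 1L) {
  stopifnot(length(shape) == 3, length(spacing) == 3, all(spacing > 0),
            radius > 0)
  half_extent <- (shape - 1) * spacing / 2
  if (any(radius > half_extent)) stop("radius too large for the volume")
  set.seed(as.integer(seed))

  center <- (shape + 1) / 2
  ax <- lapply(1:3, function(k) (seq_len(shape[k]) - center[k]) * spacing[k])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  mask <- array(as.integer(d2 <= radius^2), dim = shape)

  noise <- array(stats::rnorm(prod(shape), 0, 1), dim = shape)
  if (texture$sd > 0 && texture$scale > 0)
    noise <- gaussian_smooth3d(noise, texture$scale / spacing)
  # renormalize so the interior sd is the requested one
  if (texture$sd > 0) {
    s <- stats::sd(noise)
    if (s > 0) noise <- noise / s * texture$sd
  } else noise[] <- 0
  intensities <- texture$mean + noise

  structure(list(intensities = intensities, mask = mask, spacing = spacing),
            class = "volume_mask")
}

# separable Gaussian smoothing; sigma in voxels per axis
gaussian_smooth3d <- function(a, sigma) {
  smooth_axis <- function(a, axis, s) {
    if (s <= 0) return(a)
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    apply_along <- function(v) {
      n <- length(v)
      vp <- c(rep(v[1], r), v, rep(v[n], r))  # edge replication
      stats::convolve(vp, rev(k), type = "filter")
    }
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    m <- apply(m, 2, apply_along)
    aperm(array(m, dim = d[perm]), order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax, sigma[ax])
  a
}

#' Write / read a cohort dataset as CSV files
#'
#' Writes `features.csv`, `clinical.csv`, `lirads.csv` and `labels.csv`
#' (header row of names, one row per patient) into a directory, and reads
#' them back into a `cohort_dataset`.
#'
#' @param dataset a `cohort_dataset`.
#' @param dir output directory (created if missing).
#' @return `write_cohort_csv` returns `dir` invisibly; `read_cohort_csv`
#'   returns a `cohort_dataset` (without the generating config).
#' @export
write_cohort_csv <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(dataset$features),
                   file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(dataset$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$lirads, file.path(dir, "lirads.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  feats <- utils::read.csv(file.path(dir, "features.csv"), check.names = FALSE)
  structure(list(
    features = as.matrix(feats),
    clinical = utils::read.csv(file.path(dir, "clinical.csv")),
    lirads = utils::read.csv(file.path(dir, "lirads.csv")),
    labels = utils::read.csv(file.path(dir, "labels.csv"),
                             stringsAsFactors = FALSE),
    config = NULL), class = "cohort_dataset")
}

#' Write a lesion volume as a NIfTI image/mask pair
#'
#' @param vm a `volume_mask`.
#' @param image_path,mask_path output paths (`.nii` or `.nii.gz`).
#' @return invisibly, the two paths.
#' @export
write_volume_nifti <- function(vm, image_path, mask_path) {
  img <- RNifti::asNifti(vm$intensities, pixdim = vm$spacing)
  msk <- RNifti::asNifti(vm$mask, pixdim = vm$spacing)
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image_path, mask_path))
}

#' Read a NIfTI image/mask pair as a lesion volume
#'
#' @param image_path,mask_path NIfTI file paths.
#' @return a `volume_mask`.
#' @export
read_volume_nifti <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[1:3]
  structure(list(intensities = array(as.numeric(img), dim = dim(img)),
                 mask = array(as.integer(msk > 0), dim = dim(msk)),
                 spacing = spacing),
            class = "volume_mask")
}
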