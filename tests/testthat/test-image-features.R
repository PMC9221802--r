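make_vm <- function(arr, spacing = c(1, 1, 1), mask = NULL) {
  if (is.null(mask)) mask <- array(1L, dim(arr))
  structure(list(intensities = arr, mask = mask, spacing = spacing),
            class = "volume_mask")
}

test_that("discretization follows the fixed-width and fixed-count conventions", {
  arr <- array(0:255, c(16, 16, 1))
  lev <- discretize(make_vm(arr), disc_spec("width", width = 25))
  expect_equal(min(lev), 1)
  expect_equal(max(lev), 11)                 # floor(255/25)+1
  expect_equal(lev[arr == 255][1], 11L)

  const <- discretize(make_vm(array(7, c(3, 3, 3))), disc_spec("count", bins = 4))
  expect_true(all(const == 1L))

  v <- array(c(0, 1, 2, 3, 4, 0, 1, 2), c(2, 2, 2))
  lev4 <- discretize(make_vm(v), disc_spec("count", bins = 4))
  expect_equal(max(lev4), 4L)                # top edge goes in bin 4, not 5
  expect_equal(lev4[v == 4][1], 4L)
})

test_that("first-order features match hand values and flag undefined moments", {
  f <- first_order_features(rep(3, 10))
  expect_equal(unname(f[c("mean", "variance", "entropy")]), c(3, 0, 0))
  expect_equal(unname(f["energy"]), 10 * 9)
  expect_true(is.na(f["skewness"]) && is.na(f["kurtosis"]))

  f2 <- first_order_features(c(1, 1, 2, 2), disc_spec("count", bins = 2))
  expect_equal(unname(f2["entropy"]), 1)       # two equal bins: 1 bit
  expect_equal(unname(f2["uniformity"]), 0.5)

  expect_equal(unname(first_order_features(1:5)["skewness"]), 0)
  expect_length(f, 18)
})

test_that("GLCM reproduces the hand-built strip matrix and the pair-enumeration oracle", {
  lev <- array(c(1L, 2L, 1L, 2L), c(4, 1, 1))
  mask <- array(1L, c(4, 1, 1))
  g <- glcm_features(lev, mask)
  expect_equal(unname(g["contrast"]), 1)
  expect_equal(unname(g["joint_energy"]), 0.5)
  expect_equal(unname(g["correlation"]), -1)

  const <- glcm_features(array(1L, c(3, 3, 3)), array(1L, c(3, 3, 3)))
  expect_equal(unname(const["joint_energy"]), 1)
  expect_equal(unname(const["contrast"]), 0)
  expect_equal(unname(const["joint_entropy"]), 0)

  # brute-force voxel-pair enumeration oracle on random small volumes
  set.seed(3)
  for (i in 1:4) {
    dims <- sample(3:6, 3, replace = TRUE)
    lev <- array(sample(1:4, prod(dims), TRUE), dims)
    mask <- array(rbinom(prod(dims), 1, 0.8), dims)
    if (sum(mask) < 4) next
    expect_equal(glcm_features(lev, mask), oracle_glcm(lev, mask),
                 tolerance = 1e-10)
  }

  tiny <- array(0L, c(3, 3, 3)); tiny[1, 1, 1] <- 1L
  und <- glcm_features(array(1L, c(3, 3, 3)), tiny)
  expect_true(all(is.na(und)))                 # < 2 in-mask pairs
})

test_that("shape features are exact on voxel constructions and sane on balls", {
  one <- shape_features(array(1L, c(1, 1, 1)), c(1, 1, 1))
  expect_equal(unname(one["volume_mm3"]), 1)
  expect_equal(unname(one["surface_mm2"]), 6)

  m <- array(0L, c(3, 3, 4)); m[2, 2, 2] <- 1L; m[2, 2, 3] <- 1L
  two <- shape_features(m, c(1, 1, 3))
  expect_equal(unname(two["max_diameter_mm"]), 3)  # center-to-center
  expect_equal(unname(two["volume_mm3"]), 6)

  # digitized balls: sphericity bounded by 1 and stable across radii; the
  # exposed-face surface overestimates the smooth sphere by ~3/2, so the
  # digital-ball sphericity sits near (2/3) of the analytic value of 1
  sph <- vapply(c(4, 6, 8, 10), function(r) {
    vm <- generate_lesion_volume(shape = c(27, 27, 27), radius = r, seed = 1)
    unname(shape_features(vm$mask, vm$spacing)["sphericity"])
  }, numeric(1))
  expect_true(all(sph <= 1))
  expect_true(all(sph > 0.55 & sph < 0.8))
  expect_lt(max(sph) - min(sph), 0.05)
})

test_that("3D Haar transform is orthonormal, invertible and matches the tensor basis", {
  cvol <- array(5, c(4, 4, 4))
  b <- haar3d(cvol)
  expect_equal(unname(b$LLL[1, 1, 1]), 5 * 2 * sqrt(2))
  for (nm in setdiff(names(b), "LLL"))
    expect_equal(max(abs(b[[nm]])), 0)

  imp <- array(0, c(2, 2, 2)); imp[1, 1, 1] <- 3
  bi <- haar3d(imp)
  expect_true(all(vapply(bi, function(x) abs(abs(x[1, 1, 1]) - 3 / (2 * sqrt(2))) < 1e-12,
                         logical(1))))

  set.seed(9)
  v <- array(rnorm(6 * 4 * 8), c(6, 4, 8))
  bands <- haar3d(v)
  expect_equal(sum(v^2), sum(vapply(bands, function(x) sum(x^2), numeric(1))),
               tolerance = 1e-10)               # Parseval
  expect_equal(ihaar3d(bands), v, tolerance = 1e-10)

  # odd dims: edge replication keeps Parseval on the padded core
  v_odd <- array(rnorm(5 * 4 * 4), c(5, 4, 4))
  b_odd <- haar3d(v_odd)
  expect_equal(dim(b_odd$LLL), c(3, 2, 2))
  expect_equal(ihaar3d(b_odd)[1:5, , ], v_odd, tolerance = 1e-10)
})

test_that("extract_all satisfies the feature-count contract and invariances", {
  vm <- generate_lesion_volume(shape = c(16, 16, 16), radius = 5,
                               texture = list(mean = 100, sd = 15, scale = 1.5),
                               seed = 4)
  fv <- extract_all(vm)
  expect_length(fv, 18 + 14 + 4 + 8 * (18 + 14))
  expect_false(any(duplicated(names(fv))))

  fv2 <- extract_all(vm)
  expect_identical(fv, fv2)                     # deterministic

  # intensity shift: variance and fixed-bin-count entropy are invariant
  vm_shift <- vm; vm_shift$intensities <- vm$intensities + 37
  spec <- disc_spec("count", bins = 16)
  f1 <- extract_all(vm, spec); f2 <- extract_all(vm_shift, spec)
  expect_equal(f1["original_firstorder_variance"],
               f2["original_firstorder_variance"], tolerance = 1e-10)
  expect_equal(f1["original_firstorder_entropy"],
               f2["original_firstorder_entropy"], tolerance = 1e-10)
  expect_equal(f1["original_glcm_contrast"], f2["original_glcm_contrast"],
               tolerance = 1e-10)

  # all features finite on a textured lesion except documented undefined
  nas <- names(fv)[!is.finite(fv)]
  expect_true(all(grepl("skewness|kurtosis|correlation", nas)))
})
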