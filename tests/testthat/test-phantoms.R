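test_that("facility_spec validates its fields", {
  expect_error(facility_spec("X", gamma = 0), "gamma")
  expect_error(facility_spec("X", intensity_scale = -1), "intensity_scale")
  expect_error(facility_spec("X", noise_sigma = -0.1), "noise_sigma")
  expect_error(facility_spec("X", slice_thickness_factor = 0), "slice_thickness")
})

test_that("base phantom generation is a pure function of its seed", {
  a <- tiny_phantom(seed = 7)
  b <- tiny_phantom(seed = 7)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels, b$labels)
  c <- tiny_phantom(seed = 8)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("zero tumor radii give an empty label volume with brain tissue", {
  ph <- make_base_phantom(c(16, 16, 16), list(center = c(8, 8, 8), radii = c(0, 0, 0)),
                          seed = 3)
  expect_equal(sum(ph$labels != 0), 0)
  expect_gt(sum(ph$volume$data != 0), 0)
  expect_equal(ph$tumor_volume_ml, 0)
})

test_that("sub-region label counts match a brute-force concentric rasterization", {
  shape <- c(32L, 32L, 32L)
  ctr <- (shape + 1) / 2
  ph <- make_base_phantom(shape, list(center = ctr, radii = c(6, 6, 6),
                                      rim_width = 2, edema_width = 2), seed = 5)
  # independent voxel-by-voxel membership test over concentric spheres
  oracle <- array(0, shape)
  brad <- 0.44 * shape
  for (k in 1:shape[3]) for (j in 1:shape[2]) for (i in 1:shape[1]) {
    inb <- sum(((c(i, j, k) - ctr) / brad)^2) <= 1
    if (!inb) next
    r <- sqrt(sum((c(i, j, k) - ctr)^2))
    if (r <= 4) oracle[i, j, k] <- 1
    else if (r <= 6) oracle[i, j, k] <- 4
    else if (r <= 8) oracle[i, j, k] <- 2
  }
  expect_identical(ph$labels, oracle)
  expect_equal(ph$tumor_volume_ml, sum(oracle != 0) / 1000)
})

test_that("a tumor that does not fit in the brain is rejected, naming the radius", {
  expect_error(
    make_base_phantom(c(16, 16, 16),
                      list(center = c(8.5, 8.5, 8.5), radii = c(12, 3, 3)), seed = 1),
    "radius 12")
})

test_that("tumor contrast orderings hold on noise-free phantoms", {
  for (seed in 1:3) {
    ph <- tiny_phantom(seed = seed, shape = c(28L, 28L, 28L))
    v <- ph$volume$data
    tissue <- ph$labels == 0 & apply(v != 0, 1:3, any)
    tumor <- ph$labels != 0
    for (ch in c(2, 3))  # T2, FLAIR hyperintense tumor
      expect_gt(mean(v[, , , ch][tumor]), mean(v[, , , ch][tissue]))
    expect_gt(mean(v[, , , 4][ph$labels == 4]),   # GdT1 rim > necrotic core
              mean(v[, , , 4][ph$labels == 1]))
    expect_lt(mean(v[, , , 1][ph$labels == 1]),   # T1 core < tissue
              mean(v[, , , 1][tissue]))
    # outside the brain exactly zero
    expect_true(all(v[!array(apply(v != 0, 1:3, any), dim(v))] == 0))
  }
})

test_that("the identity facility transform is a bit-identical no-op", {
  ph <- tiny_phantom(seed = 2)
  id_spec <- facility_spec("ID")
  out <- apply_facility_transform(ph, id_spec, seed = 9)
  expect_identical(out$volume$data, ph$volume$data)
  expect_identical(out$labels, ph$labels)
  expect_equal(out$facility_id, "ID")
})

test_that("gamma acts pointwise on unit-normalized intensities", {
  ph <- tiny_phantom(seed = 4)
  sp <- facility_spec("G", gamma = 2)
  out <- apply_facility_transform(ph, sp, seed = 1)
  supp <- apply(ph$volume$data != 0, 1:3, any)
  for (ch in 1:4) {
    v <- ph$volume$data[, , , ch]
    expected <- (v[supp] / max(v[supp]))^2
    expect_equal(out$volume$data[, , , ch][supp], expected, tolerance = 1e-12)
  }
})

test_that("gamma rejects nonpositive in-brain intensities", {
  ph <- tiny_phantom(seed = 4)
  sp <- facility_spec("bad", intensity_offset = -5, gamma = 2)
  expect_error(apply_facility_transform(ph, sp, seed = 1), "positive")
})

test_that("slice-thickness degradation matches a brute-force block-average oracle", {
  ph <- tiny_phantom(seed = 6, shape = c(16L, 16L, 32L))
  sp <- facility_spec("thick", slice_thickness_factor = 4L)
  out <- apply_facility_transform(ph, sp, seed = 1)
  brain <- apply(ph$volume$data != 0, 1:3, any)
  for (ch in 1:4) {
    v <- ph$volume$data[, , , ch]
    oracle <- v
    for (g in 1:8) {
      sl <- ((g - 1) * 4 + 1):(g * 4)
      m <- (v[, , sl[1]] + v[, , sl[2]] + v[, , sl[3]] + v[, , sl[4]]) / 4
      for (s in sl) oracle[, , s] <- m
    }
    oracle[!brain] <- 0
    expect_equal(out$volume$data[, , , ch], oracle, tolerance = 1e-12)
    # piecewise constant in z within a block, over columns in-brain in both
    both <- brain[, , 15] & brain[, , 16]
    expect_equal(out$volume$data[, , 15, ch][both],
                 out$volume$data[, , 16, ch][both])
  }
  expect_identical(out$labels, ph$labels)
})

test_that("facility transforms never modify labels and distinct gammas separate", {
  ph <- tiny_phantom(seed = 11)
  s1 <- facility_spec("F1", gamma = 1.0)
  s2 <- facility_spec("F2", gamma = 1.5)
  o1 <- apply_facility_transform(ph, s1, seed = 3)
  o2 <- apply_facility_transform(ph, s2, seed = 3)
  expect_identical(o1$labels, ph$labels)
  expect_identical(o2$labels, ph$labels)
  expect_gt(mean(abs(o1$volume$data - o2$volume$data)), 10 * .Machine$double.eps)
})

test_that("facility datasets are deterministic and respect volume bounds", {
  sp <- facility_spec("F", noise_sigma = 0.02, rng_seed_offset = 5L)
  smp <- tumor_sampler(radius_range = c(4, 8))
  d1 <- generate_facility_dataset(sp, 5, c(32, 32, 32), smp, seed = 21)
  d2 <- generate_facility_dataset(sp, 5, c(32, 32, 32), smp, seed = 21)
  expect_equal(length(d1), 5)
  for (i in 1:5) expect_identical(d1[[i]]$volume$data, d2[[i]]$volume$data)

  # analytic bounds: smallest/largest rasterized whole-tumor ellipsoid
  rast_sphere_ml <- function(r) {
    g <- seq_len(32) - 16.5
    sum(outer(outer(g^2, g^2, `+`), g^2, `+`) <= r^2) / 1000
  }
  lo <- rast_sphere_ml(4 + smp$edema_width)
  hi <- rast_sphere_ml(8 + smp$edema_width)
  for (cs in d1) {
    expect_gte(cs$tumor_volume_ml, lo * 0.9)  # centers are jittered off-grid
    expect_lte(cs$tumor_volume_ml, hi * 1.1)
    expect_equal(cs$tumor_volume_ml, sum(cs$labels != 0) / 1000)
  }
})

test_that("an empty-tumor sampler yields cases with empty masks", {
  sp <- facility_spec("F")
  d <- generate_facility_dataset(sp, 1, c(16, 16, 16),
                                 tumor_sampler(radius_range = c(0, 0)), seed = 2)
  expect_equal(length(d), 1)
  expect_equal(sum(d[[1]]$labels != 0), 0)
})

test_that("facility specs round-trip through YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("siteA:",
               "  gamma: 1.4",
               "  noise_sigma: 0.05",
               "  slice_thickness_factor: 3",
               "siteB:",
               "  bias_field_amplitude: 0.15"), path)
  specs <- read_facility_specs(path)
  expect_named(specs, c("siteA", "siteB"))
  expect_equal(specs$siteA$gamma, 1.4)
  expect_equal(specs$siteA$slice_thickness_factor, 3L)
  expect_equal(specs$siteB$bias_field_amplitude, 0.15)
  expect_s3_class(specs$siteA, "facility_spec")
})
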