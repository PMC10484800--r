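make_flat_mu <- function(arr, sp = c(6, 6, 6)) {
  petcorr:::mu_map(image_volume(arr, sp, role = "lac_cm"), "reference")
}

test_that("with zero attenuation the sinogram is a plain Radon transform", {
  d <- c(32, 32, 1); sp <- c(6, 6, 6)
  act <- array(0, d); act[16, 16, 1] <- 1000
  av <- image_volume(act, sp, role = "activity_bqml")
  mu0 <- make_flat_mu(array(0, d))
  cfg <- recon_config(n_angles = 42, subsets = 21, post_fwhm_mm = 0)
  sino <- forward_project(av, mu0, cfg)
  # a single voxel integrates to activity x voxel width (in cm) at any angle
  per_angle <- apply(sino$data[, , 1], 2, sum)
  expect_equal(unname(per_angle), rep(1000 * 0.6, 42), tolerance = 0.01)

  # zero activity gives a zero sinogram
  sino0 <- forward_project(with_data(av, array(0, d)), mu0, cfg)
  expect_true(all(sino0$data == 0))
})

test_that("a uniform slab attenuates an axis-aligned ray by exp(-mu t)", {
  d <- c(40, 40, 1); sp <- c(6, 6, 6)
  act <- array(0, d); act[30, 20, 1] <- 1000
  av <- image_volume(act, sp, role = "activity_bqml")
  # slab of mu = 0.1 / cm, 17 voxels x 6 mm = 10.2 cm thick, across the ray
  mu <- array(0, d)
  mu[5:21, 14:26, 1] <- 0.1
  cfg <- recon_config(n_angles = 42, subsets = 21, post_fwhm_mm = 0)
  free <- forward_project(av, make_flat_mu(array(0, d)), cfg)
  att <- forward_project(av, make_flat_mu(mu), cfg)
  # angle index 1 is theta = 0: rays run along x
  f <- free$data[, 1, 1]; a <- att$data[, 1, 1]
  hot <- which(f > 0)
  expect_equal(sum(a[hot]) / sum(f[hot]), exp(-0.1 * 10.2), tolerance = 0.02)
})

test_that("total counts are proportional to total activity when mu is zero", {
  cfg <- recon_config(n_angles = 42, subsets = 21, post_fwhm_mm = 0)
  v1 <- random_volume(c(24, 24, 1), 0, 1000, seed = 1)
  v1$spacing <- c(6, 6, 6)
  v2 <- with_data(v1, v1$data * 3.7)
  mu0 <- make_flat_mu(array(0, dim(v1$data)))
  s1 <- forward_project(v1, mu0, cfg)
  s2 <- forward_project(v2, mu0, cfg)
  expect_equal(sum(s2$data) / sum(s1$data), 3.7, tolerance = 1e-10)
  # per-angle totals are flat across angles (full angular sampling)
  per_angle <- apply(s1$data[, , 1], 2, sum)
  expect_lt(diff(range(per_angle)) / mean(per_angle), 0.05)
})

test_that("matched noiseless OSEM recovers a uniform disc within 5 percent", {
  d <- c(64, 64, 1); sp <- c(6, 6, 6)
  xs <- (1:64 - 32.5) * 6
  r2 <- outer(xs^2, xs^2, "+")
  act <- array(0, d); act[, , 1][r2 <= 120^2] <- 1000
  mu <- array(0, d); mu[, , 1][r2 <= 150^2] <- 0.096
  av <- image_volume(act, sp, role = "activity_bqml")
  muv <- make_flat_mu(mu)
  cfg <- recon_config(iterations = 3, subsets = 21, post_fwhm_mm = 0)
  rec <- reconstruct(forward_project(av, muv, cfg), muv, cfg)
  inside <- r2 <= 110^2
  expect_equal(mean(rec$data[, , 1][inside]) / 1000, 1, tolerance = 0.05)
  expect_true(all(rec$data >= 0))
})

test_that("OSEM with one subset equals a naive MLEM implementation", {
  d <- c(32, 32, 1); sp <- c(6, 6, 6)
  xs <- (1:32 - 16.5) * 6
  r2 <- outer(xs^2, xs^2, "+")
  act <- array(0, d); act[, , 1][r2 <= 60^2] <- 800
  mu <- array(0, d); mu[, , 1][r2 <= 80^2] <- 0.096
  av <- image_volume(act, sp, role = "activity_bqml")
  muv <- make_flat_mu(mu)
  cfg <- recon_config(iterations = 3, subsets = 1, n_angles = 30,
                      post_fwhm_mm = 0)
  sino <- forward_project(av, muv, cfg)
  rec <- reconstruct(sino, muv, cfg)

  # independent MLEM: dense system matrix, textbook multiplicative update
  g <- petcorr:::projector_matrix(32, 32, 6, 6, 30, sino$n_bins,
                                  sino$bin_width_mm)
  A <- as.matrix(g$A)
  attf <- exp(-as.numeric(A %*% as.numeric(mu)))
  B <- A * attf                       # row-scaled dense matrix
  y <- as.numeric(sino$data[, , 1])
  sens <- colSums(B)
  x <- rep(1, 32 * 32)
  for (it in 1:3) {
    q <- as.numeric(B %*% x)
    ratio <- ifelse(q > 1e-12, y / q, 0)
    bp <- as.numeric(t(B) %*% ratio)
    upd <- sens > 1e-12
    x[upd] <- x[upd] * bp[upd] / sens[upd]
    x[!upd] <- 0
  }
  expect_equal(as.numeric(rec$data[, , 1]), x, tolerance = 1e-8)
})

test_that("an empty sinogram reconstructs to the zero image", {
  cs <- small_case()
  sino <- cs$pets$sinogram
  sino$data[] <- 0
  rec <- reconstruct(sino, cs$muref, cs$cfg)
  expect_true(all(rec$data == 0))
})

test_that("identical mu-maps give bit-identical PET pairs, deterministically", {
  ph <- generate_phantom(small_spec(seed = 31, shape = c(48, 48, 2)))
  mm <- phantom_mumaps(ph)
  cfg <- recon_config()
  same <- simulate_pet_pair(ph, mm$muref, mm$muref, cfg)
  expect_identical(same$pet_4c$data, same$pet_ctmr$data)
  again <- simulate_pet_pair(ph, mm$muref, mm$muref, cfg)
  expect_identical(same$pet_4c$data, again$pet_4c$data)
})

test_that("omitting bone depresses the reconstruction inside bone", {
  cs <- small_case()
  bone <- cs$phantom$labels$data == 3 & cs$phantom$pelvic_mask
  expect_lt(mean(cs$pets$pet_4c$data[bone]), mean(cs$pets$pet_ctmr$data[bone]))
})

test_that("underestimation deepens monotonically with inserted bone LAC", {
  ph <- generate_phantom(small_spec(seed = 33, shape = c(48, 48, 2)))
  mm <- phantom_mumaps(ph)
  cfg <- recon_config()
  bone <- ph$labels$data %in% c(3, 4) & ph$pelvic_mask
  means <- vapply(c(0.5, 1, 1.5), function(f) {
    boosted <- mm$mu4c$volume$data
    sel <- mm$muref$volume$data > mm$mu4c$volume$data
    boosted[sel] <- mm$mu4c$volume$data[sel] +
      f * (mm$muref$volume$data[sel] - mm$mu4c$volume$data[sel])
    muref_f <- petcorr:::mu_map(with_data(mm$muref$volume, boosted), "reference")
    pets <- simulate_pet_pair(ph, mm$mu4c, muref_f, cfg)
    mean(pets$pet_4c$data[bone]) / mean(pets$pet_ctmr$data[bone])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("Poisson noise is reproducible from the seed and preserves scale", {
  ph <- generate_phantom(small_spec(seed = 35, shape = c(48, 48, 2)))
  mm <- phantom_mumaps(ph)
  cfg <- recon_config(noise = TRUE, mean_true_counts = 1e5, seed = 42)
  s1 <- forward_project(ph$activity, mm$muref, cfg)
  s2 <- forward_project(ph$activity, mm$muref, cfg)
  expect_identical(s1$data, s2$data)
  cfg2 <- recon_config(noise = TRUE, mean_true_counts = 1e5, seed = 43)
  s3 <- forward_project(ph$activity, mm$muref, cfg2)
  expect_false(identical(s1$data, s3$data))
  # unscaled expectation: noisy sinogram totals match noiseless within a few %
  s0 <- forward_project(ph$activity, mm$muref, recon_config())
  expect_equal(sum(s1$data), sum(s0$data), tolerance = 0.05)
})

test_that("sinograms round trip through NIfTI with their geometry sidecar", {
  cs <- small_case()
  path <- file.path(tempfile(), "sino.nii.gz")
  dir.create(dirname(path))
  on.exit(unlink(dirname(path), recursive = TRUE))
  write_sinogram(cs$pets$sinogram, path)
  back <- read_sinogram(path)
  expect_equal(back$data, cs$pets$sinogram$data, tolerance = 1e-6)
  expect_identical(back$shape, cs$pets$sinogram$shape)
  # a reconstruction from the re-read sinogram matches the original
  rec <- reconstruct(back, cs$muref, cs$cfg)
  expect_equal(rec$data, cs$pets$pet_ctmr$data, tolerance = 1e-6)
})
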