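# Physics of the artificial degradation operators.

test_that("the Gaussian PSF has the closed-form shape and unit mass", {
  px <- 1
  fwhm <- 2 * sqrt(2 * log(2)) # sigma = 1 px exactly
  k <- gaussian_psf(fwhm, px)
  expect_equal(sum(k$kernel), 1, tolerance = 1e-9)
  ctr <- (nrow(k$kernel) + 1) / 2
  expect_equal(k$kernel[ctr, ctr] / k$kernel[ctr, ctr + 1], exp(1 / 2),
               tolerance = 1e-9)
  # radial symmetry
  expect_equal(k$kernel, t(k$kernel), tolerance = 1e-12)
  expect_warning(gaussian_psf(0.2, 1), "near-delta")
})

test_that("blurring a constant slide is the identity and an impulse reproduces the kernel", {
  k <- gaussian_psf(3, 1)
  s <- const_slide(77L, 32)
  expect_identical(apply_blur(s, k)$channels, s$channels)
  imp <- array(0L, c(33, 33, 4)); imp[17, 17, ] <- 255L
  si <- virtual_slide(imp, "s", "i", "normal", 1)
  b <- apply_blur(si, k)
  half <- (nrow(k$kernel) - 1) / 2
  win <- (17 - half):(17 + half)
  expect_equal(b$channels[win, win, 1] * 1.0, round(255 * k$kernel),
               tolerance = 0)
})

test_that("the blurred impulse recovers the configured FWHM within 10%", {
  for (fwhm in c(4, 6)) {
    k <- gaussian_psf(fwhm, 1)
    imp <- array(0L, c(65, 65, 4)); imp[33, 33, ] <- 255L
    b <- apply_blur(virtual_slide(imp, "s", "i", "normal", 1), k)
    prof <- as.numeric(b$channels[33, , 1])
    xs <- 1:65 - 33
    sig <- sqrt(sum(prof * xs^2) / sum(prof))
    expect_lt(abs(2 * sqrt(2 * log(2)) * sig - fwhm) / fwhm, 0.10)
  }
})

test_that("blur preserves the per-channel spatial mean within one grey level", {
  g <- generate_slide(tissue_phenotype("cancer"), size_px = 256L, seed = 3L)
  b <- apply_blur(g$slide, gaussian_psf(4, 1))
  shift <- apply(b$channels, 3, mean) - apply(g$slide$channels, 3, mean)
  expect_true(all(abs(shift) < 1))
})

test_that("ambient noise has the configured sigma and is seed-deterministic", {
  flat <- const_slide(128L, 512)
  expect_identical(add_ambient_noise(flat, c(0, 0, 0, 0))$channels,
                   flat$channels)
  n1 <- add_ambient_noise(flat, c(10, 10, 10, 10), seed = 4L)
  n2 <- add_ambient_noise(flat, c(10, 10, 10, 10), seed = 4L)
  expect_identical(n1$channels, n2$channels)
  sds <- apply(n1$channels - flat$channels, 3, sd)
  expect_true(all(sds > 9 & sds < 11)) # clipping negligible at mid-grey
})

test_that("jitter is the identity when disabled and shifts all channels coherently", {
  s <- rand_slide(64, seed = 5)
  expect_identical(apply_vibration_jitter(s, 0L, 0.5, seed = 1L)$channels,
                   s$channels)
  expect_identical(apply_vibration_jitter(s, 3L, 0, seed = 1L)$channels,
                   s$channels)
  j <- apply_vibration_jitter(s, 2L, 0.5, seed = 6L)
  # every output row interior must be some shifted window of the input row,
  # with the same shift across all four channels
  m <- 2L; W <- 64L
  interior <- (1 + m):(W - m)
  for (r in 1:64) {
    shifts_found <- vapply(1:4, function(ch) {
      ok <- vapply(-m:m, function(sft)
        all(j$channels[r, interior, ch] ==
              s$channels[r, interior - sft, ch]), logical(1))
      which(ok)[1]
    }, numeric(1))
    expect_false(anyNA(shifts_found))
    expect_true(all(shifts_found == shifts_found[1]))
  }
})

test_that("downsampling follows block-mean arithmetic, shape and pixel-size rules", {
  s <- rand_slide(512, seed = 7, px = 1)
  d <- downsample(s, 4L)
  expect_equal(dim(d), c(128L, 128L))
  expect_equal(d$pixel_size_um, 4)
  # oracle: direct block mean on a sampled set of output pixels
  for (k in 1:10) {
    i <- sample(128, 1); j <- sample(128, 1); ch <- sample(4, 1)
    blk <- s$channels[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j), ch]
    expect_equal(unname(d$channels[i, j, ch]) * 1.0,
                 min(max(round(mean(blk)), 0), 255))
  }
  expect_identical(unname(downsample(const_slide(9L, 64), 4L)$channels[1, 1, 1]), 9L)
  expect_warning(downsample(rand_slide(30, seed = 8), 4L), "cropping")
})

test_that("degrade_slide composes the operators per mode, deterministically", {
  g <- generate_slide(tissue_phenotype("cancer"), size_px = 256L, seed = 9L)
  cfg <- degradation_config(mode = "none")
  expect_identical(degrade_slide(g$slide, cfg), g$slide)

  full <- degradation_config(mode = "full", seed = 3L)
  d1 <- degrade_slide(g$slide, full)
  d2 <- degrade_slide(g$slide, full)
  expect_identical(d1$channels, d2$channels)
  expect_equal(dim(d1), c(64L, 64L))
  expect_equal(d1$pixel_size_um, 4)
  expect_identical(d1$domain_tag, "synthetic_degraded")

  ds <- degrade_slide(g$slide, degradation_config(mode = "downsample_only",
                                                  seed = 3L))
  expect_equal(dim(ds), dim(d1))
  expect_false(identical(ds$channels, d1$channels))

  deg <- degrade_slide(g$slide, degradation_config(mode = "degrade_only",
                                                   seed = 3L))
  expect_equal(dim(deg), c(256L, 256L))
})

test_that("noise sigma is recoverable from flat-field fixtures within 5%", {
  cfg <- degradation_config(mode = "degrade_only", seed = 11L,
                            jitter_line_prob = 0)
  flat <- const_slide(128L, 512)
  d <- degrade_slide(flat, cfg)
  rec <- apply(d$channels - flat$channels[seq_len(dim(d)[1]),
                                          seq_len(dim(d)[2]), ] * 0 - 128, 3, sd)
  expect_true(all(abs(rec - cfg$ambient_noise_sigma) /
                    cfg$ambient_noise_sigma < 0.05))
})

test_that("downsample factor is recoverable exactly from the shape ratio", {
  s <- rand_slide(256, seed = 12)
  d <- degrade_slide(s, degradation_config(mode = "downsample_only",
                                           downsample_factor = 4L))
  expect_identical(dim(s)[1] / dim(d)[1], 4)
})
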