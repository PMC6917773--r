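# Slide/mask/manifest I/O and composite rendering.

test_that("write -> read round-trips a slide bit-exactly, including metadata", {
  for (s in list(rand_slide(32, seed = 3, px = 0.5), const_slide(0L, 16))) {
    f <- tempfile(fileext = ".tif")
    write_slide(s, f)
    r <- read_slide(f)
    expect_identical(r$channels, s$channels)
    expect_equal(r$pixel_size_um, s$pixel_size_um)
    expect_identical(r$subject_id, s$subject_id)
    expect_identical(r$label, s$label)
    expect_identical(r$domain_tag, s$domain_tag)
  }
})

test_that("constant planes read back with their plane means in channel order", {
  pages <- lapply(c(10, 20, 30, 40) / 255, function(v) matrix(v, 64, 64))
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 8L)
  rec <- list(subject_id = "s", slide_id = "sl", label = "normal",
              pixel_size_um = 1, domain_tag = "lab")
  s <- read_slide(f, rec)
  expect_equal(unname(apply(s$channels, 3, mean)), c(10, 20, 30, 40))
})

test_that("a file with the wrong plane count raises a format error naming the channel order", {
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:3, function(i) matrix(0.5, 8, 8)), f,
                  bits.per.sample = 8L)
  rec <- list(subject_id = "s", slide_id = "sl", label = "normal",
              pixel_size_um = 1, domain_tag = "lab")
  expect_error(read_slide(f, rec), "THG, NADH, SHG, FAD")
})

test_that("16-bit sources are min-max rescaled so channel max becomes 255", {
  pages <- lapply(1:4, function(i) matrix(seq(0, 1, length.out = 64), 8, 8))
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, f, bits.per.sample = 16L)
  rec <- list(subject_id = "s", slide_id = "sl", label = "normal",
              pixel_size_um = 1, domain_tag = "lab")
  s <- read_slide(f, rec)
  expect_equal(max(s$channels), 255L)
  expect_equal(min(s$channels), 0L)
})

test_that("slide construction enforces the data-model invariants", {
  expect_error(virtual_slide(array(0L, c(8, 8, 3)), "s", "l", "normal", 1),
               "THG")
  expect_error(virtual_slide(array(-1L, c(8, 8, 4)), "s", "l", "normal", 1),
               "\\[0, 255\\]")
  expect_error(virtual_slide(array(0L, c(8, 8, 4)), "s", "l", "normal", 0),
               "positive")
  expect_error(virtual_slide(array(0L, c(8, 8, 4)), "s", "l", "benign", 1))
})

test_that("manifest validation rejects duplicates and inconsistent labels", {
  m <- tibble::tibble(subject_id = c("a", "a"), slide_id = c("s1", "s1"),
                      label = "cancer", slide_path = "x", mask_path = NA,
                      pixel_size_um = 1, domain_tag = "lab")
  expect_error(mphisto:::validate_manifest(m), "duplicate")
  m2 <- tibble::tibble(subject_id = c("a", "a"), slide_id = c("s1", "s2"),
                       label = c("cancer", "normal"), slide_path = "x",
                       mask_path = NA, pixel_size_um = 1, domain_tag = "lab")
  expect_error(mphisto:::validate_manifest(m2), "exactly one label")
})

test_that("manifest CSV round-trips through write_manifest/read_manifest", {
  m <- tibble::tibble(subject_id = c("a", "b"), slide_id = c("s1", "s2"),
                      label = c("cancer", "normal"), slide_path = c("p1", "p2"),
                      mask_path = c(NA, "m2"), pixel_size_um = 1,
                      domain_tag = "synthetic_clean")
  f <- tempfile(fileext = ".csv")
  write_manifest(m, f)
  r <- read_manifest(f)
  expect_equal(r$subject_id, m$subject_id)
  expect_equal(r$label, m$label)
  expect_true(is.na(r$mask_path[1]))
})

test_that("mask files round-trip as binary planes", {
  m <- adipocyte_mask(matrix(c(0, 1, 1, 0), 2), "s")
  f <- tempfile(fileext = ".png")
  write_mask(m, f)
  expect_identical(read_mask(f, "s")$mask, m$mask)
})

test_that("composite rendering follows the colormap arithmetic", {
  z <- render_composite(const_slide(0L, 16))
  expect_true(all(z$rgb == 0))
  # SHG-only content: green strictly dominates red and blue wherever lit
  ch <- array(0L, c(16, 16, 4)); ch[, , 3] <- 100L
  s <- virtual_slide(ch, "s", "l", "normal", 1)
  r <- render_composite(s)
  expect_true(all(r$rgb[, , 2] > r$rgb[, , 1]))
  expect_true(all(r$rgb[, , 2] > r$rgb[, , 3]))
  # rendering is deterministic
  expect_identical(r$rgb, render_composite(s)$rgb)
})

test_that("a probability overlay can only push the red plane up", {
  s <- rand_slide(32, seed = 9)
  base <- render_composite(s)
  grid <- tidyr::expand_grid(row = 1:2, col = 1:2)
  grid$r0 <- (grid$row - 1L) * 16L; grid$c0 <- (grid$col - 1L) * 16L
  grid$fraction <- 0; grid$retained <- TRUE; grid$prob <- 1
  pm <- structure(list(slide_id = s$slide_id, label = s$label, tile_size = 16L,
                       stride = 16L, dims = c(32L, 32L), grid = grid),
                  class = "tile_prob_map")
  over <- render_composite(s, prob_map = pm)
  expect_true(all(over$rgb[, , 1] >= base$rgb[, , 1]))
})

test_that("misaligned overlays raise alignment errors", {
  s <- rand_slide(32, seed = 10)
  bad <- adipocyte_mask(matrix(0, 16, 16), "s")
  expect_error(render_composite(s, mask = bad), "misaligned")
})
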