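# Synthetic-cohort simulator: determinism, geometry expectations, cohort
# structure.

empty_phenotype <- function() {
  ph <- tissue_phenotype("normal", noise_sigma = 0)
  ph$objects$density[] <- 0
  ph
}

test_that("zero densities and zero noise give an all-zero slide and empty ground truth", {
  g <- generate_slide(empty_phenotype(), size_px = 128L, seed = 1L)
  expect_true(all(g$slide$channels == 0L))
  expect_equal(nrow(g$ground_truth$objects), 0L)
  expect_true(all(g$ground_truth$mask$mask == 0L))
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_slide(tissue_phenotype("cancer"), size_px = 256L, seed = 42L)
  b <- generate_slide(tissue_phenotype("cancer"), size_px = 256L, seed = 42L)
  expect_identical(a$slide$channels, b$slide$channels)
  expect_identical(a$ground_truth$objects, b$ground_truth$objects)
  expect_identical(a$ground_truth$mask$mask, b$ground_truth$mask$mask)
})

test_that("degenerate densities are rejected", {
  ph <- tissue_phenotype("normal")
  ph$objects$density[1] <- 1e9
  expect_error(generate_slide(ph, size_px = 128L, seed = 1L), "degenerate")
})

test_that("adipocyte mask area matches an independent Monte-Carlo oracle", {
  # generator under test: adipocytes only
  ph <- empty_phenotype()
  ph$objects$density[ph$objects$object == "adipocyte"] <- 12
  size <- 256L
  fracs <- vapply(1:60, function(s)
    mean(generate_slide(ph, size_px = size, seed = s)$ground_truth$mask$mask),
    numeric(1))

  # independent oracle: same stochastic geometry (Poisson count, uniform
  # centres, U(15, 60) radii) rasterised by a plain distance-grid union
  set.seed(999)
  area_mm2 <- (size / 1000)^2
  oracle <- vapply(1:200, function(s) {
    n <- rpois(1, 12 * area_mm2)
    m <- matrix(FALSE, size, size)
    if (n > 0) for (i in seq_len(n)) {
      r0 <- sample.int(size, 1); c0 <- sample.int(size, 1)
      rad <- runif(1, 15, 60)
      rr <- pmax(1, floor(r0 - rad)):pmin(size, ceiling(r0 + rad))
      cc <- pmax(1, floor(c0 - rad)):pmin(size, ceiling(c0 + rad))
      d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
      m[rr, cc] <- m[rr, cc] | (d2 <= rad^2)
    }
    mean(m)
  }, numeric(1))

  se <- sqrt(var(fracs) / length(fracs) + var(oracle) / length(oracle))
  expect_lt(abs(mean(fracs) - mean(oracle)), 3 * se + 0.002)
})

test_that("cancer slides carry more vesicle clusters than normal slides", {
  counts <- function(class) vapply(1:20, function(s) {
    g <- generate_slide(tissue_phenotype(class), size_px = 256L, seed = 500L + s)
    sum(g$ground_truth$objects$type == "vesicle_cluster")
  }, numeric(1))
  expect_gt(mean(counts("cancer")), mean(counts("normal")))
})

test_that("cohort generation writes a consistent, reproducible manifest", {
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  m1 <- generate_cohort(2, 2, 3, size_px = 128L, out_dir = d1, seed = 7L)
  m2 <- generate_cohort(2, 2, 3, size_px = 128L, out_dir = d2, seed = 7L)
  expect_equal(nrow(m1), 12L)
  expect_equal(length(unique(m1$subject_id)), 4L)
  expect_equal(m1$slide_id, m2$slide_id)
  for (i in c(1L, 7L)) {
    a <- read_slide(m1$slide_path[i], m1[i, ])
    b <- read_slide(m2$slide_path[i], m2[i, ])
    expect_identical(a$channels, b$channels)
  }
})

test_that("the ground-truth mask written to disk equals the rasterised geometry", {
  d <- file.path(tempdir(), "coh_gt")
  m <- generate_cohort(1, 1, 1, size_px = 256L, out_dir = d, seed = 13L)
  co <- load_cohort(m)
  sid <- m$slide_id[1]
  g <- generate_slide(tissue_phenotype("cancer"),
                      subject_effect = exp(stats::rnorm(1)), # dummy; regenerate below
                      size_px = 4L, seed = 1L)
  # regenerate the exact slide via the derived seed and compare masks
  set.seed(derive_seed(13L, "subject", m$subject_id[1]))
  eff <- exp(stats::rnorm(1, 0, tissue_phenotype("cancer")$subject_sd))
  regen <- generate_slide(tissue_phenotype(m$label[1]), subject_effect = eff,
                          size_px = 256L,
                          seed = derive_seed(13L, "slide", m$subject_id[1], 1),
                          subject_id = m$subject_id[1], slide_id = sid)
  expect_identical(co$masks[[sid]]$mask, regen$ground_truth$mask$mask)
})

test_that("subject random effects induce intra-subject correlation in object counts", {
  man <- generate_cohort(5, 5, 3, size_px = 512L,
                         out_dir = file.path(tempdir(), "coh_icc"), seed = 21L)
  counts <- vapply(seq_len(nrow(man)), function(i) {
    gt <- jsonlite::read_json(man$gt_path[i], simplifyVector = TRUE)
    nrow(gt)
  }, numeric(1))
  df <- data.frame(subject = man$subject_id, label = man$label, n = counts)
  # within-class one-way decomposition: between-subject mean square should
  # exceed within-subject mean square when the random effect is active
  ms <- lapply(split(df, df$label), function(x) {
    fit <- stats::aov(n ~ subject, data = x)
    s <- summary(fit)[[1]]
    c(between = s[["Mean Sq"]][1], within = s[["Mean Sq"]][2])
  })
  agg <- Reduce(`+`, ms) / length(ms)
  expect_gt(agg[["between"]], agg[["within"]])
})

test_that("derived seeds are stable and identifier-sensitive", {
  expect_identical(derive_seed(7L, "a", 1), derive_seed(7L, "a", 1))
  expect_false(derive_seed(7L, "a", 1) == derive_seed(7L, "a", 2))
  expect_true(derive_seed(7L, "x") >= 1 && derive_seed(7L, "x") < 2^31)
})
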