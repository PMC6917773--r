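# Cohort splitting, tile sampling, training contracts, tile inference.

test_that("split_cohort assigns rounded per-class fractions without overlap", {
  man <- tibble::tibble(
    subject_id = c(sprintf("C%02d", 1:10), sprintf("N%02d", 1:10)),
    slide_id = paste0("s", 1:20),
    label = rep(c("cancer", "normal"), each = 10),
    slide_path = "x", mask_path = NA, pixel_size_um = 1,
    domain_tag = "synthetic_clean")
  sp <- split_cohort(man, seed = 3L)
  tab <- table(sp$partition, sp$label)
  expect_equal(unname(tab[, "cancer"]), unname(tab[, "normal"]))
  expect_equal(sort(unname(tab[, "cancer"])), c(1L, 4L, 5L))
  expect_equal(anyDuplicated(sp$subject_id), 0L)
  expect_identical(sp, split_cohort(man, seed = 3L))
  expect_false(identical(sp$partition, split_cohort(man, seed = 4L)$partition))
})

test_that("split_cohort refuses classes with fewer than three subjects", {
  man <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                        slide_id = paste0("s", 1:4),
                        label = c("cancer", "cancer", "cancer", "normal"),
                        slide_path = "x", mask_path = NA, pixel_size_um = 1,
                        domain_tag = "synthetic_clean")
  expect_error(split_cohort(man), "at least 3")
  # exactly three subjects per class -> one per partition
  man3 <- tibble::tibble(subject_id = paste0("s", 1:6),
                         slide_id = paste0("sl", 1:6),
                         label = rep(c("cancer", "normal"), each = 3),
                         slide_path = "x", mask_path = NA, pixel_size_um = 1,
                         domain_tag = "synthetic_clean")
  sp3 <- split_cohort(man3, seed = 1L)
  expect_equal(unname(table(sp3$partition, sp3$label)),
               matrix(1L, 3, 2))
})

test_that("sampled tiles always satisfy the retention rule (fuzzed against the oracle)", {
  set.seed(17)
  slides <- list(); masks <- list()
  for (i in 1:4) {
    s <- rand_slide(96, seed = 20 + i,
                    label = if (i <= 2) "cancer" else "normal")
    s$slide_id <- paste0("fz", i)
    m <- matrix(0L, 96, 96)
    # random adipocyte-like blocks
    for (b in 1:6) {
      r <- sample(1:64, 1); c <- sample(1:64, 1); w <- sample(8:32, 1)
      m[r:min(96, r + w), c:min(96, c + w)] <- 1L
    }
    slides[[i]] <- s; masks[[i]] <- adipocyte_mask(m, s$slide_id)
  }
  names(slides) <- vapply(slides, `[[`, character(1), "slide_id")
  for (rep in 1:25) {
    batch <- sample_batch(slides, masks, retention_rule(), tile_size = 32L,
                          seed = rep, batch_size = 4L)
    expect_length(batch, 4L)
    for (t in batch) {
      si <- match(t$slide_id, names(slides))
      frac <- sum(masks[[si]]$mask[(t$origin[1] + 1):(t$origin[1] + 32),
                                   (t$origin[2] + 1):(t$origin[2] + 32)]) / 1024
      expect_lt(frac, 0.5)
    }
    expect_equal(sum(vapply(batch, `[[`, character(1), "label") == "cancer"), 2L)
  }
})

test_that("a fully adipocyte-covered slide never contributes tiles and can exhaust sampling", {
  s1 <- rand_slide(64, seed = 30, label = "cancer"); s1$slide_id <- "full"
  s2 <- rand_slide(64, seed = 31, label = "normal"); s2$slide_id <- "free"
  slides <- list(full = s1, free = s2)
  masks <- list(adipocyte_mask(matrix(1L, 64, 64), "full"), NULL)
  # cancer tiles can only come from the covered slide -> exhaustion
  expect_error(sample_batch(slides, masks, tile_size = 32L, seed = 1L),
               "sampling exhausted")
  # with a free slide per class, the covered slide never contributes
  s3 <- rand_slide(64, seed = 32, label = "cancer"); s3$slide_id <- "free_c"
  slides$full$label <- "cancer"
  slides3 <- c(slides, list(free_c = s3))
  masks3 <- c(masks, list(NULL))
  batch <- sample_batch(slides3, masks3, tile_size = 32L, seed = 1L,
                        max_retries = 200L)
  expect_true(all(vapply(batch, `[[`, character(1), "slide_id") != "full"))
})

test_that("batch sampling is deterministic under a fixed seed", {
  fx <- fx_cohort()
  idx <- which(fx$manifest$label == "cancer")[1:2]
  idx <- c(idx, which(fx$manifest$label == "normal")[1:2])
  a <- sample_batch(fx$slides[idx], fx$masks[idx], tile_size = 64L, seed = 5L)
  b <- sample_batch(fx$slides[idx], fx$masks[idx], tile_size = 64L, seed = 5L)
  expect_identical(a, b)
})

test_that("the training loop structurally refuses out-of-partition subjects", {
  fx <- fx_cohort(); sp <- fx_split()
  tampered <- sp
  tampered$partition[tampered$partition == "train"] <- "test"
  cfg <- train_config(tile_size_px = 128L, max_iterations = 2L,
                      eval_every = 2L, n_val_tiles = 8L)
  expect_error(
    {
      tr <- mphisto:::partition_slides(fx, sp, "train")
      mphisto:::assert_partition(tr$slides, tampered, "train")
    },
    "subject-disjointness violation")
  # and a split missing assignments is rejected outright
  missing <- sp[sp$partition != "train", ]
  class(missing) <- class(sp)
  expect_error(train_classifier(fx, missing, cfg),
               "subject-disjointness violation|no partition")
})

test_that("short training runs are reproducible and log loss with validation AUC", {
  fx <- fx_cohort(); sp <- fx_split()
  cfg <- train_config(tile_size_px = 128L, max_iterations = 20L,
                      eval_every = 10L, n_val_tiles = 16L, seed = 8L)
  a <- train_classifier(fx, sp, cfg)
  b <- train_classifier(fx, sp, cfg)
  expect_identical(tidy(a), tidy(b))
  expect_named(tidy(a), c("iteration", "loss", "val_auc"))
  expect_true(all(tidy(a)$val_auc >= 0 & tidy(a)$val_auc <= 1))
  expect_true(glance(a)$trained)
  # first evaluated loss should be near the balanced cross-entropy start
  expect_lt(abs(tidy(a)$loss[1] - log(2)), 0.5)
})

test_that("predict_tiles lays out the heatmap grid and respects exclusions", {
  m <- resnet20(seed = 4)
  s <- rand_slide(512, seed = 40, label = "cancer")
  pm <- predict_tiles(m, s, tile_size = 128L)
  expect_equal(max(pm$grid$row), 4L)
  expect_equal(max(pm$grid$col), 4L)
  expect_equal(nrow(pm$grid), 16L)
  expect_true(all(pm$grid$prob >= 0 & pm$grid$prob <= 1))
  # full adipocyte cover -> zero retained tiles, flagged not error
  full <- adipocyte_mask(matrix(1L, 512, 512), s$slide_id)
  pm0 <- predict_tiles(m, s, full, tile_size = 128L)
  expect_equal(sum(pm0$grid$retained), 0L)
  expect_true(all(is.na(pm0$grid$prob)))
  # overlapping stride
  pm2 <- predict_tiles(m, s, tile_size = 128L, stride = 64L)
  expect_equal(nrow(pm2$grid), 49L)
  expect_error(predict_tiles(m, rand_slide(64, seed = 1), tile_size = 128L),
               "smaller than the tile size")
})

test_that("the pipeline accepts all three published tile sizes", {
  m <- resnet20(seed = 6)
  for (ts in c(128L, 256L, 512L)) {
    x <- array(runif(ts * ts * 4), c(ts, ts, 4, 1))
    fw <- mphisto:::nn_forward(m$net, x, train = FALSE)
    expect_equal(dim(fw$out), c(1L, 1L))
  }
})
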