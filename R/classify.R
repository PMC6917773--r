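# Subject-disjoint splitting, rejection-sampled tile extraction, classifier
# training and tile-level inference.
#
# The unit of splitting is the subject, never the slide or tile: tiles from
# one subject are strongly correlated, and slide- or tile-level splits would
# leak that correlation into the test set and inflate accuracy.

#' Split a cohort into train/validation/test by subject
#'
#' Subjects are shuffled within class and assigned whole to one partition;
#' partition sizes are the rounded fractions per class, adjusted so every
#' partition keeps at least one subject (each class needs >= 3 subjects).
#' No subject ever appears in two partitions.
#'
#' @param manifest a manifest tibble.
#' @param fractions named fractions `c(train=, val=, test=)` summing to 1.
#' @param seed integer seed.
#' @return a `cohort_split` tibble: `subject_id`, `label`, `partition`.
#' @export
split_cohort <- function(manifest, fractions = c(train = 0.5, val = 0.1, test = 0.4),
                         seed = 1L) {
  validate_manifest(manifest)
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  subjects <- dplyr::distinct(manifest, .data$subject_id, .data$label)
  set.seed(seed)
  parts <- lapply(split(subjects, subjects$label), function(s) {
    n <- nrow(s)
    if (n < 3L)
      stop("too few subjects in class '", s$label[1], "' (", n,
           "): need at least 3, one per partition")
    cnt <- c(train = round(fractions[["train"]] * n),
             val = round(fractions[["val"]] * n))
    cnt["test"] <- n - sum(cnt)
    # rounded fractions, but every partition keeps at least one subject
    while (any(cnt < 1L)) {
      cnt[which.min(cnt)] <- cnt[which.min(cnt)] + 1L
      cnt[which.max(cnt)] <- cnt[which.max(cnt)] - 1L
    }
    n_tr <- cnt[["train"]]; n_va <- cnt[["val"]]; n_te <- cnt[["test"]]
    s$partition <- sample(rep(c("train", "val", "test"), c(n_tr, n_va, n_te)))
    s
  })
  out <- dplyr::arrange(dplyr::bind_rows(parts), .data$subject_id)
  class(out) <- c("cohort_split", class(out))
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  out
}

# structural subject-disjointness guard: every slide's subject must be
# assigned to `partition` in `split`
assert_partition <- function(slides, split, partition) {
  lab <- stats::setNames(split$partition, split$subject_id)
  for (s in slides) {
    p <- lab[[s$subject_id]]
    if (is.null(p) || is.na(p))
      stop("subject-disjointness violation: subject ", s$subject_id,
           " has no partition assignment")
    if (p != partition)
      stop("subject-disjointness violation: slide ", s$slide_id,
           " belongs to subject ", s$subject_id, " in partition '", p,
           "' but was offered to '", partition, "'")
  }
  invisible(TRUE)
}

# slides/masks of one partition, with the guard applied
partition_slides <- function(cohort, split, partition) {
  unassigned <- setdiff(cohort$manifest$subject_id, split$subject_id)
  if (length(unassigned))
    stop("subject-disjointness violation: subject(s) ",
         paste(unassigned, collapse = ", "), " have no partition assignment")
  subj <- split$subject_id[split$partition == partition]
  idx <- which(cohort$manifest$subject_id %in% subj)
  slides <- cohort$slides[idx]
  assert_partition(slides, split, partition)
  list(slides = slides, masks = cohort$masks[idx])
}

#' Training configuration for the tile classifier
#'
#' Defaults are the method's standard optimiser settings: mini-batches of four
#' tiles, Adam with learning rate 5e-4, beta1 0.9, beta2 0.999, epsilon
#' 1e-8, binary cross-entropy loss, 256-px tiles.
#'
#' @param tile_size_px tile side in clean-domain pixels (128, 256 or 512).
#' @param batch_size tiles per iteration.
#' @param learning_rate,adam_beta1,adam_beta2,adam_epsilon Adam parameters.
#' @param max_iterations iteration budget.
#' @param eval_every validation-AUC checkpoint interval (iterations).
#' @param n_val_tiles size of the fixed validation tile set.
#' @param augment optional [degradation_config()] applied to every training
#'   and validation tile (physics-based augmentation; its `mode` selects the
#'   ablation arm).
#' @param seed integer seed.
#' @export
train_config <- function(tile_size_px = 256L, batch_size = 4L,
                         learning_rate = 5e-4, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, adam_epsilon = 1e-8,
                         max_iterations = 10000L, eval_every = 200L,
                         n_val_tiles = 64L, augment = NULL, seed = 1L) {
  stopifnot(tile_size_px %in% c(128L, 256L, 512L))
  structure(list(tile_size_px = as.integer(tile_size_px),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, adam_epsilon = adam_epsilon,
                 max_iterations = as.integer(max_iterations),
                 eval_every = as.integer(eval_every),
                 n_val_tiles = as.integer(n_val_tiles),
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Rejection-sample a class-balanced mini-batch of tiles
#'
#' Tiles are randomly cropped from randomly chosen slides of the requested
#' class, and accepted only if they satisfy the retention rule (adipocyte
#' fraction strictly below the rule's threshold). Sampling retries up to
#' `max_retries` per tile and then errors.
#'
#' @param slides named list of [virtual_slide()]s (one partition).
#' @param masks list of `adipocyte_mask`es aligned to `slides` (NULL entries
#'   mean no adipocytes).
#' @param rule a [retention_rule()].
#' @param tile_size tile side in pixels.
#' @param seed integer seed.
#' @param batch_size number of tiles (default 4, stratified 2+2 by class).
#' @param max_retries rejection-sampling cap per tile.
#' @return list of tile samples: `x` (tile_size x tile_size x 4 integer
#'   array), `label`, `slide_id`, `origin` (0-based row, col).
#' @export
sample_batch <- function(slides, masks, rule = retention_rule(),
                         tile_size = 256L, seed = NULL, batch_size = 4L,
                         max_retries = 100L) {
  if (!is.null(seed)) set.seed(seed)
  labels <- vapply(slides, function(s) s$label, character(1))
  # alternate so both classes get equal expected representation (2+2 at the
  # default batch size)
  classes <- rep(c("cancer", "normal"), length.out = batch_size)
  for (cl in unique(classes))
    if (!any(labels == cl))
      stop("partition contains no '", cl, "' slides to sample from")
  out <- vector("list", batch_size)
  for (b in seq_len(batch_size)) {
    cl <- classes[b]
    cand <- which(labels == cl)
    for (attempt in seq_len(max_retries)) {
      si <- cand[sample.int(length(cand), 1)]
      d <- dim(slides[[si]])
      if (d[1] < tile_size || d[2] < tile_size) next
      r0 <- sample.int(d[1] - tile_size + 1L, 1) - 1L
      c0 <- sample.int(d[2] - tile_size + 1L, 1) - 1L
      frac <- if (is.null(masks[[si]])) 0 else
        adipocyte_fraction(masks[[si]], c(r0, c0), tile_size)
      if (keep_tile(frac, rule)) {
        out[[b]] <- list(x = slides[[si]]$channels[(r0 + 1):(r0 + tile_size),
                                                   (c0 + 1):(c0 + tile_size), ,
                                                   drop = FALSE],
                         label = cl, slide_id = slides[[si]]$slide_id,
                         origin = c(r0, c0))
        break
      }
    }
    if (is.null(out[[b]]))
      stop("sampling exhausted: no retainable '", cl, "' tile found in ",
           max_retries, " attempts")
  }
  out
}

# degrade one raw integer tile according to an augmentation config
augment_tile <- function(tile_x, pixel_size_um, aug, seed) {
  s <- virtual_slide(tile_x, "aug", "aug", "normal", pixel_size_um,
                     "synthetic_clean")
  cfg <- aug
  cfg$seed <- seed
  degrade_slide(s, cfg)$channels
}

# stack tile samples into a (H, W, 4, N) float tensor in [0, 1]
stack_tiles <- function(tiles, aug = NULL, pixel_size_um = 1, aug_seed = 1L) {
  xs <- lapply(seq_along(tiles), function(i) {
    x <- tiles[[i]]$x
    if (!is.null(aug) && aug$mode != "none")
      x <- augment_tile(x, pixel_size_um, aug, derive_seed(aug_seed, "t", i))
    x
  })
  d <- dim(xs[[1]])
  xb <- array(0, c(d[1], d[2], 4L, length(xs)))
  for (i in seq_along(xs)) xb[, , , i] <- xs[[i]] / 255
  xb
}

# forward a float tensor through the classifier in inference mode
predict_logits <- function(model, xb) {
  fw <- nn_forward(model$net, xb, train = FALSE)
  as.numeric(fw$out)
}

#' Train the tile classifier
#'
#' Mini-batches are rejection-sampled from the training partition (guarded:
#' any slide whose subject is not assigned to `train` raises an error), the
#' loss is binary cross-entropy on the cancer logit, and optimisation is
#' Adam with the configured hyperparameters. Every `eval_every` iterations
#' the model is scored by tile AUC on a fixed validation tile set, and the
#' weights with the best validation AUC are kept (model selection on the
#' validation set).
#'
#' @param cohort an `mp_cohort` from [load_cohort()].
#' @param split a `cohort_split` from [split_cohort()].
#' @param config a [train_config()].
#' @param model optionally a pre-built [resnet20()]; defaults to a fresh one
#'   seeded from `config$seed`.
#' @param rule a [retention_rule()].
#' @return a trained `mphisto_model` with a training log (`$log`).
#' @export
train_classifier <- function(cohort, split, config = train_config(),
                             model = NULL, rule = retention_rule()) {
  stopifnot(inherits(cohort, "mp_cohort"), inherits(split, "cohort_split"),
            inherits(config, "train_config"))
  tr <- partition_slides(cohort, split, "train")
  va <- partition_slides(cohort, split, "val")
  if (is.null(model)) model <- resnet20(seed = config$seed)
  px <- cohort$manifest$pixel_size_um[1]

  # fixed validation tile set, sampled once
  n_val_batches <- max(1L, config$n_val_tiles %/% 4L)
  val_tiles <- unlist(lapply(seq_len(n_val_batches), function(i) {
    sample_batch(va$slides, va$masks, rule, config$tile_size_px,
                 seed = derive_seed(config$seed, "val", i), batch_size = 4L)
  }), recursive = FALSE)
  val_y <- as.numeric(vapply(val_tiles, function(t) t$label, character(1)) == "cancer")
  val_x <- stack_tiles(val_tiles, aug = config$augment, pixel_size_um = px,
                       aug_seed = derive_seed(config$seed, "valaug"))

  val_auc <- function(net) {
    m2 <- model; m2$net <- net
    probs <- numeric(length(val_tiles))
    idx <- split(seq_along(val_tiles),
                 ceiling(seq_along(val_tiles) / 16))
    for (ii in idx)
      probs[ii] <- sigmoid(predict_logits(m2, val_x[, , , ii, drop = FALSE]))
    roc_auc(probs, val_y)$auc
  }

  set.seed(config$seed)
  net <- model$net
  st <- adam_state(net)
  best <- list(auc = -Inf, net = net, iteration = 0L)
  log_rows <- list()
  last_loss <- NA_real_

  for (it in seq_len(config$max_iterations)) {
    tiles <- sample_batch(tr$slides, tr$masks, rule, config$tile_size_px,
                          seed = NULL, batch_size = config$batch_size)
    xb <- stack_tiles(tiles, aug = config$augment, pixel_size_um = px,
                      aug_seed = derive_seed(config$seed, "aug", it))
    y <- as.numeric(vapply(tiles, function(t) t$label, character(1)) == "cancer")
    fw <- nn_forward(net, xb, train = TRUE)
    l <- bce_with_logits(fw$out, matrix(y, nrow = 1))
    if (!is.finite(l$loss)) {
      warning("training diverged (non-finite loss) at iteration ", it,
              "; returning last stable checkpoint")
      break
    }
    last_loss <- l$loss
    pg <- nn_backward(net, fw, l$grad)
    r <- adam_step(fw$net, pg, st, it, lr = config$learning_rate,
                   beta1 = config$adam_beta1, beta2 = config$adam_beta2,
                   eps = config$adam_epsilon)
    net <- r$net; st <- r$state
    if (it %% config$eval_every == 0 || it == config$max_iterations) {
      auc <- val_auc(net)
      log_rows[[length(log_rows) + 1L]] <-
        tibble::tibble(iteration = it, loss = l$loss, val_auc = auc)
      if (auc > best$auc) best <- list(auc = auc, net = net, iteration = it)
      gc(verbose = FALSE) # keep the heap compact on long runs
    }
  }

  model$net <- best$net
  model$trained <- TRUE
  model$config <- config
  model$best_val_auc <- best$auc
  model$best_iteration <- best$iteration
  model$log <- if (length(log_rows)) dplyr::bind_rows(log_rows) else
    tibble::tibble(iteration = integer(), loss = numeric(), val_auc = numeric())
  model
}

#' Tile-level inference over a slide (the "heatmap")
#'
#' Probabilities are computed on a non-overlapping grid by default
#' (`stride = tile_size`); tiles failing the retention rule are flagged
#' `retained = FALSE` and carry no probability. Boundary tiles not fully
#' inside the slide are discarded.
#'
#' @param model a trained `mphisto_model`.
#' @param slide a [virtual_slide()].
#' @param mask optional `adipocyte_mask` (NULL means no adipocytes).
#' @param rule a [retention_rule()].
#' @param tile_size tile side in pixels.
#' @param stride grid stride (defaults to `tile_size`).
#' @return a `tile_prob_map`: `grid` tibble (`row`, `col`, `r0`, `c0`,
#'   `fraction`, `retained`, `prob`) plus grid geometry.
#' @export
predict_tiles <- function(model, slide, mask = NULL, rule = retention_rule(),
                          tile_size = 256L, stride = tile_size) {
  stopifnot(inherits(model, "mphisto_model"), inherits(slide, "virtual_slide"))
  d <- dim(slide)
  if (d[1] < tile_size || d[2] < tile_size)
    stop("slide (", d[1], "x", d[2], ") is smaller than the tile size")
  r0s <- seq(0L, d[1] - tile_size, by = stride)
  c0s <- seq(0L, d[2] - tile_size, by = stride)
  grid <- tidyr::expand_grid(row = seq_along(r0s), col = seq_along(c0s))
  grid$r0 <- r0s[grid$row]; grid$c0 <- c0s[grid$col]
  grid$fraction <- vapply(seq_len(nrow(grid)), function(k) {
    if (is.null(mask)) 0 else
      adipocyte_fraction(mask, c(grid$r0[k], grid$c0[k]), tile_size)
  }, numeric(1))
  grid$retained <- keep_tile(grid$fraction, rule)
  grid$prob <- NA_real_
  ret <- which(grid$retained)
  for (ii in split(ret, ceiling(seq_along(ret) / 16))) {
    xb <- array(0, c(tile_size, tile_size, 4L, length(ii)))
    for (j in seq_along(ii)) {
      k <- ii[j]
      xb[, , , j] <- slide$channels[(grid$r0[k] + 1):(grid$r0[k] + tile_size),
                                    (grid$c0[k] + 1):(grid$c0[k] + tile_size), ] / 255
    }
    grid$prob[ii] <- sigmoid(predict_logits(model, xb))
  }
  structure(list(slide_id = slide$slide_id, label = slide$label,
                 tile_size = as.integer(tile_size), stride = as.integer(stride),
                 dims = d, grid = grid), class = "tile_prob_map")
}

#' @export
print.tile_prob_map <- function(x, ...) {
  cat(sprintf("<tile_prob_map> %s: %d tiles (%d retained), tile %d px\n",
              x$slide_id, nrow(x$grid), sum(x$grid$retained), x$tile_size))
  invisible(x)
}
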