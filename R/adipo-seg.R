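# Pixel-level adipocyte segmentation and the tile-retention rule.
#
# Breast tissue is heavily adipose in both classes, so tiles dominated by
# lipid carry little diagnostic content. A U-Net-style encoder-decoder
# predicts a per-pixel lipid probability from the raw 4-channel image; tiles
# whose lipid fraction reaches 50% are excluded from training and evaluation
# (strict "< 50% of the area" retention).

#' Tile-retention rule
#'
#' A tile is retained iff its adipocyte area fraction is strictly below
#' `max_adipocyte_fraction`.
#'
#' @param max_adipocyte_fraction threshold in \[0, 1\], default 0.5.
#' @export
retention_rule <- function(max_adipocyte_fraction = 0.5) {
  stopifnot(max_adipocyte_fraction >= 0, max_adipocyte_fraction <= 1)
  structure(list(max_adipocyte_fraction = max_adipocyte_fraction),
            class = "retention_rule")
}

#' Adipocyte area fraction of a tile
#'
#' Mean of the binary mask over the half-open tile window starting at the
#' 0-based `tile_origin = c(row0, col0)`.
#'
#' @param mask an `adipocyte_mask` or 0/1 matrix.
#' @param tile_origin integer vector `c(row0, col0)`, 0-based.
#' @param tile_size tile side length in pixels.
#' @return fraction in \[0, 1\].
#' @export
adipocyte_fraction <- function(mask, tile_origin, tile_size) {
  m <- if (inherits(mask, "adipocyte_mask")) mask$mask else mask
  r0 <- tile_origin[1]; c0 <- tile_origin[2]
  if (r0 < 0 || c0 < 0 || r0 + tile_size > nrow(m) || c0 + tile_size > ncol(m))
    stop("tile [", r0, ",", c0, ") + ", tile_size, " is out of mask bounds ",
         nrow(m), "x", ncol(m))
  mean(m[(r0 + 1):(r0 + tile_size), (c0 + 1):(c0 + tile_size)])
}

#' Apply the retention rule to a tile's adipocyte fraction
#'
#' @param fraction adipocyte area fraction in \[0, 1\].
#' @param rule a [retention_rule()].
#' @return `TRUE` iff `fraction < rule$max_adipocyte_fraction` (strict).
#' @export
keep_tile <- function(fraction, rule = retention_rule()) {
  stopifnot(all(fraction >= 0), all(fraction <= 1))
  fraction < rule$max_adipocyte_fraction
}

#' Dice coefficient between two binary masks
#'
#' @param a,b 0/1 matrices (or `adipocyte_mask`es) of equal shape. Returns 1
#'   when both are empty.
#' @export
dice <- function(a, b) {
  ma <- if (inherits(a, "adipocyte_mask")) a$mask else a
  mb <- if (inherits(b, "adipocyte_mask")) b$mask else b
  stopifnot(all(dim(ma) == dim(mb)))
  s <- sum(ma == 1) + sum(mb == 1)
  if (s == 0) return(1)
  2 * sum(ma == 1 & mb == 1) / s
}

#' Segmenter training configuration
#'
#' @param base base filter count of the encoder-decoder.
#' @param patch_px training crop size.
#' @param batch_size crops per iteration.
#' @param iterations Adam steps.
#' @param learning_rate Adam learning rate.
#' @export
seg_spec <- function(base = 8L, patch_px = 64L, batch_size = 8L,
                     iterations = 400L, learning_rate = 1e-3) {
  structure(list(base = base, patch_px = patch_px, batch_size = batch_size,
                 iterations = iterations, learning_rate = learning_rate),
            class = "seg_spec")
}

#' Train the adipocyte segmenter
#'
#' Random crops are drawn from the training slides; half the crops are
#' centred on a lipid pixel so the positive class is represented despite its
#' low area fraction. Loss is per-pixel binary cross-entropy; optimisation
#' is Adam. Training is seed-reproducible.
#'
#' @param slides list of [virtual_slide()]s.
#' @param masks list of ground-truth `adipocyte_mask`es aligned to `slides`.
#' @param spec a [seg_spec()].
#' @param seed integer seed.
#' @return a trained `mphisto_segmenter`.
#' @export
train_segmenter <- function(slides, masks, spec = seg_spec(), seed = 1L) {
  if (length(slides) < 1L || length(masks) < 1L)
    stop("missing labels: need at least one slide with an aligned mask")
  stopifnot(length(slides) == length(masks))
  for (i in seq_along(slides))
    if (!all(dim(masks[[i]]$mask) == dim(slides[[i]])))
      stop("mask ", i, " is not aligned to its slide")

  model <- unet(base = spec$base, seed = seed)
  set.seed(seed + 1L)
  st <- adam_state(model$net)
  net <- model$net
  P <- spec$patch_px
  log_rows <- list()

  lipid_px <- lapply(masks, function(m) which(m$mask == 1L, arr.ind = TRUE))

  for (it in seq_len(spec$iterations)) {
    xb <- array(0, c(P, P, 4L, spec$batch_size))
    yb <- array(0, c(P, P, 1L, spec$batch_size))
    for (b in seq_len(spec$batch_size)) {
      si <- sample.int(length(slides), 1)
      d <- dim(slides[[si]])
      lp <- lipid_px[[si]]
      if (nrow(lp) > 0 && stats::runif(1) < 0.5) {
        ctr <- lp[sample.int(nrow(lp), 1), ]
        r0 <- min(max(ctr[1] - P %/% 2, 0), d[1] - P)
        c0 <- min(max(ctr[2] - P %/% 2, 0), d[2] - P)
      } else {
        r0 <- sample.int(d[1] - P + 1L, 1) - 1L
        c0 <- sample.int(d[2] - P + 1L, 1) - 1L
      }
      xb[, , , b] <- slides[[si]]$channels[(r0 + 1):(r0 + P),
                                           (c0 + 1):(c0 + P), ] / 255
      yb[, , 1, b] <- masks[[si]]$mask[(r0 + 1):(r0 + P), (c0 + 1):(c0 + P)]
    }
    fw <- nn_forward(net, xb, train = TRUE)
    l <- bce_with_logits(fw$out, yb)
    pg <- nn_backward(net, fw, l$grad)
    r <- adam_step(fw$net, pg, st, it, lr = spec$learning_rate)
    net <- r$net; st <- r$state
    if (it %% 50 == 0)
      log_rows[[length(log_rows) + 1L]] <-
        tibble::tibble(iteration = it, loss = l$loss)
  }
  model$net <- net
  model$trained <- TRUE
  model$spec <- spec
  model$log <- dplyr::bind_rows(log_rows)
  model
}

#' Predict an adipocyte mask for a slide
#'
#' Inference runs in overlapping blocks (block interior kept, margins
#' discarded) so arbitrarily large slides fit in memory; per-pixel sigmoid
#' probabilities are thresholded into a binary mask.
#'
#' @param segmenter a trained `mphisto_segmenter`.
#' @param slide a [virtual_slide()].
#' @param threshold probability cut (default 0.5); `probability >= threshold`
#'   maps to lipid.
#' @param block_px interior block size (multiple of 4).
#' @param margin_px context margin around each block.
#' @return an `adipocyte_mask`.
#' @export
segment <- function(segmenter, slide, threshold = 0.5,
                    block_px = 256L, margin_px = 32L) {
  stopifnot(inherits(segmenter, "mphisto_segmenter"),
            inherits(slide, "virtual_slide"))
  d <- dim(slide)
  prob <- matrix(0, d[1], d[2])
  rs <- seq(1L, d[1], by = block_px)
  cs <- seq(1L, d[2], by = block_px)
  for (r0 in rs) for (c0 in cs) {
    r1 <- min(r0 + block_px - 1L, d[1]); c1 <- min(c0 + block_px - 1L, d[2])
    # clamp-padded context window, side a multiple of 4
    wr <- pmin(pmax((r0 - margin_px):(r1 + margin_px), 1L), d[1])
    wc <- pmin(pmax((c0 - margin_px):(c1 + margin_px), 1L), d[2])
    wr <- wr[seq_len(length(wr) %/% 4 * 4)]
    wc <- wc[seq_len(length(wc) %/% 4 * 4)]
    x <- array(slide$channels[wr, wc, ] / 255, c(length(wr), length(wc), 4L, 1L))
    fw <- nn_forward(segmenter$net, x, train = FALSE)
    p <- sigmoid(fw$out[, , 1, 1])
    ir <- (r0:r1) - (r0 - margin_px) + 1L
    ic <- (c0:c1) - (c0 - margin_px) + 1L
    ir <- ir[ir <= nrow(p)]; ic <- ic[ic <= ncol(p)]
    prob[r0:(r0 + length(ir) - 1L), c0:(c0 + length(ic) - 1L)] <- p[ir, ic]
  }
  adipocyte_mask(prob >= threshold, slide$slide_id)
}
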