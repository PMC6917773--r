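# Model interpretability: penultimate-feature extraction, t-SNE canvas and
# class activation mapping (CAM).
#
# The classifier's head is a 1x1 convolutional projection to 512 maps,
# global average pooling and a single linear cancer neuron, so (a) the
# 512-d pooled vector is the compact representation fed to the final
# decision, and (b) classic CAM applies exactly: the spatial class-evidence
# map is the linear combination of the 512 final maps under the output
# weights.

#' Sample a labelled tile set from a slide collection
#'
#' Convenience wrapper around [sample_batch()] that accumulates `n` retained
#' tiles (class-balanced) for feature extraction and embedding.
#'
#' @param slides named list of [virtual_slide()]s.
#' @param masks aligned list of masks (or NULLs).
#' @param n number of tiles.
#' @param tile_size tile side in pixels.
#' @param rule a [retention_rule()].
#' @param seed integer seed.
#' @return list of tile samples (see [sample_batch()]).
#' @export
sample_tiles <- function(slides, masks = NULL, n = 64L, tile_size = 256L,
                         rule = retention_rule(), seed = 1L) {
  if (is.null(masks)) masks <- vector("list", length(slides))
  nb <- ceiling(n / 4)
  tiles <- unlist(lapply(seq_len(nb), function(i)
    sample_batch(slides, masks, rule, tile_size,
                 seed = derive_seed(seed, "tileset", i), batch_size = 4L)),
    recursive = FALSE)
  tiles[seq_len(n)]
}

#' Extract 512-d penultimate features for tiles
#'
#' Deterministic inference-mode forward pass; one row per tile.
#'
#' @param model a trained `mphisto_model`.
#' @param tiles list of tile samples, or a `(H, W, 4, N)` array already
#'   scaled to \[0, 1\].
#' @return numeric matrix `n x 512`.
#' @export
extract_features <- function(model, tiles) {
  stopifnot(inherits(model, "mphisto_model"))
  xb <- if (is.array(tiles)) tiles else stack_tiles(tiles)
  n <- dim(xb)[4]
  feats <- matrix(0, n, 512L)
  for (ii in split(seq_len(n), ceiling(seq_len(n) / 16))) {
    fw <- nn_forward(model$net, xb[, , , ii, drop = FALSE], train = FALSE,
                     keep = model$feat_node)
    f <- fw$acts[[model$feat_node]] # 512 x batch
    if (nrow(f) != 512L) stop("penultimate feature width is not 512")
    feats[ii, ] <- t(f)
  }
  feats
}

# ---- t-SNE (exact, O(n^2)) --------------------------------------------------

# conditional p_{j|i} with per-point precision tuned to the target perplexity
.tsne_p <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf
    beta <- 1 / (mean(di) + .Machine$double.eps) # scale-aware start
    for (iter in 1:64) {
      w <- exp(-di * beta)
      sw <- sum(w)
      H <- if (sw > 0) log(sw) + beta * sum(di * w) / sw else -Inf
      if (is.finite(H) && abs(H - target) < tol) break
      if (H > target) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else { # entropy too low (or all weights underflowed): soften
        hi <- beta
        beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2
      }
    }
    if (sum(w) == 0) w[] <- 1 # pathological row: fall back to uniform
    P[i, -i] <- w / sum(w)
  }
  P
}

#' Embed features in 2-d with t-SNE
#'
#' Exact t-SNE on Euclidean distances with the standard recipe: PCA
#' pre-reduction to 50 components, early exaggeration, momentum gradient
#' descent with adaptive gains. Deterministic given `seed`.
#'
#' @param features numeric matrix (tiles x dims).
#' @param perplexity target perplexity (default 30); requires
#'   `nrow(features) >= 3 * perplexity`.
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @return matrix `n x 2` of embedding coordinates.
#' @export
tsne_embed <- function(features, perplexity = 30, seed = 1L, max_iter = 500L) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 3 * perplexity)
    stop("too few tiles (", n, ") for perplexity ", perplexity,
         "; reduce the perplexity to at most ", floor(n / 3))
  set.seed(seed)
  X <- scale(X, center = TRUE, scale = FALSE)
  if (ncol(X) > 50) X <- stats::prcomp(X, rank. = 50)$x
  D2 <- as.matrix(stats::dist(X))^2
  P <- .tsne_p(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- gains <- matrix(0, n, 2); gains[] <- 1
  exag <- 4; lr <- 100
  Pe <- P * exag
  for (it in seq_len(max_iter)) {
    if (it == 101L) Pe <- P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * Y %*% t(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it < 250) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- mom * dY - lr * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' t-SNE canvas of tiles in feature space
#'
#' Embeds the tiles' penultimate features in 2-d and builds a canvas where a
#' random subset of points is replaced by its rendered composite thumbnail.
#'
#' @param features `n x 512` feature matrix (see [extract_features()]).
#' @param tiles the tile samples the rows correspond to.
#' @param perplexity,seed,max_iter passed to [tsne_embed()].
#' @param n_thumbs how many tiles to render onto the canvas.
#' @param thumb_px thumbnail side in canvas pixels.
#' @param colormap channel colormap for the thumbnails.
#' @return list with `embedding` (tibble `tile`, `x`, `y`, `label`) and
#'   `plot` (a ggplot canvas).
#' @export
tsne_canvas <- function(features, tiles, perplexity = 30, seed = 1L,
                        max_iter = 500L, n_thumbs = 40L, thumb_px = 64L,
                        colormap = default_colormap()) {
  Y <- tsne_embed(features, perplexity, seed, max_iter)
  labels <- vapply(tiles, function(t) t$label, character(1))
  emb <- tibble::tibble(tile = seq_len(nrow(Y)), x = Y[, 1], y = Y[, 2],
                        label = labels)
  set.seed(derive_seed(seed, "thumbs"))
  shown <- sample(nrow(emb), min(n_thumbs, nrow(emb)))
  half <- diff(range(emb$x)) * 0.035
  p <- ggplot2::ggplot(emb, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = NULL) +
    ggplot2::theme_minimal()
  for (i in shown) {
    thumb <- tile_thumbnail(tiles[[i]]$x, thumb_px, colormap)
    p <- p + ggplot2::annotation_raster(thumb,
                                        xmin = emb$x[i] - half, xmax = emb$x[i] + half,
                                        ymin = emb$y[i] - half, ymax = emb$y[i] + half)
  }
  list(embedding = emb, plot = p)
}

# render a raw integer tile to a small RGB raster
tile_thumbnail <- function(x, thumb_px, colormap = default_colormap()) {
  idx_r <- round(seq(1, dim(x)[1], length.out = thumb_px))
  idx_c <- round(seq(1, dim(x)[2], length.out = thumb_px))
  small <- x[idx_r, idx_c, , drop = FALSE]
  rgb <- array(0, c(thumb_px, thumb_px, 3))
  for (ci in 1:4) for (pl in 1:3)
    rgb[, , pl] <- rgb[, , pl] + colormap[ci, pl] * small[, , ci]
  pmin(rgb, 255) / 255
}

# ---- class activation mapping ----------------------------------------------

bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  interp_mat <- function(n_out, n_in) {
    pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pos <- pmin(pmax(pos, 1), n_in)
    lo <- pmin(floor(pos), n_in - ifelse(n_in > 1, 1, 0))
    f <- pos - lo
    A <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      A[i, lo[i]] <- 1 - f[i]
      if (lo[i] < n_in) A[i, lo[i] + 1] <- A[i, lo[i] + 1] + f[i]
    }
    A
  }
  interp_mat(H, h) %*% m %*% t(interp_mat(W, w))
}

#' Class activation map for one tile
#'
#' The cancer-evidence map is the sum of the 512 final convolutional feature
#' maps weighted by the output neuron's weights, bilinearly upsampled to the
#' tile resolution and min-max normalised to \[0, 1\] (a constant map stays
#' flat at 0).
#'
#' @param model a trained `mphisto_model` with a GAP + linear head.
#' @param tile a tile sample (from [sample_batch()]) or a raw
#'   `(H, W, 4)` integer tile array.
#' @return an `activation_map`: list with `map` (H x W matrix in \[0, 1\])
#'   and the tile's provenance.
#' @export
cam <- function(model, tile) {
  stopifnot(inherits(model, "mphisto_model"))
  if (is.null(model$cam_node))
    stop("model architecture does not expose a GAP + linear head; CAM undefined")
  x <- if (is.list(tile)) tile$x else tile
  d <- dim(x)
  xb <- array(x / 255, c(d[1], d[2], 4L, 1L))
  fw <- nn_forward(model$net, xb, train = FALSE, keep = model$cam_node)
  maps <- fw$acts[[model$cam_node]] # (h, w, 512, 1)
  md <- dim(maps)
  wts <- as.numeric(model$net$nodes[[model$logit_node]]$w)
  flat <- matrix(maps[, , , 1], md[1] * md[2], md[3])
  m <- matrix(flat %*% wts, md[1], md[2])
  up <- bilinear_upsample(m, d[1], d[2])
  rng <- range(up)
  map <- if (rng[2] > rng[1]) (up - rng[1]) / (rng[2] - rng[1]) else up * 0
  structure(list(map = map,
                 slide_id = if (is.list(tile)) tile$slide_id else NA_character_,
                 origin = if (is.list(tile)) tile$origin else c(0L, 0L)),
            class = "activation_map")
}

#' CAM localisation benchmark against simulator ground truth
#'
#' Samples cancer tiles that contain at least one planted
#' cancer-discriminative object (tumor-cell or vesicle cluster), computes
#' each tile's CAM, and scores a hit when the map's peak falls inside any
#' such object's bounding box dilated by `dilate_px`.
#'
#' @param model a trained `mphisto_model`.
#' @param cohort an `mp_cohort` with ground truth loaded.
#' @param slide_ids slides to draw from (default: all cancer slides).
#' @param n_tiles number of test tiles.
#' @param tile_size tile side in pixels.
#' @param dilate_px bounding-box dilation.
#' @param seed integer seed.
#' @return list with `rate` (fraction of hits) and `details` tibble.
#' @export
cam_localization_rate <- function(model, cohort, slide_ids = NULL,
                                  n_tiles = 30L, tile_size = 256L,
                                  dilate_px = 16L, seed = 1L) {
  man <- cohort$manifest
  if (is.null(slide_ids)) slide_ids <- man$slide_id[man$label == "cancer"]
  set.seed(seed)
  rows <- list()
  guard <- 0L
  while (length(rows) < n_tiles && guard < n_tiles * 200L) {
    guard <- guard + 1L
    sid <- sample(slide_ids, 1)
    slide <- cohort$slides[[sid]]
    gt <- cohort$ground_truth[[sid]]
    if (is.null(gt)) stop("cohort has no ground truth for slide ", sid)
    d <- dim(slide)
    r0 <- sample.int(d[1] - tile_size + 1L, 1) - 1L
    c0 <- sample.int(d[2] - tile_size + 1L, 1) - 1L
    mask <- cohort$masks[[sid]]
    frac <- if (is.null(mask)) 0 else adipocyte_fraction(mask, c(r0, c0), tile_size)
    if (!keep_tile(frac, retention_rule())) next
    obj <- gt[gt$type %in% CANCER_OBJECTS &
              gt$row > r0 & gt$row <= r0 + tile_size &
              gt$col > c0 & gt$col <= c0 + tile_size, , drop = FALSE]
    if (!nrow(obj)) next
    tile <- list(x = slide$channels[(r0 + 1):(r0 + tile_size),
                                    (c0 + 1):(c0 + tile_size), , drop = FALSE],
                 label = "cancer", slide_id = sid, origin = c(r0, c0))
    am <- cam(model, tile)
    peak <- which(am$map == max(am$map), arr.ind = TRUE)[1, ]
    pr <- peak[1] + r0; pc <- peak[2] + c0
    hit <- any(pr >= obj$bbox_rmin - dilate_px & pr <= obj$bbox_rmax + dilate_px &
               pc >= obj$bbox_cmin - dilate_px & pc <= obj$bbox_cmax + dilate_px)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      slide_id = sid, r0 = r0, c0 = c0, peak_row = pr, peak_col = pc,
      n_objects = nrow(obj), hit = hit)
  }
  details <- dplyr::bind_rows(rows)
  list(rate = mean(details$hit), details = details)
}
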