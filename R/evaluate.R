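# Slide-level aggregation, ROC/AUC statistics and the domain-adaptation
# ablation harness.

#' Slide-level cancer score
#'
#' Arithmetic mean of the probabilities of all retained tiles in the slide's
#' heatmap (excluded tiles are ignored).
#'
#' @param map a `tile_prob_map` from [predict_tiles()].
#' @return a scalar in \[0, 1\].
#' @export
slide_score <- function(map) {
  stopifnot(inherits(map, "tile_prob_map"))
  p <- map$grid$prob[map$grid$retained]
  if (!length(p))
    stop("slide ", map$slide_id,
         " has zero retained tiles; slide score is undefined")
  mean(p)
}

#' Slide scores for a list of heatmaps
#'
#' @param maps list of `tile_prob_map`s.
#' @return tibble `slide_id`, `label`, `n_retained`, `score` (`NA` for
#'   unevaluable slides with zero retained tiles, which are flagged in
#'   `evaluable`).
#' @export
slide_scores <- function(maps) {
  dplyr::bind_rows(lapply(maps, function(m) {
    n_ret <- sum(m$grid$retained)
    tibble::tibble(slide_id = m$slide_id, label = m$label,
                   n_retained = n_ret,
                   score = if (n_ret) mean(m$grid$prob[m$grid$retained]) else NA_real_,
                   evaluable = n_ret > 0)
  }))
}

#' Tile-level predictions across heatmaps as one tidy table
#'
#' @param maps list of `tile_prob_map`s.
#' @return tibble `slide_id`, `label`, `row`, `col`, `prob`, `retained`.
#' @export
tile_predictions <- function(maps) {
  dplyr::bind_rows(lapply(maps, function(m)
    dplyr::mutate(m$grid, slide_id = m$slide_id, label = m$label,
                  .before = 1)))
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney U statistic normalised by
#' `n_pos * n_neg`, with ties counted one half — equivalently the
#' trapezoidal area under the (FPR, TPR) curve swept over all score
#' thresholds.
#'
#' @param scores numeric scores (higher = more cancer-like).
#' @param labels class labels: `"cancer"`/`"normal"`, logical, or 0/1
#'   (1 = cancer = positive).
#' @param level `"tile"` or `"slide"` (annotation only).
#' @return a `roc_result`: list with `curve` tibble (`threshold`, `tpr`,
#'   `fpr`), `auc`, `level`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, level = c("tile", "slide")) {
  level <- match.arg(level)
  y <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "cancer" else as.logical(labels)
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    stop("degenerate labels: both classes must be present to compute a ROC")
  # Mann-Whitney via midranks (ties get half credit)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!y] >= t), numeric(1))
  structure(list(curve = tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr),
                 auc = auc, level = level, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s-level AUC = %.4f (%d pos, %d neg)\n",
              x$level, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Evaluate a model on a set of slides at tile and slide level
#'
#' @param model a trained `mphisto_model`.
#' @param slides named list of [virtual_slide()]s.
#' @param masks aligned list of masks (or NULL entries).
#' @param rule a [retention_rule()].
#' @param tile_size tile side in pixels.
#' @return list with `maps`, `tile_roc`, `slide_roc`, `slide_table`.
#' @export
evaluate_model <- function(model, slides, masks = NULL,
                           rule = retention_rule(), tile_size = 256L) {
  if (is.null(masks)) masks <- vector("list", length(slides))
  maps <- lapply(seq_along(slides), function(i)
    predict_tiles(model, slides[[i]], masks[[i]], rule, tile_size))
  tp <- tile_predictions(maps)
  tp <- tp[tp$retained, ]
  ss <- slide_scores(maps)
  list(maps = maps,
       tile_roc = roc_auc(tp$prob, tp$label, level = "tile"),
       slide_roc = roc_auc(ss$score[ss$evaluable], ss$label[ss$evaluable],
                           level = "slide"),
       slide_table = ss)
}

#' Domain-adaptation ablation experiment
#'
#' Reproduces the augmentation ablation: one classifier is trained per
#' augmentation mode on identically split clean-domain data (the mode's
#' degradation applied to each training tile), and all models are evaluated
#' on the same artificially degraded test slides (always degraded with
#' `mode = "full"`), at tile and slide level.
#'
#' @param cohort a clean-domain `mp_cohort`.
#' @param split a `cohort_split`; test subjects are held out and degraded.
#' @param degrade_config a [degradation_config()] defining the degraded
#'   domain.
#' @param config a [train_config()]; its `tile_size_px` is the clean-domain
#'   crop size, so arms with downsampling see
#'   `tile_size_px / downsample_factor` px inputs.
#' @param modes augmentation arms to run.
#' @param seed integer seed (training and degradation streams derive from it).
#' @return an `ablation_report`: tibble `mode`, `tile_auc`, `slide_auc`,
#'   `seed`, with the per-mode evaluation objects in
#'   `attr(, "evaluations")`.
#' @export
run_ablation <- function(cohort, split, degrade_config = degradation_config(),
                         config = train_config(),
                         modes = c("none", "downsample_only", "full"),
                         seed = 1L) {
  stopifnot(inherits(cohort, "mp_cohort"))
  te <- partition_slides(cohort, split, "test")
  # degraded test domain: always the full physics model
  test_cfg <- degrade_config
  test_cfg$mode <- "full"
  test_cfg$seed <- derive_seed(seed, "testdomain")
  f <- degrade_config$downsample_factor
  test_slides <- lapply(te$slides, degrade_slide, config = test_cfg)
  test_masks <- lapply(te$masks, function(m) {
    if (is.null(m)) return(NULL)
    downsample_mask(m, f)
  })
  test_tile <- config$tile_size_px %/% f

  rows <- list(); evals <- list()
  for (mode in modes) {
    cfg <- config
    cfg$seed <- derive_seed(seed, "train", mode)
    aug <- degrade_config
    aug$mode <- mode
    aug$seed <- derive_seed(seed, "aug", mode)
    cfg$augment <- if (mode == "none") NULL else aug
    fit <- train_classifier(cohort, split, cfg)
    ev <- evaluate_model(fit, test_slides, test_masks,
                         tile_size = test_tile)
    evals[[mode]] <- ev
    rows[[mode]] <- tibble::tibble(mode = mode,
                                   tile_auc = ev$tile_roc$auc,
                                   slide_auc = ev$slide_roc$auc,
                                   seed = seed)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ablation_report", class(out))
  attr(out, "evaluations") <- evals
  out
}

#' Downsample a binary mask by block-mean thresholding
#'
#' A low-resolution pixel is lipid iff at least half of its source block is.
#' @param mask an `adipocyte_mask`.
#' @param factor integer block size.
#' @export
downsample_mask <- function(mask, factor) {
  m <- mask$mask
  h <- nrow(m) %/% factor * factor; w <- ncol(m) %/% factor * factor
  m <- m[seq_len(h), seq_len(w)]
  m <- matrix(colMeans(matrix(m, nrow = factor)), nrow = h %/% factor)
  m <- t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = w %/% factor))
  adipocyte_mask(m >= 0.5, mask$slide_id)
}
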