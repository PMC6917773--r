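# broom-style tidiers for fitted objects and results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained classifier's training log
#'
#' @param x a `mphisto_model`.
#' @param ... unused.
#' @return tibble with `iteration`, `loss`, `val_auc`.
#' @method tidy mphisto_model
#' @export
tidy.mphisto_model <- function(x, ...) {
  if (is.null(x$log)) tibble::tibble(iteration = integer(), loss = numeric(),
                                     val_auc = numeric())
  else tibble::as_tibble(x$log)
}

#' One-row summary of a trained classifier
#'
#' @param x a `mphisto_model`.
#' @param ... unused.
#' @method glance mphisto_model
#' @export
glance.mphisto_model <- function(x, ...) {
  tibble::tibble(arch = x$arch, trained = x$trained,
                 best_val_auc = x$best_val_auc %||% NA_real_,
                 best_iteration = x$best_iteration %||% NA_integer_,
                 n_nodes = length(x$net$nodes))
}

#' @method tidy mphisto_segmenter
#' @export
tidy.mphisto_segmenter <- function(x, ...) {
  if (is.null(x$log)) tibble::tibble(iteration = integer(), loss = numeric())
  else tibble::as_tibble(x$log)
}

#' @method glance mphisto_segmenter
#' @export
glance.mphisto_segmenter <- function(x, ...) {
  tibble::tibble(depth = x$depth, base = x$base, trained = x$trained)
}

#' Tidy a ROC result into its curve
#'
#' @param x a `roc_result`.
#' @param ... unused.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, level = x$level, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @method tidy tile_prob_map
#' @export
tidy.tile_prob_map <- function(x, ...) {
  dplyr::mutate(x$grid, slide_id = x$slide_id, .before = 1)
}

#' @method tidy ablation_report
#' @export
tidy.ablation_report <- function(x, ...) tibble::as_tibble(x)
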