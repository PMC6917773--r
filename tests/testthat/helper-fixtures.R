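# Shared fixtures, built lazily and cached for the whole test run.
# Heavy objects (cohorts, trained models) are constructed once on first use
# so every test file sees identical, reproducible inputs.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# small clean cohort used across module tests: 6 + 6 subjects, 2 slides each,
# 512 px at 1 um/px
fx_cohort <- function() fx_get("cohort", function() {
  man <- generate_cohort(6, 6, 2, size_px = 512L,
                         out_dir = file.path(tempdir(), "fx_cohort"),
                         seed = 11L)
  load_cohort(man)
})

fx_split <- function() fx_get("split", function() {
  split_cohort(fx_cohort()$manifest, seed = 2L)
})

# classifier trained briefly on the small cohort (128-px tiles); good enough
# for interpretability and evaluation plumbing
fx_classifier <- function() fx_get("classifier", function() {
  cfg <- train_config(tile_size_px = 128L, max_iterations = 150L,
                      eval_every = 25L, n_val_tiles = 32L, seed = 5L)
  train_classifier(fx_cohort(), fx_split(), cfg)
})

# adipocyte segmenter trained on synthetic slides with ground-truth masks;
# held-out slides for Dice evaluation come from fx_seg_holdout()
fx_segmenter <- function() fx_get("segmenter", function() {
  gen <- fx_seg_slides()
  train_segmenter(gen$slides[1:4], gen$masks[1:4], seg_spec(iterations = 400L),
                  seed = 3L)
})

fx_seg_slides <- function() fx_get("seg_slides", function() {
  ph <- tissue_phenotype("normal")
  gen <- lapply(1:6, function(i)
    generate_slide(ph, size_px = 512L, seed = 100L + i,
                   slide_id = paste0("seg", i)))
  list(slides = lapply(gen, `[[`, "slide"),
       masks = lapply(gen, function(g) g$ground_truth$mask))
})

# quick ad-hoc slides
const_slide <- function(value = 0L, size = 64L, px = 1) {
  virtual_slide(array(as.integer(value), c(size, size, 4L)),
                "subj", "slide", "normal", px)
}

rand_slide <- function(size = 64L, seed = 1L, px = 1, label = "normal") {
  set.seed(seed)
  virtual_slide(array(sample(0:255, size * size * 4L, replace = TRUE),
                      c(size, size, 4L)),
                "subj", paste0("rand", seed), label, px)
}

# brute-force AUC oracle: pairwise comparison with half credit for ties
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
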