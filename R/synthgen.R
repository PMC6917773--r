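# Synthetic-cohort simulator.
#
# Stands in for the non-deposited clinical data: four colocalised
# intrinsic-contrast channels, cancer-discriminative objects (tumor-cell
# clusters in NADH/FAD, THG vesicle clusters) over a shared background
# (SHG collagen fibers, NADH+FAD elastin fibers, adipocytes) plus
# normal-enriched confusers (duct/vessel rings), multi-slide-per-subject
# cohort structure with a per-subject random effect, and exact ground-truth
# geometry for testing segmentation and activation-map localisation.

CANCER_OBJECTS <- c("tumor_cell_cluster", "vesicle_cluster")

#' Tissue phenotype parameters
#'
#' Densities are objects per mm^2; intensities 8-bit. The defaults encode the
#' contrast structure a classifier can exploit: tumor-cell clusters and
#' vesicle clusters are cancer-enriched, duct/vessel rings normal-enriched,
#' fibers and adipocytes shared. No quantitative densities are available for
#' real breast tissue in these contrasts, so these are simulator conventions
#' chosen once (see the methods vignette).
#'
#' @param class `"cancer"` or `"normal"`.
#' @param noise_sigma background Gaussian noise sd (8-bit units).
#' @param subject_sd sd of the per-subject log-normal density multiplier.
#' @return an object of class `tissue_phenotype`.
#' @export
tissue_phenotype <- function(class = c("cancer", "normal"),
                             noise_sigma = 5, subject_sd = 0.15) {
  class <- match.arg(class)
  dens <- if (class == "cancer") {
    c(tumor_cell_cluster = 45, vesicle_cluster = 60, collagen_fiber = 30,
      elastin_fiber = 10, duct_vessel = 1, adipocyte = 6)
  } else {
    c(tumor_cell_cluster = 0, vesicle_cluster = 6, collagen_fiber = 30,
      elastin_fiber = 10, duct_vessel = 15, adipocyte = 6)
  }
  objects <- tibble::tibble(
    object = names(dens),
    density = unname(dens),
    int_min = c(120, 150, 80, 60, 120, 150),
    int_max = c(220, 255, 200, 150, 220, 240))
  stopifnot(all(objects$density >= 0),
            all(objects$int_min >= 0), all(objects$int_max <= 255))
  structure(list(class = class, objects = objects,
                 noise_sigma = noise_sigma, subject_sd = subject_sd),
            class = "tissue_phenotype")
}

#' @rdname tissue_phenotype
#' @export
phenotype_pair <- function(noise_sigma = 5, subject_sd = 0.15) {
  list(cancer = tissue_phenotype("cancer", noise_sigma, subject_sd),
       normal = tissue_phenotype("normal", noise_sigma, subject_sd))
}

#' @rdname tissue_phenotype
#' @description `null_phenotype_pair()` gives both classes the normal-tissue
#'   parameters, a null condition under which a classifier's AUC must be
#'   indistinguishable from 0.5.
#' @export
null_phenotype_pair <- function(noise_sigma = 5, subject_sd = 0.15) {
  p <- tissue_phenotype("normal", noise_sigma, subject_sd)
  cn <- p; cn$class <- "cancer"
  list(cancer = cn, normal = p)
}

#' Derive a stable child seed from a master seed and identifiers
#'
#' Polynomial string hash folded into the master seed, modulo 2^31 - 1, so
#' subject and slide streams are reproducible and decoupled.
#' @param master integer master seed.
#' @param ... character/numeric identifiers.
#' @return an integer in 1..(2^31 - 2).
#' @export
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (tok in unlist(lapply(list(...), as.character))) {
    for (code in utf8ToInt(tok)) h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h) + 1L
}

# ---- rasterisation helpers --------------------------------------------------

# add `patch` (times scale) onto `plane` in place at 1-based centres;
# `plane` must be exclusively owned by the caller (C++ mutates it directly)
stamp_add <- function(plane, r, c, patch, scale = 1) {
  cpp_stamp_add_many(plane, as.integer(round(r)), as.integer(round(c)),
                     patch, as.numeric(scale))
  invisible(plane)
}

gauss_patch <- function(sigma, amp) {
  rad <- max(1L, ceiling(3 * sigma))
  d <- (-rad):rad
  g <- exp(-d^2 / (2 * sigma^2))
  amp * outer(g, g)
}

disk_patch <- function(radius, amp) {
  rad <- ceiling(radius)
  d <- (-rad):rad
  dist <- sqrt(outer(d^2, d^2, "+"))
  amp * (dist <= radius)
}

annulus_patch <- function(radius, thickness, amp) {
  rad <- ceiling(radius + thickness)
  d <- (-rad):rad
  dist <- sqrt(outer(d^2, d^2, "+"))
  amp * exp(-((dist - radius)^2) / (2 * (thickness / 2)^2))
}

# smoothed random-walk polyline: matrix of (row, col) positions
fiber_path <- function(r0, c0, n_steps, step = 1.5, turn_sd = 0.25) {
  theta <- stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(n_steps, 0, turn_sd))
  rr <- r0 + cumsum(step * sin(theta))
  cc <- c0 + cumsum(step * cos(theta))
  cbind(round(rr), round(cc))
}

# ---- slide generation -------------------------------------------------------

#' Generate one synthetic virtual slide with ground truth
#'
#' Object counts are Poisson with density x area x `subject_effect`; objects
#' are rasterised additively into their designated channels, Gaussian
#' background noise is added, and the result is clipped and quantised to
#' 8 bits. The returned ground truth records every placed object (type,
#' centre, bounding box) and the exact rasterised adipocyte mask.
#'
#' @param phenotype a [tissue_phenotype()].
#' @param subject_effect multiplicative density effect (drawn once per
#'   subject by [generate_cohort()]).
#' @param size_px slide side length in pixels.
#' @param pixel_size_um pixel size (micrometres).
#' @param seed integer seed; same seed and parameters give a bit-identical
#'   slide.
#' @param subject_id,slide_id identity to stamp on the slide.
#' @return list with elements `slide` ([virtual_slide()]) and `ground_truth`
#'   (list of `objects` tibble and `mask`, an [adipocyte_mask()]).
#' @export
generate_slide <- function(phenotype, subject_effect = 1, size_px = 1024L,
                           pixel_size_um = 1, seed = 1L,
                           subject_id = "S1", slide_id = "S1_1") {
  stopifnot(inherits(phenotype, "tissue_phenotype"))
  set.seed(seed)
  area_mm2 <- (size_px * pixel_size_um / 1000)^2
  obj <- phenotype$objects
  expected_total <- sum(obj$density) * area_mm2 * subject_effect
  if (expected_total > size_px^2 / 10)
    stop("degenerate parameters: expected object count (", round(expected_total),
         ") exceeds pixels/10")

  # separate planes so the C++ rasteriser can accumulate in place
  thg <- matrix(0, size_px, size_px); nadh <- matrix(0, size_px, size_px)
  shg <- matrix(0, size_px, size_px); fad <- matrix(0, size_px, size_px)
  adipo <- matrix(0, size_px, size_px)
  gt <- list()

  add_gt <- function(type, r, c, rad) {
    tibble::tibble(type = type, row = r, col = c,
                   bbox_rmin = max(1, r - rad), bbox_rmax = min(size_px, r + rad),
                   bbox_cmin = max(1, c - rad), bbox_cmax = min(size_px, c + rad))
  }

  for (k in seq_len(nrow(obj))) {
    n <- stats::rpois(1, obj$density[k] * area_mm2 * subject_effect)
    if (n == 0) next
    for (i in seq_len(n)) {
      r <- sample.int(size_px, 1); c <- sample.int(size_px, 1)
      amp <- stats::runif(1, obj$int_min[k], obj$int_max[k])
      type <- obj$object[k]
      if (type == "tumor_cell_cluster") {
        ncell <- sample(6:12, 1); spread <- 20
        for (j in seq_len(ncell)) {
          rr <- r + round(stats::rnorm(1, 0, spread / 2))
          cc <- c + round(stats::rnorm(1, 0, spread / 2))
          p <- gauss_patch(stats::runif(1, 2, 4), amp * stats::runif(1, 0.7, 1))
          stamp_add(nadh, rr, cc, p)
          stamp_add(fad, rr, cc, p, scale = 0.8)
        }
        gt[[length(gt) + 1L]] <- add_gt(type, r, c, spread + 10)
      } else if (type == "vesicle_cluster") {
        npunct <- sample(4:10, 1); spread <- 12
        for (j in seq_len(npunct)) {
          rr <- r + round(stats::rnorm(1, 0, spread / 2))
          cc <- c + round(stats::rnorm(1, 0, spread / 2))
          p <- disk_patch(stats::runif(1, 1, 3), amp * stats::runif(1, 0.7, 1))
          stamp_add(thg, rr, cc, p)
        }
        gt[[length(gt) + 1L]] <- add_gt(type, r, c, spread + 6)
      } else if (type == "collagen_fiber") {
        path <- fiber_path(r, c, sample(60:200, 1))
        stamp_add(shg, path[, 1], path[, 2], gauss_patch(1.5, amp * 0.25))
        rad <- max(abs(path[, 1] - r), abs(path[, 2] - c)) + 5
        gt[[length(gt) + 1L]] <- add_gt(type, r, c, rad)
      } else if (type == "elastin_fiber") {
        path <- fiber_path(r, c, sample(40:120, 1), turn_sd = 0.15)
        p <- gauss_patch(1.2, amp * 0.25)
        stamp_add(nadh, path[, 1], path[, 2], p)
        stamp_add(fad, path[, 1], path[, 2], p)
        rad <- max(abs(path[, 1] - r), abs(path[, 2] - c)) + 5
        gt[[length(gt) + 1L]] <- add_gt(type, r, c, rad)
      } else if (type == "duct_vessel") {
        rad <- stats::runif(1, 15, 40); th <- stats::runif(1, 3, 6)
        p <- annulus_patch(rad, th, amp)
        stamp_add(nadh, r, c, p)
        stamp_add(fad, r, c, p, scale = 0.7)
        gt[[length(gt) + 1L]] <- add_gt(type, r, c, ceiling(rad + th))
      } else if (type == "adipocyte") {
        rad_um <- stats::runif(1, 15, 60)
        rad <- rad_um / pixel_size_um
        rim <- annulus_patch(rad, 2.5, amp)
        half <- (nrow(rim) - 1L) %/% 2L
        dd <- (-half):half
        interior <- (sqrt(outer(dd^2, dd^2, "+")) <= rad) * 1
        # speckled THG texture inside the lipid body plus a thin bright rim
        tex <- interior * stats::runif(length(interior), 20, 60)
        dim(tex) <- dim(interior)
        stamp_add(thg, r, c, tex + rim)
        stamp_add(adipo, r, c, interior)
        gt[[length(gt) + 1L]] <- add_gt(type, r, c, ceiling(rad + 3))
      }
    }
  }

  acc <- array(c(thg, nadh, shg, fad), c(size_px, size_px, 4L))
  if (phenotype$noise_sigma > 0)
    acc <- acc + stats::rnorm(length(acc), 0, phenotype$noise_sigma)
  ch <- array(as.integer(pmin(pmax(round(acc), 0), 255)), dim(acc))

  objects <- if (length(gt)) dplyr::bind_rows(gt) else
    tibble::tibble(type = character(), row = numeric(), col = numeric(),
                   bbox_rmin = numeric(), bbox_rmax = numeric(),
                   bbox_cmin = numeric(), bbox_cmax = numeric())
  slide <- virtual_slide(ch, subject_id, slide_id,
                         label = phenotype$class, pixel_size_um = pixel_size_um,
                         domain_tag = "synthetic_clean")
  list(slide = slide,
       ground_truth = list(objects = objects,
                           mask = adipocyte_mask(adipo > 0, slide_id)))
}

# ---- cohort generation ------------------------------------------------------

#' Generate a synthetic cohort and write it to disk
#'
#' Each subject receives one log-normal density multiplier applied to all of
#' its slides, inducing the intra-subject correlation that motivates
#' subject-level splitting. Slides are written as multi-page TIFFs, masks as
#' PNGs, ground truth as JSON, plus a manifest CSV.
#'
#' @param n_cancer,n_normal subjects per class (>= 1).
#' @param slides_per_subject slides per subject.
#' @param params list with `cancer` and `normal` [tissue_phenotype()]s.
#' @param size_px,pixel_size_um slide geometry.
#' @param out_dir output directory (created if needed).
#' @param seed master seed; subject and slide seeds are derived by stable
#'   hashing of identifiers, so regeneration is bit-identical.
#' @return the manifest tibble (invisibly written to `out_dir/manifest.csv`),
#'   with an extra `gt_path` column.
#' @export
generate_cohort <- function(n_cancer, n_normal, slides_per_subject = 3L,
                            params = phenotype_pair(), size_px = 1024L,
                            pixel_size_um = 1, out_dir = tempfile("cohort"),
                            seed = 1L) {
  stopifnot(n_cancer >= 1, n_normal >= 1, slides_per_subject >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- tibble::tibble(
    subject_id = c(sprintf("C%02d", seq_len(n_cancer)),
                   sprintf("N%02d", seq_len(n_normal))),
    label = rep(c("cancer", "normal"), c(n_cancer, n_normal)))

  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    ph <- params[[subjects$label[i]]]
    set.seed(derive_seed(seed, "subject", sid))
    eff <- exp(stats::rnorm(1, 0, ph$subject_sd))
    for (j in seq_len(slides_per_subject)) {
      slide_id <- sprintf("%s_s%d", sid, j)
      g <- generate_slide(ph, subject_effect = eff, size_px = size_px,
                          pixel_size_um = pixel_size_um,
                          seed = derive_seed(seed, "slide", sid, j),
                          subject_id = sid, slide_id = slide_id)
      sp <- file.path(out_dir, paste0(slide_id, ".tif"))
      mp <- file.path(out_dir, paste0(slide_id, "_mask.png"))
      gp <- file.path(out_dir, paste0(slide_id, "_gt.json"))
      write_slide(g$slide, sp)
      write_mask(g$ground_truth$mask, mp)
      jsonlite::write_json(g$ground_truth$objects, gp, digits = NA)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, slide_id = slide_id, label = subjects$label[i],
        slide_path = sp, mask_path = mp, pixel_size_um = pixel_size_um,
        domain_tag = "synthetic_clean", gt_path = gp)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  validate_manifest(manifest)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Load a cohort's slides, masks and ground truth into memory
#'
#' @param manifest a manifest tibble (from [generate_cohort()] or
#'   [read_manifest()]).
#' @return a `cohort` object: list of `manifest`, named `slides`, `masks`,
#'   and `ground_truth` (NULL entries where files are absent).
#' @export
load_cohort <- function(manifest) {
  validate_manifest(manifest)
  slides <- masks <- gts <- stats::setNames(vector("list", nrow(manifest)),
                                            manifest$slide_id)
  for (i in seq_len(nrow(manifest))) {
    slides[[i]] <- read_slide(manifest$slide_path[i], manifest[i, ])
    if (!is.na(manifest$mask_path[i]) && nzchar(manifest$mask_path[i]))
      masks[[i]] <- read_mask(manifest$mask_path[i], manifest$slide_id[i])
    if ("gt_path" %in% names(manifest) && !is.na(manifest$gt_path[i]))
      gts[[i]] <- tibble::as_tibble(
        jsonlite::read_json(manifest$gt_path[i], simplifyVector = TRUE))
  }
  structure(list(manifest = manifest, slides = slides, masks = masks,
                 ground_truth = gts), class = "mp_cohort")
}

#' @export
print.mp_cohort <- function(x, ...) {
  cat("<mp_cohort>", nrow(x$manifest), "slides,",
      length(unique(x$manifest$subject_id)), "subjects\n")
  invisible(x)
}
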