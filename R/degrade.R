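# Physics-based artificial degradation: clean lab-domain slides are
# converted into intraoperative-like slides by (1) convolution with an
# incremental point-spread-function so the net system FWHM is 10% larger
# than the clean system's, (2) row-wise jitter mimicking floor vibrations,
# (3) additive white Gaussian ambient-light noise per channel, and
# (4) 4x block-mean downsampling. Composition order blur -> jitter -> noise
# -> downsample is a documented convention; each stage re-clips and
# re-quantises to 8 bits because the pipeline carries 8-bit slides.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Degradation configuration
#'
#' @param psf_fwhm_scale net FWHM inflation of the degraded system relative
#'   to the clean system (>= 1; default 1.10, i.e. "10% larger").
#' @param base_psf_fwhm_um effective PSF FWHM of the clean system, in um.
#' @param ambient_noise_sigma per-channel Gaussian noise sd, 8-bit units
#'   (THG, NADH, SHG, FAD).
#' @param jitter_max_shift_px maximum row shift in pixels.
#' @param jitter_line_prob probability a given row is shifted.
#' @param frame_shift_px optional whole-frame shift bound ("shifting of
#'   pixels" as distinct from lines; 0 disables).
#' @param downsample_factor integer block size of the mean reduction.
#' @param mode one of `"full"`, `"downsample_only"`, `"degrade_only"`,
#'   `"none"` (ablation arms).
#' @param seed integer seed for the stochastic stages.
#' @export
degradation_config <- function(psf_fwhm_scale = 1.10, base_psf_fwhm_um = 2,
                               ambient_noise_sigma = c(25, 25, 25, 25),
                               jitter_max_shift_px = 2L,
                               jitter_line_prob = 0.1,
                               frame_shift_px = 0L,
                               downsample_factor = 4L,
                               mode = c("full", "downsample_only",
                                        "degrade_only", "none"),
                               seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(psf_fwhm_scale >= 1, base_psf_fwhm_um > 0,
            all(ambient_noise_sigma >= 0), length(ambient_noise_sigma) == 4L,
            jitter_max_shift_px >= 0, jitter_line_prob >= 0,
            jitter_line_prob <= 1, downsample_factor >= 1)
  structure(list(psf_fwhm_scale = psf_fwhm_scale,
                 base_psf_fwhm_um = base_psf_fwhm_um,
                 ambient_noise_sigma = ambient_noise_sigma,
                 jitter_max_shift_px = as.integer(jitter_max_shift_px),
                 jitter_line_prob = jitter_line_prob,
                 frame_shift_px = as.integer(frame_shift_px),
                 downsample_factor = as.integer(downsample_factor),
                 mode = mode, seed = as.integer(seed)),
            class = "degradation_config")
}

#' Discrete Gaussian PSF kernel
#'
#' Gaussian surrogate for a measured point-spread function with
#' `sigma = fwhm_um * FWHM_TO_SIGMA / pixel_size_um`, truncated at
#' `truncate_sigmas` and normalised to sum 1.
#'
#' @param fwhm_um full width at half maximum in micrometres.
#' @param pixel_size_um pixel size in micrometres.
#' @param truncate_sigmas truncation radius in sigmas.
#' @return a `psf_kernel`: list of `kernel` matrix, `fwhm_um`,
#'   `pixel_size_um`.
#' @export
gaussian_psf <- function(fwhm_um, pixel_size_um, truncate_sigmas = 4) {
  stopifnot(fwhm_um > 0, pixel_size_um > 0)
  sigma <- fwhm_um * FWHM_TO_SIGMA / pixel_size_um
  if (fwhm_um < pixel_size_um / 2)
    warning("PSF FWHM below half a pixel; returning a near-delta kernel")
  rad <- max(1L, ceiling(truncate_sigmas * sigma))
  d <- (-rad):rad
  g <- exp(-d^2 / (2 * sigma^2))
  k <- outer(g, g)
  structure(list(kernel = k / sum(k), fwhm_um = fwhm_um,
                 pixel_size_um = pixel_size_um), class = "psf_kernel")
}

# apply an operator plane-wise and re-quantise to 8 bit
requantize <- function(slide, planes, domain_tag = slide$domain_tag) {
  ch <- array(as.integer(pmin(pmax(round(planes), 0), 255)), dim(planes))
  s <- slide
  s$channels <- ch
  dimnames(s$channels) <- list(NULL, NULL, MP_CHANNELS)
  s$domain_tag <- domain_tag
  s
}

#' Blur a slide with a PSF kernel
#'
#' Reflect-padded convolution of each channel, re-quantised to 8 bits.
#'
#' @param slide a [virtual_slide()].
#' @param kernel a [gaussian_psf()] kernel (normalised).
#' @export
apply_blur <- function(slide, kernel) {
  stopifnot(inherits(kernel, "psf_kernel"))
  d <- dim(slide$channels)
  out <- array(0, d)
  for (i in 1:4)
    out[, , i] <- cpp_conv2_reflect(slide$channels[, , i] * 1.0, kernel$kernel)
  requantize(slide, out)
}

#' Add per-channel ambient-light noise
#'
#' i.i.d. Gaussian noise per pixel and channel, clipped to 0..255 and
#' quantised; deterministic given `seed`.
#'
#' @param slide a [virtual_slide()].
#' @param sigma_per_channel length-4 nonnegative sds (8-bit units).
#' @param seed integer seed.
#' @export
add_ambient_noise <- function(slide, sigma_per_channel, seed = 1L) {
  stopifnot(all(sigma_per_channel >= 0), length(sigma_per_channel) == 4L)
  set.seed(seed)
  d <- dim(slide$channels)
  out <- array(0, d)
  for (i in 1:4) {
    out[, , i] <- slide$channels[, , i] +
      if (sigma_per_channel[i] > 0)
        stats::rnorm(d[1] * d[2], 0, sigma_per_channel[i]) else 0
  }
  requantize(slide, out)
}

#' Row-jitter a slide to mimic floor vibrations
#'
#' Each row is independently shifted horizontally by a uniform integer in
#' `[-max_shift_px, max_shift_px]` with probability `line_prob`; edge pixels
#' are replicated. All four channels shift identically per row (they are
#' acquired simultaneously). Optionally the whole frame is shifted first.
#'
#' @param slide a [virtual_slide()].
#' @param max_shift_px maximum per-row shift.
#' @param line_prob probability a row shifts.
#' @param seed integer seed.
#' @param frame_shift_px bound of an optional whole-frame integer shift.
#' @export
apply_vibration_jitter <- function(slide, max_shift_px, line_prob, seed = 1L,
                                   frame_shift_px = 0L) {
  stopifnot(max_shift_px >= 0)
  set.seed(seed)
  d <- dim(slide$channels)
  ch <- slide$channels
  if (frame_shift_px > 0) {
    fs <- sample(-frame_shift_px:frame_shift_px, 2L, replace = TRUE)
    ri <- pmin(pmax(seq_len(d[1]) + fs[1], 1L), d[1])
    ci <- pmin(pmax(seq_len(d[2]) + fs[2], 1L), d[2])
    ch <- ch[ri, ci, , drop = FALSE]
  }
  if (max_shift_px > 0 && line_prob > 0) {
    hit <- stats::runif(d[1]) < line_prob
    shifts <- integer(d[1])
    shifts[hit] <- sample(-max_shift_px:max_shift_px, sum(hit), replace = TRUE)
    for (s in setdiff(unique(shifts), 0L)) {
      rows <- which(shifts == s)
      ci <- pmin(pmax(seq_len(d[2]) + s, 1L), d[2]) # edge replication
      ch[rows, , ] <- ch[rows, ci, , drop = FALSE]
    }
  }
  s <- slide; s$channels <- ch
  dimnames(s$channels) <- list(NULL, NULL, MP_CHANNELS)
  s
}

#' Block-mean downsampling
#'
#' `factor x factor` block-mean reduction per channel; the output pixel size
#' is `factor` times the input's. Non-divisible dimensions are cropped to the
#' nearest multiple with a warning.
#'
#' @param slide a [virtual_slide()].
#' @param factor integer reduction factor.
#' @export
downsample <- function(slide, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(slide)
  d <- dim(slide$channels)
  h <- d[1] %/% factor * factor; w <- d[2] %/% factor * factor
  if (h != d[1] || w != d[2])
    warning("dimensions not divisible by ", factor, "; cropping to ", h, "x", w)
  out <- array(0, c(h %/% factor, w %/% factor, 4L))
  for (i in 1:4) {
    m <- slide$channels[seq_len(h), seq_len(w), i]
    # block means: average rows within blocks, then columns
    m <- matrix(colMeans(matrix(m, nrow = factor)), nrow = h %/% factor)
    m <- t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = w %/% factor))
    out[, , i] <- m
  }
  s <- requantize(slide, out)
  s$pixel_size_um <- slide$pixel_size_um * factor
  s
}

#' Degrade a clean slide into the intraoperative-like domain
#'
#' Applies the configured composition: `full` = blur, jitter, noise, then
#' downsample; `downsample_only` and `degrade_only` are the ablation arms;
#' `none` is the identity. The blur uses an incremental Gaussian kernel of
#' width `base * sqrt(scale^2 - 1)` so the net system FWHM equals
#' `scale * base` (widths add in quadrature).
#'
#' @param slide a clean-domain [virtual_slide()].
#' @param config a [degradation_config()].
#' @return a [virtual_slide()]; `domain_tag` becomes `"synthetic_degraded"`
#'   unless `mode = "none"`.
#' @export
degrade_slide <- function(slide, config) {
  stopifnot(inherits(config, "degradation_config"))
  if (config$mode == "none") return(slide)
  s <- slide
  if (config$mode %in% c("full", "degrade_only")) {
    inc_fwhm <- config$base_psf_fwhm_um * sqrt(config$psf_fwhm_scale^2 - 1)
    if (inc_fwhm > 0) {
      k <- suppressWarnings(gaussian_psf(inc_fwhm, slide$pixel_size_um))
      s <- apply_blur(s, k)
    }
    s <- apply_vibration_jitter(s, config$jitter_max_shift_px,
                                config$jitter_line_prob,
                                seed = derive_seed(config$seed, "jitter",
                                                   slide$slide_id),
                                frame_shift_px = config$frame_shift_px)
    s <- add_ambient_noise(s, config$ambient_noise_sigma,
                           seed = derive_seed(config$seed, "noise",
                                              slide$slide_id))
  }
  if (config$mode %in% c("full", "downsample_only"))
    s <- downsample(s, config$downsample_factor)
  s$domain_tag <- "synthetic_degraded"
  s
}
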