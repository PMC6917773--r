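# Virtual-slide data model and file I/O.
#
# A virtual slide is one large field-of-view, four-channel multiphoton image:
# THG (interfaces, vesicles, lipid rims), NADH and FAD (two-/three-photon
# autofluorescence of cellular metabolism) and SHG (collagen). Channels are
# co-registered by the imaging physics, stored as 8-bit planes.

#' Fixed multiphoton channel order
#' @export
MP_CHANNELS <- c("THG", "NADH", "SHG", "FAD")

#' Valid slide domain tags
#' @export
MP_DOMAINS <- c("lab", "intraop", "synthetic_clean", "synthetic_degraded")

#' Construct a virtual slide
#'
#' @param channels integer array of dim `(H, W, 4)` with values in 0..255,
#'   channel order THG, NADH, SHG, FAD.
#' @param subject_id,slide_id identifiers; a subject may own several slides.
#' @param label `"cancer"` or `"normal"` (subject-level diagnosis).
#' @param pixel_size_um isotropic pixel size in micrometres (> 0).
#' @param domain_tag one of [MP_DOMAINS].
#' @return an object of class `virtual_slide`.
#' @export
virtual_slide <- function(channels, subject_id, slide_id, label,
                          pixel_size_um, domain_tag = "synthetic_clean") {
  d <- dim(channels)
  if (length(d) != 3L || d[3] != 4L)
    stop("`channels` must be an (H, W, 4) array in order ",
         paste(MP_CHANNELS, collapse = ", "))
  if (anyNA(channels) || min(channels) < 0 || max(channels) > 255)
    stop("channel intensities must lie in [0, 255]")
  if (any(channels != round(channels)))
    stop("channel intensities must be integers (8-bit representation)")
  label <- match.arg(label, c("cancer", "normal"))
  domain_tag <- match.arg(domain_tag, MP_DOMAINS)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar")
  storage.mode(channels) <- "integer"
  dimnames(channels) <- list(NULL, NULL, MP_CHANNELS)
  structure(list(subject_id = as.character(subject_id),
                 slide_id = as.character(slide_id),
                 label = label, channels = channels,
                 pixel_size_um = pixel_size_um, domain_tag = domain_tag),
            class = "virtual_slide")
}

#' @export
print.virtual_slide <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<virtual_slide> %s/%s [%s, %s] %dx%d px @ %.3g um/px\n",
              x$subject_id, x$slide_id, x$label, x$domain_tag,
              d[1], d[2], x$pixel_size_um))
  invisible(x)
}

#' @export
dim.virtual_slide <- function(x) dim(x$channels)[1:2]

#' Read a virtual slide from a multi-page TIFF
#'
#' The file must hold exactly four pages of equal shape in THG, NADH, SHG,
#' FAD order. Identity and pixel size come from `record` (a one-row manifest
#' entry) or, failing that, from the JSON sidecar written by [write_slide()].
#' Non-8-bit sources are linearly min-max rescaled per channel to 0..255 and
#' rounded.
#'
#' @param path path to the slide TIFF.
#' @param record optional one-row data frame with columns `subject_id`,
#'   `slide_id`, `label`, `pixel_size_um`, `domain_tag`.
#' @return a [virtual_slide()].
#' @export
read_slide <- function(path, record = NULL) {
  if (!file.exists(path)) stop("slide file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 4L)
    stop("expected 4 channel pages (", paste(MP_CHANNELS, collapse = ", "),
         ") but found ", length(pages))
  shp <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), shp), logical(1))))
    stop("channel planes are misaligned: pages differ in shape")
  ch <- array(0L, c(shp, 4L))
  for (i in 1:4) {
    p <- pages[[i]]
    if (max(p) > 255 || min(p) < 0) { # non-8-bit source: min-max rescale
      rng <- range(p)
      p <- if (rng[2] > rng[1]) round((p - rng[1]) / (rng[2] - rng[1]) * 255) else p * 0
    }
    ch[, , i] <- as.integer(round(p))
  }
  if (is.null(record)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no manifest record supplied and no sidecar found for ", path)
    record <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  virtual_slide(ch, record$subject_id, record$slide_id, record$label,
                record$pixel_size_um, record$domain_tag)
}

#' Write a virtual slide as a multi-page TIFF plus JSON sidecar
#'
#' The sidecar (`<path>.json`) carries identity, label, pixel size and
#' domain tag so that `read_slide(write_slide(s))` reproduces `s` bit-exactly.
#'
#' @param slide a [virtual_slide()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "virtual_slide"))
  pages <- lapply(1:4, function(i) slide$channels[, , i] / 255)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 8L), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write slide to ", path)
  jsonlite::write_json(list(subject_id = slide$subject_id,
                            slide_id = slide$slide_id, label = slide$label,
                            pixel_size_um = slide$pixel_size_um,
                            domain_tag = slide$domain_tag),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary adipocyte mask (PNG or TIFF)
#'
#' @param path mask path; pixels > 0 are lipid.
#' @param slide_id identifier of the slide the mask belongs to.
#' @return an `adipocyte_mask`: list with `slide_id` and integer 0/1 `mask`.
#' @export
read_mask <- function(path, slide_id = NA_character_) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(m)) == 3L) m <- m[, , 1]
  adipocyte_mask(m > 0.5, slide_id)
}

#' @rdname read_mask
#' @param mask logical or 0/1 matrix.
#' @export
adipocyte_mask <- function(mask, slide_id = NA_character_) {
  m <- matrix(as.integer(mask > 0), nrow = nrow(mask))
  structure(list(slide_id = as.character(slide_id), mask = m),
            class = "adipocyte_mask")
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "adipocyte_mask"))
  png::writePNG(mask$mask * 1.0, path)
  invisible(path)
}

# ---- manifest ---------------------------------------------------------------

manifest_cols <- c("subject_id", "slide_id", "label", "slide_path",
                   "mask_path", "pixel_size_um", "domain_tag")

validate_manifest <- function(m) {
  miss <- setdiff(manifest_cols, names(m))
  if (length(miss)) stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(paste(m$subject_id, m$slide_id)))
    stop("manifest has duplicate (subject_id, slide_id) pairs")
  lab_per_subj <- tapply(m$label, m$subject_id, function(x) length(unique(x)))
  if (any(lab_per_subj > 1))
    stop("each subject must carry exactly one label; offending subject(s): ",
         paste(names(lab_per_subj)[lab_per_subj > 1], collapse = ", "))
  if (!all(m$label %in% c("cancer", "normal")))
    stop("labels must be 'cancer' or 'normal'")
  invisible(m)
}

#' Read or write a cohort manifest CSV
#'
#' Columns: `subject_id, slide_id, label, slide_path, mask_path,
#' pixel_size_um, domain_tag`. `(subject_id, slide_id)` must be unique and a
#' subject has exactly one label.
#'
#' @param path CSV path.
#' @return a tibble with one row per slide.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- tibble::as_tibble(m)
  m$mask_path <- as.character(m$mask_path)
  m$mask_path[is.na(m$mask_path) | !nzchar(m$mask_path)] <- NA_character_
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest tibble of manifest rows.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest[manifest_cols], path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- composite rendering ----------------------------------------------------

#' Default channel colormap
#'
#' Rows are channel weights into (R, G, B): SHG renders green (collagen),
#' THG blue (vesicles, interfaces), NADH cyan-weighted and FAD red+green so
#' coincident NADH+FAD structures (elastin) render towards yellow.
#'
#' @return a 4x3 matrix with rownames THG, NADH, SHG, FAD.
#' @export
default_colormap <- function() {
  cm <- rbind(THG  = c(0.0, 0.0, 1.0),
              NADH = c(0.0, 0.5, 0.5),
              SHG  = c(0.0, 1.0, 0.0),
              FAD  = c(0.6, 0.6, 0.0))
  colnames(cm) <- c("R", "G", "B")
  cm
}

#' Render a slide as an RGB composite with optional overlays
#'
#' The base image is a per-pixel linear combination of the four channels
#' under `colormap`, clipped to 0..255. A tile probability map pushes the red
#' plane towards 255 proportionally to each tile's cancer probability; an
#' adipocyte mask renders lipid pixels blue.
#'
#' @param slide a [virtual_slide()].
#' @param prob_map optional `tile_prob_map` aligned to the slide.
#' @param mask optional `adipocyte_mask` aligned to the slide.
#' @param colormap 4x3 channel->RGB weight matrix.
#' @return a `composite_rendering`: list with 8-bit `rgb` array `(H, W, 3)`.
#' @export
render_composite <- function(slide, prob_map = NULL, mask = NULL,
                             colormap = default_colormap()) {
  stopifnot(inherits(slide, "virtual_slide"))
  d <- dim(slide$channels)
  rgb <- array(0, c(d[1], d[2], 3L))
  for (ci in 1:4)
    for (pl in 1:3)
      if (colormap[ci, pl] != 0)
        rgb[, , pl] <- rgb[, , pl] + colormap[ci, pl] * slide$channels[, , ci]
  rgb <- pmin(pmax(rgb, 0), 255)
  if (!is.null(prob_map)) {
    pp <- prob_pixels(prob_map, c(d[1], d[2]))
    rgb[, , 1] <- rgb[, , 1] + pp * (255 - rgb[, , 1])
  }
  if (!is.null(mask)) {
    if (!all(dim(mask$mask) == d[1:2]))
      stop("adipocyte mask is misaligned with the slide grid")
    mm <- mask$mask == 1L
    for (pl in 1:2) { p <- rgb[, , pl]; p[mm] <- 0.3 * p[mm]; rgb[, , pl] <- p }
    b <- rgb[, , 3]; b[mm] <- pmax(b[mm], 220); rgb[, , 3] <- b
  }
  structure(list(rgb = round(rgb), colormap = colormap,
                 slide_id = slide$slide_id), class = "composite_rendering")
}

# expand a tile probability map to a per-pixel [0,1] plane
prob_pixels <- function(prob_map, dims) {
  stopifnot(inherits(prob_map, "tile_prob_map"))
  pp <- matrix(0, dims[1], dims[2])
  g <- prob_map$grid
  ts <- prob_map$tile_size
  for (k in seq_len(nrow(g))) {
    if (!g$retained[k]) next
    r0 <- g$r0[k]; c0 <- g$c0[k]
    if (r0 + ts > dims[1] || c0 + ts > dims[2])
      stop("probability map is misaligned with the slide grid")
    pp[(r0 + 1):(r0 + ts), (c0 + 1):(c0 + ts)] <- g$prob[k]
  }
  pp
}

#' @rdname render_composite
#' @param rendering a `composite_rendering`.
#' @param path output PNG path.
#' @export
write_rendering <- function(rendering, path) {
  png::writePNG(rendering$rgb / 255, path)
  invisible(path)
}
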