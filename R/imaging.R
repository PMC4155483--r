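#' Masked time-lapse image stack
#'
#' Bundles the frame files of a degradation time-lapse with their acquisition
#' times, the region-of-interest mask (the pixels of the degrading sample)
#' and a disjoint reference region (a neutral patch used for colour balance).
#'
#' @param frame_paths Character vector of image file paths, in time order.
#' @param times Acquisition times in minutes, one per frame.
#' @param roi_mask Logical matrix (same dimensions as the frames), `TRUE` on
#'   sample pixels; must be non-empty.
#' @param reference_region Logical matrix, `TRUE` on reference-patch pixels;
#'   non-empty and disjoint from the ROI.
#' @return An object of class `masked_stack`.
#' @export
masked_stack <- function(frame_paths, times, roi_mask, reference_region) {
  stopifnot(is.character(frame_paths), length(frame_paths) >= 1L,
            length(times) == length(frame_paths),
            is.logical(roi_mask), is.logical(reference_region))
  if (!any(roi_mask)) stop(input_error("ROI mask is empty"))
  if (!any(reference_region)) stop(input_error("reference region is empty"))
  if (!identical(dim(roi_mask), dim(reference_region))) {
    stop(input_error("mask and reference rasters must share dimensions"))
  }
  if (any(roi_mask & reference_region)) {
    stop(input_error("reference region must be disjoint from the ROI"))
  }
  structure(list(frame_paths = frame_paths, times = times,
                 roi_mask = roi_mask, reference_region = reference_region),
            class = "masked_stack")
}

read_frame_rgb <- function(path) {
  img <- tryCatch(png::readPNG(path), error = function(e) {
    stop(data_error(sprintf("cannot read frame '%s': %s", path,
                            conditionMessage(e))))
  })
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  img[, , 1:3, drop = FALSE] * 255
}

#' Extract the mean-RGB time series from a masked image stack
#'
#' Per frame: optionally apply [reference_balance()] using the mean RGB of
#' the reference region, then take the arithmetic mean of the ROI pixels per
#' channel. The balance scaling is applied at the level of the channel means
#' (it is a per-channel linear map, so pre-clipping this equals per-pixel
#' application).
#'
#' @param stack A [masked_stack()].
#' @param balance Apply the reference-patch balance (default `TRUE`).
#' @return An [rgb_series()].
#' @export
extract_rgb_series <- function(stack, balance = TRUE) {
  stopifnot(inherits(stack, "masked_stack"))
  rgb <- matrix(NA_real_, length(stack$frame_paths), 3L)
  for (i in seq_along(stack$frame_paths)) {
    img <- read_frame_rgb(stack$frame_paths[i])
    if (!identical(dim(img)[1:2], dim(stack$roi_mask))) {
      stop(data_error(sprintf(
        "frame '%s' dimensions (%d x %d) do not match the mask (%d x %d)",
        stack$frame_paths[i], dim(img)[1], dim(img)[2],
        nrow(stack$roi_mask), ncol(stack$roi_mask))))
    }
    roi_mean <- vapply(1:3, function(c) mean(img[, , c][stack$roi_mask]),
                       numeric(1))
    if (balance) {
      ref_mean <- vapply(1:3, function(c) {
        mean(img[, , c][stack$reference_region])
      }, numeric(1))
      roi_mean <- reference_balance(roi_mean, ref_mean)
    }
    rgb[i, ] <- roi_mean
  }
  rgb_series(stack$times, rgb)
}

# Default fixture geometry: centred disc ROI, rectangular reference patch in
# the top-left corner, dark background.
fixture_masks <- function(size_px, roi_radius_px) {
  ctr <- (size_px + 1) / 2
  xy <- expand.grid(row = seq_len(size_px), col = seq_len(size_px))
  roi <- matrix((xy$row - ctr)^2 + (xy$col - ctr)^2 <= roi_radius_px^2,
                size_px, size_px)
  ref <- matrix(FALSE, size_px, size_px)
  ref[2:(max(3, size_px %/% 8)), 2:(max(3, size_px %/% 8))] <- TRUE
  if (any(roi & ref)) stop(input_error("fixture ROI and reference overlap"))
  list(roi = roi, ref = ref)
}

#' Generate a synthetic image stack from a rendered RGB series
#'
#' Writes one 8-bit RGB PNG per time point: a centred disc ROI filled with
#' the rendered triplet (plus optional seeded Gaussian per-pixel noise), a
#' neutral-gray reference patch, and a distinct dark background; plus the ROI
#' and reference mask rasters (single-channel PNG, 0/255) and a
#' `manifest.csv` (`filename, time_min`). Output is deterministic for a given
#' seed. PNG is used for losslessness; these synthetic frames stand in for
#' the flow-cell photographs of a real experiment.
#'
#' @param rendered An [rgb_series()] of ROI triplets.
#' @param out_dir Output directory (created if needed).
#' @param noise_sd Gaussian pixel-noise SD in 8-bit counts, per channel
#'   (scalar or length 3; default 0).
#' @param seed Optional RNG seed (caller's RNG state is restored).
#' @param size_px Frame side length in pixels (square frames; default 64).
#' @param roi_radius_px ROI disc radius in pixels (default `size_px * 3/8`).
#' @param reference_gray Reference-patch level in counts (default 180).
#' @param background_gray Background level in counts (default 40).
#' @return A [masked_stack()] pointing at the written files.
#' @export
generate_fixture_stack <- function(rendered, out_dir, noise_sd = 0,
                                   seed = NULL, size_px = 64,
                                   roi_radius_px = round(size_px * 3 / 8),
                                   reference_gray = 180,
                                   background_gray = 40) {
  if (!inherits(rendered, "rgb_series")) {
    stop(input_error("rendered must be an rgb_series"))
  }
  if (any(noise_sd < 0)) stop(input_error("noise_sd must be >= 0"))
  noise_sd <- rep_len(noise_sd, 3L)
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop(data_error(sprintf("cannot write to directory '%s'", out_dir)))
  }
  masks <- fixture_masks(size_px, roi_radius_px)
  n_roi <- sum(masks$roi)
  paths <- character(nrow(rendered))
  with_seed(seed, {
    for (i in seq_len(nrow(rendered))) {
      img <- array(background_gray / 255, c(size_px, size_px, 3L))
      for (c in 1:3) {
        plane <- img[, , c]
        px <- rep(as.numeric(rendered[i, c + 1L]), n_roi)
        if (noise_sd[c] > 0) px <- px + stats::rnorm(n_roi, sd = noise_sd[c])
        plane[masks$roi] <- pmin(255, pmax(0, px)) / 255
        plane[masks$ref] <- reference_gray / 255
        img[, , c] <- plane
      }
      img <- round(img * 255) / 255  # 8-bit quantization
      paths[i] <- file.path(out_dir, sprintf("frame_%04d.png", i))
      png::writePNG(img, paths[i])
    }
  })
  png::writePNG(matrix(as.numeric(masks$roi), size_px, size_px),
                file.path(out_dir, "roi_mask.png"))
  png::writePNG(matrix(as.numeric(masks$ref), size_px, size_px),
                file.path(out_dir, "reference_mask.png"))
  utils::write.csv(data.frame(filename = basename(paths),
                              time_min = rendered$time_min),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  masked_stack(paths, rendered$time_min, masks$roi, masks$ref)
}

#' Load a masked stack from a fixture directory
#'
#' Reads `manifest.csv`, `roi_mask.png` and `reference_mask.png` as written
#' by [generate_fixture_stack()].
#'
#' @param dir Directory containing the stack.
#' @return A [masked_stack()].
#' @export
read_masked_stack <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) {
    stop(data_error(sprintf("no manifest.csv in '%s'", dir)))
  }
  man <- utils::read.csv(manifest)
  read_mask <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop(data_error(sprintf("missing mask '%s'", p)))
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m > 0.5
  }
  masked_stack(file.path(dir, man$filename), man$time_min,
               read_mask("roi_mask.png"), read_mask("reference_mask.png"))
}
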