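#' Segment canopy pixels from a thermal image
#'
#' Either passes through an externally provided mask or splits the pixel
#' temperatures into two one-dimensional clusters (two-means) and assigns
#' the cooler cluster to the canopy.  The temperature-gap route requires
#' the split to be convincingly bimodal: the separation index
#' `(m2 - m1) / (s1 + s2)` (cluster-mean gap over summed within-cluster
#' standard deviations) must reach `min_separation`.  A unimodal
#' distribution scores around 1.3 on this index, so the default threshold
#' of 2 rejects images with no visible canopy/background gap.
#'
#' @param img a [thermal_image()].
#' @param mask optional logical matrix congruent with the image; when
#'   supplied it is validated and passed through.
#' @param min_pixels minimum admissible canopy size in pixels.
#' @param min_separation bimodality threshold for the separation index.
#' @return An object of class `"canopy_mask"`: list with `mask` (logical
#'   matrix) and `n_canopy`.
#' @export
#' @examples
#' sim <- simulate_thermal_image(seed = 1)
#' m <- segment_canopy(sim$image)
#' m$n_canopy
segment_canopy <- function(img, mask = NULL, min_pixels = 25,
                           min_separation = 2) {
  stopifnot(inherits(img, "thermal_image"))
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(img$pixels)))
      stop("provided mask shape does not match the image", call. = FALSE)
    if (!is.logical(mask)) mask <- mask > 0
  } else {
    px <- as.numeric(img$pixels)
    if (diff(range(px)) == 0)
      stop("segmentation failure: image is constant, no temperature gap",
           call. = FALSE)
    km <- kmeans(px, centers = sort(quantile(px, c(0.1, 0.9))))
    mu <- sort(km$centers[, 1L])
    cool <- which.min(km$centers[, 1L])
    s <- vapply(1:2, function(g) {
      v <- px[km$cluster == g]
      if (length(v) > 1L) sd(v) else 0
    }, numeric(1L))
    sep <- (mu[2L] - mu[1L]) / max(sum(s), .Machine$double.eps)
    if (sep < min_separation)
      stop("segmentation failure: pixel distribution not bimodal ",
           "(separation index ", format(sep, digits = 3), " < ",
           min_separation, ")", call. = FALSE)
    mask <- matrix(km$cluster == cool, nrow = nrow(img$pixels))
  }
  n <- sum(mask)
  if (n < min_pixels)
    stop("segmentation failure: canopy has ", n, " pixels (< ",
         min_pixels, ")", call. = FALSE)
  structure(list(mask = mask, n_canopy = n), class = "canopy_mask")
}

#' @export
print.canopy_mask <- function(x, ...) {
  cat("Canopy mask:", x$n_canopy, "of", length(x$mask), "pixels\n")
  invisible(x)
}

#' Empirical wet and dry reference temperatures
#'
#' Frequency analysis of the canopy pixel distribution: the wet reference
#' is the mean of the coolest `ceiling(tail * n)` canopy pixels and the
#' dry reference the mean of the hottest `ceiling(tail * n)`.  A constant
#' canopy returns `t_wet == t_dry` with `flat = TRUE`.
#'
#' @param img a [thermal_image()].
#' @param mask a [segment_canopy()] mask (or logical matrix).
#' @param tail tail fraction in (0, 0.5); default 0.05.
#' @return A list with `t_wet`, `t_dry`, `n_tail` and `flat`.
#' @export
#' @examples
#' img <- thermal_image(matrix(20:24, 1), ambient_temp = 25)
#' reference_temperatures(img, matrix(TRUE, 1, 5), tail = 0.2)
reference_temperatures <- function(img, mask, tail = 0.05) {
  stopifnot(inherits(img, "thermal_image"))
  if (inherits(mask, "canopy_mask")) mask <- mask$mask
  if (!is.numeric(tail) || length(tail) != 1L || tail <= 0 || tail >= 0.5)
    stop("tail fraction must lie strictly in (0, 0.5)", call. = FALSE)
  canopy <- sort(img$pixels[mask])
  n <- length(canopy)
  m <- ceiling(tail * n)
  if (m < 1L)
    stop("too few canopy pixels for tail fraction ", tail, call. = FALSE)
  t_wet <- mean(canopy[seq_len(m)])
  t_dry <- mean(canopy[seq.int(n - m + 1L, n)])
  list(t_wet = t_wet, t_dry = t_dry, n_tail = m,
       flat = isTRUE(all.equal(t_wet, t_dry)))
}

#' Crop water stress index
#'
#' \deqn{CWSI = (T_c - T_{wet})/(T_{dry} - T_{wet})}: 0 for a fully
#' transpiring canopy at the wet reference, 1 for a fully stressed canopy
#' at the dry reference.
#'
#' @param t_c canopy temperature, degC.
#' @param t_wet,t_dry wet and dry reference temperatures, degC.
#' @return The index (vectorized); `NA` where `t_dry <= t_wet`.
#' @export
#' @examples
#' cwsi(24.13, t_wet = 22.98, t_dry = 24.97)   # 0.578
cwsi <- function(t_c, t_wet, t_dry) {
  ifelse(t_dry > t_wet, (t_c - t_wet) / (t_dry - t_wet), NA_real_)
}

#' Infrared (stomatal-conductance) index
#'
#' \deqn{I_g = (T_{dry} - T_c)/(T_c - T_{wet})}, proportional to stomatal
#' conductance; higher values mean a cooler, more conductive canopy.
#' Undefined (`NA`) when `t_c == t_wet`.
#'
#' @inheritParams cwsi
#' @return The index (vectorized).
#' @export
ig_index <- function(t_c, t_wet, t_dry) {
  ifelse(t_c != t_wet, (t_dry - t_c) / (t_c - t_wet), NA_real_)
}

#' Canopy temperature depression
#'
#' \deqn{CTD = T_a - T_c}; positive when the canopy is cooler than the
#' surrounding air.
#'
#' @param t_a ambient air temperature, degC.
#' @param t_c canopy temperature, degC.
#' @return Temperature depression, degC (vectorized).
#' @export
ctd <- function(t_a, t_c) t_a - t_c

#' Water-stress summary of a thermal image
#'
#' Computes the canopy temperature (mean over canopy pixels), the
#' empirical reference temperatures, and the three water-stress indices
#' CWSI, Ig and CTD for one plant.  References supplied externally may
#' place `t_c` outside `[t_wet, t_dry]`; values are then flagged, never
#' clipped.
#'
#' @param img a [thermal_image()].
#' @param mask optional mask; segmented from the image when absent.
#' @param refs optional list with `t_wet`, `t_dry` (computed from the
#'   canopy tails when absent).
#' @param tail tail fraction for [reference_temperatures()].
#' @param ... passed to [segment_canopy()] when a mask must be derived.
#' @return A one-row data frame of class `"water_stress_summary"` with
#'   columns `plant_id`, `t_c`, `t_wet`, `t_dry`, `t_a`, `cwsi`, `ig`,
#'   `ctd`, `flag` (empty when all indices are defined and ordered).
#' @export
#' @examples
#' sim <- simulate_thermal_image(seed = 2)
#' water_stress_summary(sim$image, mask = sim$mask)
water_stress_summary <- function(img, mask = NULL, refs = NULL,
                                 tail = 0.05, ...) {
  stopifnot(inherits(img, "thermal_image"))
  if (is.null(mask)) mask <- segment_canopy(img, ...)
  if (inherits(mask, "canopy_mask")) mask <- mask$mask
  if (is.null(refs)) refs <- reference_temperatures(img, mask, tail = tail)
  t_c <- mean(img$pixels[mask])
  t_a <- img$ambient_temp
  flags <- character(0)
  if (refs$t_dry <= refs$t_wet) flags <- c(flags, "degenerate_references")
  if (t_c < refs$t_wet || t_c > refs$t_dry)
    flags <- c(flags, "tc_outside_references")
  cw <- cwsi(t_c, refs$t_wet, refs$t_dry)
  ig <- ig_index(t_c, refs$t_wet, refs$t_dry)
  if (is.na(ig) && !is.na(cw)) flags <- c(flags, "ig_undefined")
  out <- data.frame(plant_id = img$plant_id, t_c = t_c,
                    t_wet = refs$t_wet, t_dry = refs$t_dry, t_a = t_a,
                    cwsi = cw, ig = ig, ctd = ctd(t_a, t_c),
                    flag = paste(flags, collapse = ";"),
                    stringsAsFactors = FALSE)
  class(out) <- c("water_stress_summary", "data.frame")
  out
}

#' Batch water-stress summaries
#'
#' Applies [water_stress_summary()] to a list of thermal images (one row
#' per plant).  When several images share a `plant_id`, per-image indices
#' are computed first and then averaged (index-first averaging; averaging
#' temperatures first gives different, order-dependent results).
#'
#' @param imgs list of [thermal_image()] objects.
#' @param tail tail fraction for the reference temperatures.
#' @param average_by_plant average rows sharing a `plant_id`
#'   (default `TRUE`).
#' @param ... passed to [water_stress_summary()].
#' @return A data frame with one row per image (or per plant).
#' @export
water_stress_batch <- function(imgs, tail = 0.05, average_by_plant = TRUE,
                               ...) {
  rows <- do.call(rbind, lapply(imgs, water_stress_summary, tail = tail, ...))
  if (!average_by_plant || !anyDuplicated(rows$plant_id)) return(rows)
  num <- c("t_c", "t_wet", "t_dry", "t_a", "cwsi", "ig", "ctd")
  agg <- aggregate(rows[num], by = list(plant_id = rows$plant_id), mean)
  fl <- aggregate(rows["flag"], by = list(plant_id = rows$plant_id),
                  function(f) paste(unique(f[nzchar(f)]), collapse = ";"))
  out <- merge(agg, fl, by = "plant_id")
  class(out) <- c("water_stress_summary", "data.frame")
  out
}
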