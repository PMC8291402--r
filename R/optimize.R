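#' Configuration of the stack-optimization chain
#'
#' Defaults follow the acquisition-scale processing of micro-optical
#' whole-brain stacks: a grayscale opening with a 75x75x75 voxel kernel and
#' a 100x100x100 box filter build the background reference, and a 3x3x3
#' bilateral filter denoises. For desk-scale volumes pass proportionally
#' smaller kernels; kernels are validated against the (downsampled)
#' volume they are applied to.
#'
#' @param opening_kernel odd voxel kernel per axis for the grayscale opening.
#' @param boxfilter_kernel odd voxel kernel per axis for the box (mean) filter.
#' @param bilateral_kernel bilateral neighbourhood (fixed 3x3x3).
#' @param bilateral_sigma_spatial spatial sigma in voxels.
#' @param bilateral_sigma_range range sigma in gray levels; default 10\% of
#'   the dynamic range.
#' @param stretch_percentiles (low, high) percentiles mapped to the dynamic
#'   range ends by the linear histogram transform.
#' @param strip_axis axis the stripe artifact varies along (1 = z, 2 = y,
#'   3 = x).
#' @param strip_smooth_window odd window of the running-median baseline
#'   used by the stripe correction.
#' @param downsample_factor integer factor for the background estimation
#'   grid; kernels are scaled by the same factor.
#' @param background_mode \code{"subtract"} (flat-field by subtraction,
#'   preserving absolute vessel-background differences) or \code{"divide"}.
#' @return An object of class \code{optimize_config}.
#' @export
optimize_config <- function(opening_kernel = c(75, 75, 75),
                            boxfilter_kernel = c(100, 100, 100) + 1,
                            bilateral_kernel = c(3, 3, 3),
                            bilateral_sigma_spatial = 1,
                            bilateral_sigma_range = NULL,
                            stretch_percentiles = c(0.1, 99.9),
                            strip_axis = 2L,
                            strip_smooth_window = 33L,
                            downsample_factor = 4L,
                            background_mode = c("subtract", "divide")) {
  opening_kernel <- make_odd(opening_kernel)
  boxfilter_kernel <- make_odd(boxfilter_kernel)
  assert_odd(opening_kernel, "opening_kernel")
  assert_odd(boxfilter_kernel, "boxfilter_kernel")
  if (!all(bilateral_kernel == 3)) stop("bilateral_kernel is fixed at 3x3x3")
  sp <- stretch_percentiles
  if (length(sp) != 2 || sp[1] < 0 || sp[2] > 100 || sp[1] >= sp[2])
    stop("stretch_percentiles must satisfy 0 <= low < high <= 100")
  structure(list(opening_kernel = as.integer(opening_kernel),
                 boxfilter_kernel = as.integer(boxfilter_kernel),
                 bilateral_kernel = as.integer(bilateral_kernel),
                 bilateral_sigma_spatial = bilateral_sigma_spatial,
                 bilateral_sigma_range = bilateral_sigma_range,
                 stretch_percentiles = sp,
                 strip_axis = as.integer(strip_axis),
                 strip_smooth_window = as.integer(strip_smooth_window),
                 downsample_factor = as.integer(downsample_factor),
                 background_mode = match.arg(background_mode)),
            class = "optimize_config")
}

make_odd <- function(k) { k <- as.integer(k); k + ifelse(k %% 2 == 0, 1L, 0L) }

#' Correct periodic stripe artifacts by baseline drift modification
#'
#' Computes the mean gray profile along the stripe axis (one value per
#' plane perpendicular to \code{strip_axis}), smooths it with a running
#' median to obtain the anatomical baseline, and subtracts the
#' mean-centred residual (the stripe drift) from every plane. The volume
#' mean is preserved exactly.
#'
#' @param v a \code{\link{volume3d}}.
#' @param strip_axis axis the stripes vary along.
#' @param smooth_window odd running-median window, >= 3; must exceed the
#'   stripe period for full suppression and be at most the profile length.
#' @return The corrected \code{\link{volume3d}}.
#' @export
correct_strips <- function(v, strip_axis = 2L, smooth_window = 33L) {
  assert_odd(smooth_window, "smooth_window")
  if (smooth_window < 3) stop("smooth_window must be >= 3")
  d <- dim(v$voxels)
  if (smooth_window > d[strip_axis])
    stop("smooth_window (", smooth_window, ") exceeds profile length (",
         d[strip_axis], ") along axis ", strip_axis)
  prof <- apply(v$voxels, strip_axis, mean)
  base <- runmed(prof, smooth_window, endrule = "median")
  delta <- prof - base
  delta <- delta - mean(delta)           # exact mean preservation
  out <- sweep(v$voxels, strip_axis, delta, `-`)
  volume3d(clip_range(out, v$dtype_range), v$spacing, v$dtype_range)
}

#' Estimate the smooth staining background of a stack
#'
#' Grayscale opening (erosion then dilation with a box structuring
#' element) removes thin bright structures such as vessels; a box filter
#' then smooths the opened image into the background reference. Both are
#' computed on a block-mean-downsampled grid with kernels scaled by the
#' same factor, then trilinearly upsampled -- the full-scale kernels of
#' the acquisition pipeline are infeasible naively.
#'
#' @param v a \code{\link{volume3d}}.
#' @param cfg an \code{\link{optimize_config}}.
#' @return The background \code{\link{volume3d}}.
#' @export
estimate_background <- function(v, cfg = optimize_config()) {
  f <- max(1L, cfg$downsample_factor)
  d <- dim(v$voxels)
  small <- if (f > 1) .block_mean(v$voxels, as.integer(c(f, f, f))) else
    v$voxels
  ds <- dim(small)
  ko <- make_odd(pmax(1L, as.integer(round(cfg$opening_kernel / f))))
  kb <- make_odd(pmax(1L, as.integer(round(cfg$boxfilter_kernel / f))))
  ax_names <- c("z", "y", "x")
  for (a in 1:3) {
    if (ko[a] > ds[a] || kb[a] > ds[a])
      stop("background kernel exceeds volume extent along axis ",
           ax_names[a], " (", max(ko[a], kb[a]), " > ", ds[a],
           " voxels on the downsampled grid)")
  }
  bg <- small
  for (a in 1:3) bg <- .box_filter_axis(bg, a - 1L, ko[a], 0L)  # erosion
  for (a in 1:3) bg <- .box_filter_axis(bg, a - 1L, ko[a], 1L)  # dilation
  for (a in 1:3) bg <- .box_filter_axis(bg, a - 1L, kb[a], 2L)  # box mean
  if (f > 1) bg <- .resize3d(bg, as.integer(d))
  volume3d(bg, v$spacing, v$dtype_range)
}

#' Flatten non-uniform brightness against a background reference
#'
#' Subtractive flat-field: \code{v - bg + mean(bg)}, clipped to the dynamic
#' range (keeps absolute vessel-background differences intact). A division
#' mode \code{v / bg * mean(bg)} is available.
#'
#' @param v,bg volumes of identical shape.
#' @param mode \code{"subtract"} or \code{"divide"}.
#' @return The corrected \code{\link{volume3d}}.
#' @export
correct_background <- function(v, bg, mode = c("subtract", "divide")) {
  mode <- match.arg(mode)
  if (!all(dim(v$voxels) == dim(bg$voxels)))
    stop("volume and background shapes differ")
  m <- mean(bg$voxels)
  out <- if (mode == "subtract") v$voxels - bg$voxels + m
         else v$voxels / pmax(bg$voxels, 1e-6) * m
  volume3d(clip_range(out, v$dtype_range), v$spacing, v$dtype_range)
}

#' Edge-preserving denoising with a 3x3x3 bilateral filter
#'
#' Standard bilateral weights: Gaussian in space over the 26-neighbourhood
#' times Gaussian in intensity difference. Constant regions are unchanged;
#' step edges are preserved while plateau noise is averaged down.
#'
#' @param v a \code{\link{volume3d}}.
#' @param sigma_spatial spatial sigma, voxels.
#' @param sigma_range range sigma, gray levels; default 10\% of the
#'   dynamic range.
#' @return The denoised \code{\link{volume3d}}.
#' @export
denoise_bilateral <- function(v, sigma_spatial = 1, sigma_range = NULL) {
  if (is.null(sigma_range))
    sigma_range <- 0.1 * diff(v$dtype_range)
  if (sigma_spatial <= 0 || sigma_range <= 0) stop("sigmas must be > 0")
  volume3d(.bilateral3(v$voxels, sigma_spatial, sigma_range), v$spacing,
           v$dtype_range)
}

#' Linear histogram transform for contrast enhancement
#'
#' Affine map sending the low/high data percentiles to the ends of the
#' dynamic range, clipping outside; strictly monotone between them.
#'
#' @param v a \code{\link{volume3d}}.
#' @param stretch_percentiles (low, high) percentiles.
#' @return The stretched \code{\link{volume3d}}.
#' @export
enhance_contrast <- function(v, stretch_percentiles = c(0.1, 99.9)) {
  q <- quantile(v$voxels, stretch_percentiles / 100, names = FALSE)
  if (q[1] >= q[2])
    stop("degenerate histogram: percentiles ", stretch_percentiles[1],
         " and ", stretch_percentiles[2], " coincide at ", q[1])
  r <- v$dtype_range
  out <- (v$voxels - q[1]) / (q[2] - q[1]) * (r[2] - r[1]) + r[1]
  volume3d(clip_range(out, r), v$spacing, r)
}

#' Full image-optimization chain
#'
#' Applies, in fixed order: stripe baseline correction, background
#' estimation and flat-field correction, bilateral denoising, and linear
#' contrast stretch. Per-stage summary statistics are attached as the
#' \code{"log"} attribute.
#'
#' @param v a \code{\link{volume3d}}.
#' @param cfg an \code{\link{optimize_config}}.
#' @param stages must be the canonical stage order; supplied only to make
#'   the fixed ordering explicit. Any other value is refused.
#' @return The optimized \code{\link{volume3d}} with a \code{"log"}
#'   attribute (data frame of per-stage statistics).
#' @export
optimize_volume <- function(v, cfg = optimize_config(),
                            stages = c("strips", "background", "denoise",
                                       "contrast")) {
  canonical <- c("strips", "background", "denoise", "contrast")
  if (!identical(as.character(stages), canonical))
    stop("the optimization stage order is fixed: ",
         paste(canonical, collapse = " -> "))
  log <- list(stage_stats("input", v))
  v <- correct_strips(v, cfg$strip_axis, cfg$strip_smooth_window)
  log <- c(log, list(stage_stats("strips", v)))
  bg <- estimate_background(v, cfg)
  v <- correct_background(v, bg, cfg$background_mode)
  log <- c(log, list(stage_stats("background", v)))
  v <- denoise_bilateral(v, cfg$bilateral_sigma_spatial,
                         cfg$bilateral_sigma_range)
  log <- c(log, list(stage_stats("denoise", v)))
  v <- enhance_contrast(v, cfg$stretch_percentiles)
  log <- c(log, list(stage_stats("contrast", v)))
  attr(v, "log") <- do.call(rbind, log)
  v
}

stage_stats <- function(stage, v) {
  data.frame(stage = stage, mean = mean(v$voxels), sd = sd(v$voxels),
             min = min(v$voxels), max = max(v$voxels))
}
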