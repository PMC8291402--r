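#' Gray-value vessel extraction
#'
#' Vessels image brighter than all other tissue classes, so extraction is
#' plain gray-value thresholding: \code{mask = v >= threshold}. The
#' threshold and method are recorded in the mask's provenance.
#'
#' @param v a \code{\link{volume3d}} (normally an optimized one; extraction
#'   on raw stacks is permitted but warned about).
#' @param method \code{"otsu"} (between-class variance maximization over
#'   the above-median half of the 256-bin histogram, which isolates the
#'   small bright vessel class from the soma and parenchyma masses),
#'   \code{"fixed"} (absolute gray value) or \code{"percentile"}.
#' @param value threshold gray value (fixed) or percentile in (0, 100).
#' @param warn_raw set \code{FALSE} to silence the raw-input warning.
#' @return A \code{vessel_mask}: binary voxels, spacing, and a
#'   \code{provenance} list (method, threshold).
#' @export
threshold_vessels <- function(v, method = c("otsu", "fixed", "percentile"),
                              value = NULL, warn_raw = TRUE) {
  method <- match.arg(method)
  if (warn_raw && is.null(attr(v, "log")))
    warning("thresholding a volume with no optimization log; ",
            "extraction is intended for optimized stacks", call. = FALSE)
  thr <- switch(method,
    otsu = otsu_threshold(v$voxels),
    fixed = {
      if (is.null(value)) stop("method 'fixed' needs a threshold value")
      value
    },
    percentile = {
      if (is.null(value)) stop("method 'percentile' needs a percentile")
      if (value <= 0 || value >= 100) stop("percentile must be in (0, 100)")
      quantile(v$voxels, value / 100, names = FALSE)
    })
  vessel_mask(array(as.integer(v$voxels >= thr), dim = dim(v$voxels)),
              v$spacing, provenance = list(method = method, threshold = thr))
}

#' Construct a binary vessel mask
#'
#' Wraps a binary voxel array (e.g. a phantom truth mask) in the container
#' used by the extraction and morphometry functions.
#'
#' @param voxels binary 3D array, \code{(z, y, x)} order.
#' @param spacing micrometres per axis.
#' @param provenance free-form list recording how the mask was made.
#' @return An object of class \code{vessel_mask}.
#' @export
vessel_mask <- function(voxels, spacing = c(1, 1, 1), provenance = list()) {
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 provenance = provenance),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("vessel_mask: %s voxels, %d foreground (%.3f%%), method %s @ %s\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              100 * mean(x$voxels),
              x$provenance$method %||% "?",
              format(x$provenance$threshold %||% NA)))
  invisible(x)
}

# Otsu's between-class variance criterion, applied to the upper half of
# the histogram (gray values above the median). Vessels are a small
# (often ~1%) bright class; on the full histogram the variance criterion
# is dominated by the dark soma mass and the broad parenchyma mode and
# settles between them. The lower half of the histogram carries only
# those tissue classes, so restricting to values above the median turns
# the problem back into the two-class one that Otsu's criterion solves;
# on genuinely bimodal background/vessel data the restriction is
# inconsequential (the median sits inside the background mode).
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[x >= median(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("constant volume: no threshold exists")
  h <- tabulate(pmin(nbins, 1L + floor((x - rng[1]) / diff(rng) * nbins)),
                nbins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(nbins) - 0.5) / nbins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b[-nbins])
  rng[1] + k / nbins * diff(rng)   # upper edge of the chosen bin
}

#' Remove small connected components from a vessel mask
#'
#' Drops 26-connected components smaller than \code{min_size_voxels};
#' never adds voxels.
#'
#' @param m a \code{vessel_mask}.
#' @param min_size_voxels minimum component size kept.
#' @return The cleaned \code{vessel_mask}.
#' @export
clean_mask <- function(m, min_size_voxels = 27L) {
  if (min_size_voxels <= 1) return(m)
  lab <- .label26(m$voxels)
  if (max(lab) == 0) return(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size_voxels)
  out <- array(as.integer(lab %in% keep), dim = dim(m$voxels))
  vessel_mask(out, m$spacing,
              c(m$provenance, list(min_size_voxels = min_size_voxels)))
}

#' Local vascular volumetric density
#'
#' \code{mode = "3d"}: mean of the binary mask over a sliding cubic window
#' of side \code{window_um}; windows are cropped at the borders and
#' renormalized. \code{mode = "slab2d"}: per-(row, col) vessel fraction
#' over a slab of thickness \code{slab_um} along \code{axis}.
#'
#' @param m a \code{vessel_mask}.
#' @param window_um window side in micrometres (3d mode).
#' @param mode \code{"3d"} or \code{"slab2d"}.
#' @param slab_um slab thickness, um (slab2d mode; default whole axis).
#' @param axis projection axis for slab2d (1 = z, 2 = y, 3 = x).
#' @param slab_start first slice (1-based) of the slab.
#' @return A \code{density_map}: values in [0, 1] (3D array for
#'   \code{"3d"}, matrix for \code{"slab2d"}), plus window/slab metadata.
#' @export
density_map <- function(m, window_um = 20, mode = c("3d", "slab2d"),
                        slab_um = NULL, axis = 1L, slab_start = 1L) {
  mode <- match.arg(mode)
  d <- dim(m$voxels)
  if (mode == "3d") {
    k <- make_odd(pmax(1L, as.integer(round(window_um / m$spacing))))
    if (any(window_um < m$spacing))
      stop("window smaller than one voxel along at least one axis")
    num <- boxsum_zero(m$voxels, k)
    den <- boxsum_zero(array(1, dim = d), k)
    structure(list(values = num / den, window = window_um, mode = mode,
                   spacing = m$spacing),
              class = "density_map")
  } else {
    nslices <- if (is.null(slab_um)) d[axis]
               else max(1L, round(slab_um / m$spacing[axis]))
    idx <- slab_start:min(d[axis], slab_start + nslices - 1L)
    sl <- switch(axis,
                 m$voxels[idx, , , drop = FALSE],
                 m$voxels[, idx, , drop = FALSE],
                 m$voxels[, , idx, drop = FALSE])
    vals <- apply(sl, setdiff(1:3, axis), mean)
    structure(list(values = vals, window = NA_real_,
                   slab = length(idx) * m$spacing[axis], mode = mode,
                   spacing = m$spacing[setdiff(1:3, axis)]),
              class = "density_map")
  }
}

# separable box SUM with zero padding (for cropped-window renormalization)
boxsum_zero <- function(a, k) {
  d <- dim(a)
  h <- k %/% 2
  big <- array(0, dim = d + 2 * h)
  big[h[1] + seq_len(d[1]), h[2] + seq_len(d[2]), h[3] + seq_len(d[3])] <- a
  for (ax in 1:3) big <- .box_filter_axis(big, ax - 1L, k[ax], 2L) * k[ax]
  big[h[1] + seq_len(d[1]), h[2] + seq_len(d[2]), h[3] + seq_len(d[3])]
}

#' Maximum intensity projection over a slab
#'
#' Per-pixel maximum of the volume over a range of slices along one axis.
#' Commutes with any monotone intensity map.
#'
#' @param v a \code{\link{volume3d}} (or \code{vessel_mask}).
#' @param axis projection axis (1 = z, 2 = y, 3 = x).
#' @param slab_range 1-based slice range \code{c(from, to)}; default all.
#' @return A 2D matrix of projected intensities.
#' @export
mip <- function(v, axis = 1L, slab_range = NULL) {
  a <- v$voxels
  d <- dim(a)
  if (is.null(slab_range)) slab_range <- c(1L, d[axis])
  idx <- slab_range[1]:slab_range[2]
  sl <- switch(axis,
               a[idx, , , drop = FALSE],
               a[, idx, , drop = FALSE],
               a[, , idx, drop = FALSE])
  apply(sl, setdiff(1:3, axis), max)
}
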