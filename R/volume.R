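#' 3D image volume with voxel spacing
#'
#' The carrier type for raw, optimized and background image stacks. Voxels
#' are stored as a numeric 3D array in \code{(z, y, x)} index order; spacing
#' gives the physical voxel size in micrometres per axis, in the same order.
#' World coordinates are in micrometres, with the voxel at index
#' \code{(i, j, k)} centred at \code{((k - 0.5) * sx, (j - 0.5) * sy,
#' (i - 0.5) * sz)}.
#'
#' @param voxels numeric 3D array, \code{(z, y, x)} order.
#' @param spacing micrometres per axis, length 3 \code{(z, y, x)}; all > 0.
#' @param dtype_range representable gray range, default 8-bit \code{c(0, 255)}.
#' @return An object of class \code{volume3d}.
#' @export
volume3d <- function(voxels, spacing = c(1, 1, 1), dtype_range = c(0, 255)) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3D array")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive values (z, y, x)")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 dtype_range = as.numeric(dtype_range)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("volume3d: %d x %d x %d (z,y,x), spacing %s um, range [%g, %g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$voxels)

clip_range <- function(a, rng) {
  a[a < rng[1]] <- rng[1]
  a[a > rng[2]] <- rng[2]
  a
}

#' Read a multi-page TIFF stack as a volume
#'
#' Pages are stacked along z. Gray values are rescaled from the TIFF unit
#' interval back to the integer dynamic range of the file.
#'
#' @param path TIFF file path.
#' @param spacing voxel size in micrometres \code{(z, y, x)}.
#' @return A \code{\link{volume3d}}.
#' @export
read_volume <- function(path, spacing = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits <- attr(pages[[1]], "bits.per.sample") %||% 8
  scale <- 2^bits - 1
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * scale
  volume3d(arr, spacing, dtype_range = c(0, scale))
}

#' Write a volume as a multi-page TIFF stack (z-major)
#'
#' @param v a \code{\link{volume3d}}.
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(v, path, bits = if (v$dtype_range[2] > 255) 16L else 8L) {
  scale <- 2^bits - 1
  d <- dim(v$voxels)
  pages <- lapply(seq_len(d[1]), function(i) {
    p <- v$voxels[i, , ] / scale
    p[p < 0] <- 0
    p[p > 1] <- 1
    p
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Integer label volume naming anatomical compartments
#'
#' @param labels integer 3D array \code{(z, y, x)}; 0 = outside all regions.
#' @param spacing micrometres per axis.
#' @param names named integer vector mapping region names to label values,
#'   e.g. \code{c(Sub = 1, "CA1-2" = 2, CA3 = 3, "DG-ml" = 4)}.
#' @return An object of class \code{region_mask}.
#' @export
region_mask <- function(labels, spacing = c(1, 1, 1), names = NULL) {
  if (length(dim(labels)) != 3) stop("labels must be a 3D array")
  present <- sort(unique(as.integer(labels[labels != 0])))
  if (is.null(names)) names <- setNames(present, paste0("region", present))
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 names = names),
            class = "region_mask")
}

region_label_value <- function(region, label) {
  if (is.character(label)) {
    if (!label %in% names(region$names))
      stop("label '", label, "' not in region mask; available: ",
           paste(names(region$names), collapse = ", "), call. = FALSE)
    region$names[[label]]
  } else as.integer(label)
}
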