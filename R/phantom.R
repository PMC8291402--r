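#' Specification of a synthetic vascular phantom
#'
#' Describes a ground-truthed vascular tree and its rendering into a
#' micro-optical-style image volume: parallel, equally spaced transverse
#' trunk vessels in a rake-like arrangement, hierarchically branching
#' daughters, and (optionally) a comb-like bed of short near-perpendicular
#' capillaries along designated trunks. Gray levels are ordered
#' vessel > process > parenchyma > soma, emulating resin-filled lumina that
#' image brighter than the surrounding Nissl-stained tissue.
#'
#' The tree geometry itself (trunk count, daughter counts, taper, capillary
#' length) is a stand-in: the imaged brains give pattern descriptions, not a
#' generative model, so all distributional choices here are package choices
#' documented in the methods vignette.
#'
#' @param volume_shape voxel counts \code{(z, y, x)}.
#' @param spacing micrometres per voxel \code{(z, y, x)}; the source
#'   instrument samples at 0.35 x 0.35 x 1 um, desk-scale phantoms default
#'   to isotropic 1 um.
#' @param trunk_radius trunk vessel radius, um.
#' @param trunk_spacing distance between neighbouring trunks, um.
#' @param n_branch_levels number of branching generations below the trunks
#'   (0 = unbranched trunks).
#' @param radius_decay child/parent radius ratio per generation, in (0, 1).
#' @param branch_angle_mean,branch_angle_sd normal law (degrees) for the
#'   divergence angle of a child from its parent's continuation; draws are
#'   clipped to (5, 90).
#' @param comb_mode add short perpendicular (80--90 degree) capillaries of
#'   sub-10-um diameter along the last trunk, emulating the comb-like
#'   capillary bed of the dentate-gyrus molecular layer.
#' @param diameter_scale,angle_scale group-effect multipliers in (0, 1];
#'   1 is wild-type-like, below 1 emulates the disease-model reductions.
#'   \code{diameter_scale} rescales all radii once, globally, so the
#'   measured mean-diameter ratio between two cohorts tracks the parameter.
#' @param intensity_levels named gray values for \code{vessel}, \code{process},
#'   \code{parenchyma}, \code{soma}; must be strictly decreasing in that order.
#' @param soma_density dark soma blobs per mm^3.
#' @param seed integer RNG seed; every derived quantity is a pure function
#'   of (spec, seed).
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(volume_shape = c(64, 128, 128),
                         spacing = c(1, 1, 1),
                         trunk_radius = 3.2,
                         trunk_spacing = 40,
                         n_branch_levels = 3,
                         radius_decay = 0.68,
                         branch_angle_mean = 40,
                         branch_angle_sd = 8,
                         comb_mode = TRUE,
                         diameter_scale = 1,
                         angle_scale = 1,
                         intensity_levels = c(vessel = 200, process = 120,
                                              parenchyma = 100, soma = 40),
                         soma_density = 1e5,
                         seed = 1L) {
  spec <- list(volume_shape = as.integer(volume_shape),
               spacing = as.numeric(spacing),
               trunk_radius = trunk_radius, trunk_spacing = trunk_spacing,
               n_branch_levels = as.integer(n_branch_levels),
               radius_decay = radius_decay,
               branch_angle_mean = branch_angle_mean,
               branch_angle_sd = branch_angle_sd,
               comb_mode = isTRUE(comb_mode),
               diameter_scale = diameter_scale, angle_scale = angle_scale,
               intensity_levels = intensity_levels,
               soma_density = soma_density, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  stopifnot(length(s$volume_shape) == 3, all(s$volume_shape >= 1),
            length(s$spacing) == 3, all(s$spacing > 0))
  if (s$trunk_radius <= 0) stop("trunk_radius must be > 0")
  if (s$radius_decay <= 0 || s$radius_decay >= 1)
    stop("radius_decay must be in (0, 1)")
  if (s$diameter_scale <= 0 || s$diameter_scale > 1 ||
      s$angle_scale <= 0 || s$angle_scale > 1)
    stop("diameter_scale and angle_scale must be in (0, 1]")
  il <- s$intensity_levels
  need <- c("vessel", "process", "parenchyma", "soma")
  if (!all(need %in% names(il))) stop("intensity_levels must name ",
                                      paste(need, collapse = ", "))
  if (!(il["vessel"] > il["process"] && il["process"] > il["parenchyma"] &&
        il["parenchyma"] > il["soma"]))
    stop("intensity ordering vessel > process > parenchyma > soma violated")
  invisible(s)
}

#' Imaging-artifact specification
#'
#' Models the two artifact classes of micro-optical serial-sectioning
#' stacks -- periodic stripe noise from uneven illumination and a smooth
#' staining-inhomogeneity background -- plus i.i.d. sensor noise.
#'
#' @param strip_amplitude sinusoidal stripe amplitude, gray levels.
#' @param strip_period stripe period in voxels (>= 2).
#' @param strip_axis axis the stripes vary along (1 = z, 2 = y, 3 = x).
#' @param background_amplitude peak amplitude of the smooth random
#'   background field, gray levels.
#' @param background_length_scale correlation length of the background, um.
#' @param noise_sd Gaussian noise standard deviation, gray levels.
#' @param seed RNG seed; each artifact class uses an independent substream
#'   so toggling one class does not change the others.
#' @return An object of class \code{artifact_spec}.
#' @export
artifact_spec <- function(strip_amplitude = 20, strip_period = 16,
                          strip_axis = 2,
                          background_amplitude = 30,
                          background_length_scale = 64,
                          noise_sd = 5, seed = 1L) {
  if (strip_amplitude < 0 || background_amplitude < 0 || noise_sd < 0)
    stop("artifact amplitudes must be >= 0")
  if (strip_period < 2) stop("strip_period must be >= 2 voxels")
  structure(list(strip_amplitude = strip_amplitude,
                 strip_period = strip_period,
                 strip_axis = as.integer(strip_axis),
                 background_amplitude = background_amplitude,
                 background_length_scale = background_length_scale,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "artifact_spec")
}

#' Generate a ground-truth vascular tree
#'
#' Deterministically (given \code{spec$seed}) grows parallel, equally spaced
#' trunk segments along the x axis and, below them, \code{n_branch_levels}
#' generations of straight daughter branches. Each daughter leaves its
#' parent at an angle drawn from
#' \code{Normal(branch_angle_mean * angle_scale, branch_angle_sd)}, clipped
#' to (5, 90) degrees, with uniform azimuth; its radius is the parent radius
#' times \code{radius_decay}. With \code{comb_mode}, the last trunk also
#' carries a comb of short (20--60 um) capillaries leaving at 80--90
#' degrees. The whole tree is clipped to the volume bounds.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return A \code{vessel_tree}: list with \code{nodes} (data frame: id,
#'   x, y, z, parent) and \code{segments} (list of id, parent segment id,
#'   branch level, centerline \code{points} (n x 3 um, columns x, y, z) and
#'   per-point \code{radius} (um)).
#' @export
generate_tree <- function(spec) {
  validate_phantom_spec(spec)
  ext <- rev(spec$volume_shape * spec$spacing)   # (x, y, z) um
  margin <- spec$trunk_radius + 2
  if (ext[1] < 4 * spec$trunk_radius || ext[3] < 2 * (spec$trunk_radius + 1) ||
      ext[2] < 2 * (spec$trunk_radius + 1))
    stop("volume too small to contain one trunk of radius ",
         spec$trunk_radius, " um")
  set.seed(spec$seed)

  step <- 2
  r_trunk <- spec$trunk_radius * spec$diameter_scale

  # equally spaced trunks along x, spread over y, at mid z
  ymar <- max(margin, 10)
  n_trunk <- max(1L, floor((ext[2] - 2 * ymar) / spec$trunk_spacing) + 1L)
  span <- (n_trunk - 1) * spec$trunk_spacing
  y0 <- (ext[2] - span) / 2
  zmid <- ext[3] / 2

  segments <- list()
  next_id <- 1L
  add_segment <- function(points, radius, parent, level) {
    seg <- list(id = next_id, parent = parent, level = level,
                points = points, radius = radius)
    segments[[next_id]] <<- seg
    next_id <<- next_id + 1L
    seg$id
  }

  clip_polyline <- function(P, r) {
    # keep the leading run of points at least (r + 0.5) um inside the bounds
    m <- r + 0.5
    ok <- P[, 1] >= m & P[, 1] <= ext[1] - m &
          P[, 2] >= m & P[, 2] <= ext[2] - m &
          P[, 3] >= m & P[, 3] <= ext[3] - m
    n <- if (all(ok)) nrow(P) else which(!ok)[1] - 1L
    if (n < 2) return(NULL)
    P[seq_len(n), , drop = FALSE]
  }

  trunk_ids <- integer(0)
  trunk_y <- y0 + (seq_len(n_trunk) - 1) * spec$trunk_spacing
  for (tk in seq_len(n_trunk)) {
    xs <- seq(margin, ext[1] - margin, by = step)
    P <- cbind(xs, trunk_y[tk], zmid)
    # mild taper along the trunk
    R <- seq(r_trunk, 0.9 * r_trunk, length.out = nrow(P))
    id <- add_segment(P, R, NA_integer_, 1L)
    trunk_ids <- c(trunk_ids, id)
  }

  # transverse vessels supply disjoint territories and do not anastomose:
  # every branch of a trunk's subtree stays within the trunk's half-spacing
  # slab, so subtrees of neighbouring trunks can never fuse
  truncate_at_trunks <- function(P, r, own_trunk) {
    if (n_trunk < 2) return(P)
    half <- spec$trunk_spacing / 2
    keep <- abs(P[, 2] - trunk_y[own_trunk]) < half - r - 0.5
    n <- if (all(keep)) nrow(P) else which(!keep)[1] - 1L
    if (n < 2) return(NULL)
    P[seq_len(n), , drop = FALSE]
  }

  draw_angle <- function() {
    a <- rnorm(1, spec$branch_angle_mean * spec$angle_scale,
               spec$branch_angle_sd)
    min(90, max(5, a))
  }

  root_trunk <- integer(0)   # index of the trunk each segment descends from
  root_trunk[trunk_ids] <- seq_along(trunk_ids)

  # vascular trees are self-avoiding: track placed centerline samples so a
  # new branch is truncated before touching any vessel other than its
  # parent (clearance = sum of radii + 0.8 um)
  placed_P <- do.call(rbind, lapply(trunk_ids,
                                    function(id) segments[[id]]$points))
  placed_r <- unlist(lapply(trunk_ids, function(id) segments[[id]]$radius))
  placed_seg <- rep(trunk_ids, vapply(trunk_ids, function(id)
    nrow(segments[[id]]$points), integer(1)))

  truncate_at_vessels <- function(C, r, parent_id) {
    if (is.null(placed_P) || !nrow(placed_P)) return(C)
    use <- placed_seg != parent_id
    if (!any(use)) return(C)
    Q <- placed_P[use, , drop = FALSE]
    thr <- placed_r[use] + r + 0.8
    ok <- vapply(seq_len(nrow(C)), function(k) {
      d2 <- (Q[, 1] - C[k, 1])^2 + (Q[, 2] - C[k, 2])^2 +
        (Q[, 3] - C[k, 3])^2
      all(d2 > thr^2)
    }, logical(1))
    n <- if (all(ok)) nrow(C) else which(!ok)[1] - 1L
    if (n < 2) return(NULL)
    C[seq_len(n), , drop = FALSE]
  }

  sprout <- function(parent, t_arc, theta_deg, length_um, radius_um,
                     psi = NULL) {
    P <- parent$points
    arc <- polyline_arclength(P)
    i <- which(arc >= t_arc)[1]
    if (is.na(i) || i < 2) i <- nrow(P)
    origin <- P[i, ]
    tang <- P[i, ] - P[i - 1, ]
    tang <- tang / sqrt(sum(tang^2))
    b <- perp_basis(tang)
    if (is.null(psi)) psi <- runif(1, 0, 2 * pi)
    th <- theta_deg * pi / 180
    dirn <- cos(th) * tang + sin(th) * (cos(psi) * b$u + sin(psi) * b$v)
    n_pts <- max(2L, ceiling(length_um / step) + 1L)
    s <- seq(0, length_um, length.out = n_pts)
    C <- cbind(origin[1] + s * dirn[1], origin[2] + s * dirn[2],
               origin[3] + s * dirn[3])
    C <- clip_polyline(C, radius_um)
    if (!is.null(C))
      C <- truncate_at_trunks(C, radius_um, root_trunk[parent$id])
    if (!is.null(C))
      C <- truncate_at_vessels(C, radius_um, parent$id)
    if (is.null(C)) return(NULL)
    R <- seq(radius_um, 0.9 * radius_um, length.out = nrow(C))
    id <- add_segment(C, R, parent$id, parent$level + 1L)
    root_trunk[id] <<- root_trunk[parent$id]
    placed_P <<- rbind(placed_P, C)
    placed_r <<- c(placed_r, R)
    placed_seg <<- c(placed_seg, rep(id, nrow(C)))
    id
  }

  if (spec$n_branch_levels > 0) {
    frontier <- trunk_ids
    base_len <- 34
    for (lev in seq_len(spec$n_branch_levels)) {
      new_frontier <- integer(0)
      for (pid in frontier) {
        parent <- segments[[pid]]
        arc <- polyline_arclength(parent$points)
        total <- arc[length(arc)]
        if (parent$level == 1L) {
          ts <- seq(0.12, 0.95, length.out = max(2, floor(total / 18)))
          ts <- ts * total + runif(length(ts), -3, 3)
        } else {
          # daughters at regularly spaced, jittered positions so junctions
          # stay separated (regular hierarchical branching)
          nc <- max(1L, min(3L, floor(total / 12)))
          ts <- seq(0.3, 0.92, length.out = nc + 1)[-1] * total +
            runif(nc, -2, 2)
        }
        child_len <- base_len * 0.62^(lev - 1)
        child_rad <- parent$radius[1] * spec$radius_decay
        if (child_rad < 0.25) next
        for (ci in seq_along(ts)) {
          # trunk daughters alternate dorsal/ventral sides (branches leave
          # the transverse vessels from both sides), which also keeps
          # neighbouring junction mouths apart
          psi <- if (parent$level == 1L)
            (ci %% 2) * pi + pi / 2 + runif(1, -1, 1) * pi / 3 else NULL
          cid <- sprout(parent, ts[ci], draw_angle(),
                        child_len * runif(1, 0.8, 1.2), child_rad, psi)
          if (!is.null(cid)) new_frontier <- c(new_frontier, cid)
        }
      }
      frontier <- new_frontier
      if (!length(frontier)) break
    }
  }

  if (spec$comb_mode && length(trunk_ids)) {
    comb_trunk <- segments[[trunk_ids[length(trunk_ids)]]]
    arc <- polyline_arclength(comb_trunk$points)
    total <- arc[length(arc)]
    r_comb <- 0.8 * spec$diameter_scale
    for (t_arc in seq(4, total - 4, by = 6)) {
      sprout(comb_trunk, t_arc, runif(1, 80, 90), runif(1, 20, 60), r_comb)
    }
  }

  nodes <- do.call(rbind, lapply(segments, function(s) {
    data.frame(id = s$id, x = s$points[1, 1], y = s$points[1, 2],
               z = s$points[1, 3], parent = s$parent)
  }))
  structure(list(nodes = nodes, segments = segments),
            class = "vessel_tree", spec = spec)
}

#' @export
print.vessel_tree <- function(x, ...) {
  lv <- vapply(x$segments, `[[`, integer(1), "level")
  cat(sprintf("vessel_tree: %d segments, levels 1..%d (%s)\n",
              length(x$segments), max(lv),
              paste(tabulate(lv), collapse = ", ")))
  invisible(x)
}

#' Rasterize a vessel tree into an image volume and truth mask
#'
#' A voxel is vessel iff its center lies within the local (linearly
#' tapered) radius of any centerline segment -- a union of sphere-swept
#' capsules, so joints cannot open gaps. The clean volume renders vessels
#' bright on a parenchyma background with dark soma ellipsoids (radii
#' 3--8 um, Poisson-placed outside vessels); the truth mask marks exactly
#' the vessel voxels.
#'
#' @param tree a \code{vessel_tree}.
#' @param spec the generating \code{\link{phantom_spec}} (defaults to the
#'   one attached to the tree); provides shape, spacing, gray levels and
#'   soma density.
#' @param shape,spacing override the output grid.
#' @return list with \code{clean} (\code{\link{volume3d}}) and
#'   \code{truth_mask} (binary \code{volume3d}).
#' @export
rasterize <- function(tree, spec = attr(tree, "spec"),
                      shape = spec$volume_shape, spacing = spec$spacing) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  P <- do.call(rbind, lapply(tree$segments, `[[`, "points"))
  R <- unlist(lapply(tree$segments, `[[`, "radius"))
  starts <- cumsum(c(1L, vapply(tree$segments, function(s) nrow(s$points),
                                integer(1))))
  starts <- starts[-length(starts)]
  dimv <- as.integer(shape)
  if (length(tree$segments)) {
    mask <- .rasterize_capsules(dimv, as.numeric(spacing), P, R,
                                as.integer(starts))
  } else {
    mask <- array(0L, dim = dimv)
  }
  il <- spec$intensity_levels
  vox <- array(as.numeric(il["parenchyma"]), dim = dimv)

  # dark somata: Poisson-placed ellipsoids outside the vessels
  if (spec$soma_density > 0) {
    set.seed(spec$seed + 7L)
    ext <- rev(dimv * spacing)
    vol_mm3 <- prod(ext) * 1e-9
    n_soma <- rpois(1, spec$soma_density * vol_mm3)
    for (i in seq_len(n_soma)) {
      ctr <- c(runif(1, 0, ext[1]), runif(1, 0, ext[2]), runif(1, 0, ext[3]))
      rad <- runif(3, 3, 8)   # (x, y, z) semi-axes
      iv <- pmin(dimv, pmax(1L, ceiling(rev(ctr) / spacing)))
      if (mask[iv[1], iv[2], iv[3]]) next
      xr <- pmax(1L, floor((ctr[1] - rad[1]) / spacing[3])):
            pmin(dimv[3], ceiling((ctr[1] + rad[1]) / spacing[3]))
      yr <- pmax(1L, floor((ctr[2] - rad[2]) / spacing[2])):
            pmin(dimv[2], ceiling((ctr[2] + rad[2]) / spacing[2]))
      zr <- pmax(1L, floor((ctr[3] - rad[3]) / spacing[1])):
            pmin(dimv[1], ceiling((ctr[3] + rad[3]) / spacing[1]))
      cx <- (xr - 0.5) * spacing[3]
      cy <- (yr - 0.5) * spacing[2]
      cz <- (zr - 0.5) * spacing[1]
      dx2 <- ((cx - ctr[1]) / rad[1])^2
      dy2 <- ((cy - ctr[2]) / rad[2])^2
      dz2 <- ((cz - ctr[3]) / rad[3])^2
      inside <- outer(outer(dz2, dy2, `+`), dx2, `+`) <= 1
      sub <- vox[zr, yr, xr, drop = FALSE]
      msub <- mask[zr, yr, xr, drop = FALSE]
      sub[inside & msub == 0] <- as.numeric(il["soma"])
      vox[zr, yr, xr] <- sub
    }
  }
  vox[mask == 1] <- as.numeric(il["vessel"])
  rng <- c(0, max(255, max(il)))
  list(clean = volume3d(vox, spacing, dtype_range = rng),
       truth_mask = volume3d(array(as.integer(mask), dim = dimv), spacing,
                             dtype_range = c(0, 1)))
}

#' Degrade a clean volume with imaging artifacts
#'
#' Adds, in order: (i) a sinusoidal stripe field varying along
#' \code{strip_axis} and constant along the others; (ii) a smooth random
#' background (white noise on a coarse grid at the background length scale,
#' trilinearly interpolated, scaled to the requested peak amplitude);
#' (iii) i.i.d. Gaussian noise. The result is clipped to the volume's
#' dynamic range. Each class draws from its own seeded substream.
#'
#' @param volume a \code{\link{volume3d}}.
#' @param art an \code{\link{artifact_spec}}.
#' @return The degraded \code{\link{volume3d}}.
#' @export
degrade <- function(volume, art) {
  v <- volume$voxels
  d <- dim(v)
  if (art$strip_amplitude > 0) {
    i <- seq_len(d[art$strip_axis])
    prof <- art$strip_amplitude * sin(2 * pi * (i - 1) / art$strip_period)
    v <- sweep(v, art$strip_axis, prof, `+`)
  }
  if (art$background_amplitude > 0) {
    set.seed(art$seed + 1L)
    ext <- volume$spacing * d
    cd <- pmax(2L, as.integer(ceiling(ext / art$background_length_scale)) + 1L)
    coarse <- array(rnorm(prod(cd)), dim = cd)
    field <- .resize3d(coarse, as.integer(d))
    field <- field / max(abs(field)) * art$background_amplitude
    v <- v + field
  }
  if (art$noise_sd > 0) {
    set.seed(art$seed + 2L)
    v <- v + array(rnorm(length(v), 0, art$noise_sd), dim = d)
  }
  volume3d(clip_range(v, volume$dtype_range), volume$spacing,
           volume$dtype_range)
}

#' Analytic morphometry of a generative tree
#'
#' Computes the morphometric report directly from the stored centerlines
#' and radii -- summed polyline length, summed conical-frustum volume,
#' length-weighted mean diameter -- without any imaging, rasterization or
#' skeletonization. Serves as the ground-truth counterpart of
#' \code{\link{region_morphometry}}.
#'
#' @param tree a \code{vessel_tree}.
#' @param region optional \code{\link{region_mask}}; with \code{label},
#'   restricts the analysis to one labelled compartment.
#' @param label region label (name or integer) when \code{region} is given.
#' @param shape,spacing analysis frame when no region mask is supplied.
#' @return A \code{morphometry_report} (see \code{\link{region_morphometry}}).
#' @export
true_morphometry <- function(tree, region = NULL, label = NULL,
                             shape = attr(tree, "spec")$volume_shape,
                             spacing = attr(tree, "spec")$spacing) {
  if (!is.null(region)) {
    spacing <- region$spacing
    shape <- dim(region$labels)
    lab <- region_label_value(region, label)
    inreg <- function(P) {
      iv <- cbind(pmin(shape[1], pmax(1, ceiling(P[, 3] / spacing[1]))),
                  pmin(shape[2], pmax(1, ceiling(P[, 2] / spacing[2]))),
                  pmin(shape[3], pmax(1, ceiling(P[, 1] / spacing[3]))))
      region$labels[iv] == lab
    }
    region_voxels <- sum(region$labels == lab)
    if (region_voxels == 0)
      return(morphometry_report(region = as.character(label), empty = TRUE))
    V_um3 <- region_voxels * prod(spacing)
    rname <- as.character(label)
  } else {
    inreg <- function(P) rep(TRUE, nrow(P))
    V_um3 <- prod(shape) * prod(spacing)
    rname <- "whole"
  }

  total_len <- 0; total_vol <- 0; wsum_d <- 0; max_d <- 0
  seg_mean_d <- numeric(0)
  for (s in tree$segments) {
    P <- s$points; R <- s$radius
    if (nrow(P) < 2) next
    mid <- (P[-1, , drop = FALSE] + P[-nrow(P), , drop = FALSE]) / 2
    keep <- inreg(mid)
    if (!any(keep)) next
    ds <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
    r0 <- R[-length(R)]; r1 <- R[-1]
    frus <- pi / 3 * ds * (r0^2 + r0 * r1 + r1^2)
    rmid <- (r0 + r1) / 2
    total_len <- total_len + sum(ds[keep])
    total_vol <- total_vol + sum(frus[keep])
    wsum_d <- wsum_d + sum(2 * rmid[keep] * ds[keep])
    max_d <- max(max_d, 2 * max(R))
    seg_mean_d <- c(seg_mean_d,
                    sum(2 * rmid[keep] * ds[keep]) / sum(ds[keep]))
  }
  morphometry_report(
    region = rname,
    mean_diameter = if (total_len > 0) wsum_d / total_len else NA_real_,
    length_density = total_len / V_um3 * 1e3,
    volume_fraction = 100 * total_vol / V_um3,
    max_diameter = max_d,
    segment_mean_diameters = seg_mean_d,
    total_length = total_len,
    empty = total_len == 0)
}
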