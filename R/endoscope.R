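#' Iso-surface mesh of a vessel mask
#'
#' Marching tetrahedra at level 0.5 of the (optionally Gaussian-smoothed)
#' binary field, on the Freudenthal cube decomposition, scaled to
#' micrometres. Triangles are oriented so normals point outward (total
#' signed volume positive); per-vertex normals are area-weighted averages
#' of the incident face normals.
#'
#' @param m a \code{vessel_mask} (or binary \code{\link{volume3d}}).
#' @param smoothing_iters passes of a small Gaussian (sigma 0.8 voxel)
#'   applied to the binary field before meshing; if smoothing would erase
#'   the structure entirely (tiny masks), the unsmoothed field is used.
#' @return A \code{surface_mesh}: \code{vertices} (n x 3 um),
#'   \code{triangles} (m x 3, 1-based), \code{normals} (outward unit),
#'   \code{scalar} (per-vertex lumen distance, once computed).
#' @export
mesh_vessel <- function(m, smoothing_iters = 2L) {
  if (sum(m$voxels) == 0) stop("empty mask: nothing to mesh")
  field <- array(as.numeric(m$voxels != 0), dim = dim(m$voxels))
  if (smoothing_iters > 0) {
    kern <- gauss_kernel(0.8)
    sm <- field
    for (i in seq_len(smoothing_iters))
      for (a in 1:3) sm <- .conv_axis(sm, a - 1L, kern)
    if (max(sm) > 0.5) field <- sm
  }
  mc <- .march_tets(field, m$spacing, 0.5)
  V <- mc$vertices
  Tr <- mc$triangles
  if (nrow(Tr) == 0) stop("no iso-surface at level 0.5")
  if (mesh_signed_volume(V, Tr) < 0) Tr <- Tr[, c(1, 3, 2), drop = FALSE]
  structure(list(vertices = V, triangles = Tr,
                 normals = vertex_normals(V, Tr), scalar = NULL),
            class = "surface_mesh")
}

gauss_kernel <- function(sigma, radius = 2L) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Signed enclosed volume of a triangulated surface
#'
#' Divergence-theorem sum over triangles; positive for a closed,
#' outward-oriented surface.
#'
#' @param V vertices (n x 3), or a \code{surface_mesh} (then \code{Tr} is
#'   ignored).
#' @param Tr triangles (m x 3, 1-based).
#' @return Volume in cubic micrometres.
#' @export
mesh_signed_volume <- function(V, Tr = NULL) {
  if (inherits(V, "surface_mesh")) { Tr <- V$triangles; V <- V$vertices }
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  c_ <- V[Tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

vertex_normals <- function(V, Tr) {
  N <- matrix(0, nrow(V), 3)
  e1 <- V[Tr[, 2], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  e2 <- V[Tr[, 3], , drop = FALSE] - V[Tr[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted
  for (j in 1:3) for (k in 1:3) {
    acc <- rowsum(fn[, k], Tr[, j])
    ids <- as.integer(rownames(acc))
    N[ids, k] <- N[ids, k] + acc
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}

#' Per-vertex lumen-distance scalar field by inward ray casting
#'
#' For each vertex, a ray is cast from the vertex along the inward normal
#' (minus the outward vertex normal); the scalar is the distance to its
#' first intersection with any triangle of the same mesh, excluding the
#' vertex's own incident triangles and hits closer than \code{eps_um}.
#' On tubular surfaces this wall-to-wall distance approximates the local
#' lumen diameter. Vertices whose ray hits nothing within
#' \code{max_ray_um} receive \code{NA} (exported as a negative sentinel).
#'
#' @param mesh an oriented \code{surface_mesh}.
#' @param max_ray_um maximum ray length, um.
#' @param eps_um minimum travel before a hit counts, um.
#' @return The mesh with \code{scalar} filled in.
#' @export
normal_distance_field <- function(mesh, max_ray_um = 200, eps_um = 0.25) {
  if (is.null(mesh$normals)) stop("mesh has no normals (unoriented)")
  dirs <- -mesh$normals
  mesh$scalar <- .ray_self_distance(mesh$vertices, mesh$triangles, dirs,
                                    eps_um, max_ray_um)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, volume %.1f um^3%s\n",
              nrow(x$vertices), nrow(x$triangles),
              mesh_signed_volume(x),
              if (!is.null(x$scalar))
                sprintf(", scalar median %.2f um",
                        median(x$scalar, na.rm = TRUE)) else ""))
  invisible(x)
}

#' Centerline camera path for a virtual lumen flythrough
#'
#' Concatenates a connected chain of graph segments, resamples the
#' centerline at \code{step_um}, smooths it with a moving average, and
#' builds per-pose frames: the view direction is the unit tangent and the
#' up vector is propagated by parallel transport (double-reflection
#' minimal-rotation frames, so no roll flips accumulate). If a mask is
#' supplied, each pose is flagged for being strictly inside the lumen.
#'
#' @param g a \code{vessel_graph}.
#' @param chain segment ids forming a connected chain, in order.
#' @param step_um pose spacing along the path, um.
#' @param smooth_window_um moving-average window, um.
#' @param mask optional \code{vessel_mask} for the inside-lumen flag.
#' @return A \code{camera_path}: data frame with position (x, y, z),
#'   view and up unit vectors, arc-length parameter, and (optionally)
#'   an \code{inside} flag.
#' @export
camera_path <- function(g, chain, step_um = 2, smooth_window_um = 8,
                        mask = NULL) {
  segs <- g$segments[chain]
  P <- segs[[1]]$points
  tail_node <- segs[[1]]$node_to
  head_node <- segs[[1]]$node_from
  if (length(segs) > 1) {
    nxt <- segs[[2]]
    if (head_node %in% c(nxt$node_from, nxt$node_to) &&
        !tail_node %in% c(nxt$node_from, nxt$node_to)) {
      P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
      tail_node <- head_node
    }
  }
  for (s in segs[-1]) {
    if (s$node_from == tail_node) {
      P <- rbind(P, s$points[-1, , drop = FALSE])
      tail_node <- s$node_to
    } else if (s$node_to == tail_node) {
      rp <- s$points[rev(seq_len(nrow(s$points))), , drop = FALSE]
      P <- rbind(P, rp[-1, , drop = FALSE])
      tail_node <- s$node_from
    } else {
      stop("chain is not connected at segment ", s$id)
    }
  }
  P <- resample_polyline(P, step_um)
  w <- max(1L, make_odd(round(smooth_window_um / step_um)))
  if (w > 1 && nrow(P) > w) {
    for (j in 1:3) {
      sm <- stats::filter(P[, j], rep(1 / w, w), sides = 2)
      keep <- !is.na(sm)
      P[keep, j] <- sm[keep]
    }
  }
  n <- nrow(P)
  if (n < 2) stop("path too short for a camera trajectory")
  # tangents: central differences
  Tg <- (P[pmin(n, seq_len(n) + 1), , drop = FALSE] -
         P[pmax(1, seq_len(n) - 1), , drop = FALSE])
  Tg <- Tg / pmax(sqrt(rowSums(Tg^2)), 1e-12)
  # parallel transport of the up vector (double-reflection method)
  U <- matrix(0, n, 3)
  U[1, ] <- perp_basis(Tg[1, ])$u
  for (i in seq_len(n - 1)) {
    v1 <- P[i + 1, ] - P[i, ]
    c1 <- sum(v1 * v1)
    rL <- if (c1 > 1e-15) U[i, ] - (2 / c1) * sum(v1 * U[i, ]) * v1 else U[i, ]
    tL <- if (c1 > 1e-15) Tg[i, ] - (2 / c1) * sum(v1 * Tg[i, ]) * v1 else
      Tg[i, ]
    v2 <- Tg[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    u2 <- if (c2 > 1e-15) rL - (2 / c2) * sum(v2 * rL) * v2 else rL
    # re-orthogonalize against the tangent
    u2 <- u2 - sum(u2 * Tg[i + 1, ]) * Tg[i + 1, ]
    U[i + 1, ] <- u2 / sqrt(sum(u2^2))
  }
  arc <- polyline_arclength(P)
  out <- data.frame(x = P[, 1], y = P[, 2], z = P[, 3],
                    vx = Tg[, 1], vy = Tg[, 2], vz = Tg[, 3],
                    ux = U[, 1], uy = U[, 2], uz = U[, 3],
                    arclength = arc)
  if (!is.null(mask)) {
    d <- dim(mask$voxels); sp <- mask$spacing
    iz <- pmin(d[1], pmax(1, ceiling(P[, 3] / sp[1])))
    iy <- pmin(d[2], pmax(1, ceiling(P[, 2] / sp[2])))
    ix <- pmin(d[3], pmax(1, ceiling(P[, 1] / sp[3])))
    out$inside <- mask$voxels[cbind(iz, iy, ix)] != 0
  }
  class(out) <- c("camera_path", "data.frame")
  out
}

#' Export an endoscopy bundle (mesh + poses + manifest)
#'
#' Writes the mesh as binary little-endian PLY with a per-vertex float
#' property \code{lumen_distance} (no-hit sentinel -1), the camera poses
#' as CSV, and a JSON manifest. Byte-stable across runs on identical
#' inputs.
#'
#' @param mesh a \code{surface_mesh} (scalar field optional).
#' @param path a \code{camera_path}.
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
export_endoscopy <- function(mesh, path, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mesh_file <- file.path(out_dir, "vessel_mesh.ply")
  pose_file <- file.path(out_dir, "camera_path.csv")
  manifest_file <- file.path(out_dir, "manifest.json")
  write_ply(mesh, mesh_file)
  pose_df <- as.data.frame(path)
  write.csv(pose_df, pose_file, row.names = FALSE)
  manifest <- list(
    mesh = basename(mesh_file),
    poses = basename(pose_file),
    n_vertices = nrow(mesh$vertices),
    n_triangles = nrow(mesh$triangles),
    n_poses = nrow(pose_df),
    path_length_um = max(path$arclength),
    scalar = !is.null(mesh$scalar),
    no_hit_sentinel = -1)
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(mesh = mesh_file, poses = pose_file, manifest = manifest_file))
}

write_ply <- function(mesh, file) {
  nV <- nrow(mesh$vertices); nT <- nrow(mesh$triangles)
  has_scalar <- !is.null(mesh$scalar)
  con <- file(file, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           paste("element vertex", nV),
           "property float x", "property float y", "property float z",
           "property float nx", "property float ny", "property float nz",
           if (has_scalar) "property float lumen_distance",
           paste("element face", nT),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con, sep = "\n")
  scalar <- if (has_scalar) ifelse(is.na(mesh$scalar), -1, mesh$scalar)
  vdat <- cbind(mesh$vertices, mesh$normals, if (has_scalar) scalar)
  writeBin(as.numeric(t(vdat)), con, size = 4, endian = "little")
  for (i in seq_len(nT)) {
    writeBin(as.integer(3), con, size = 1)
    writeBin(as.integer(mesh$triangles[i, ] - 1L), con, size = 4,
             endian = "little")
  }
  invisible(file)
}

#' Read back a PLY mesh written by \code{\link{export_endoscopy}}
#'
#' @param file PLY file path.
#' @return A \code{surface_mesh}.
#' @export
read_ply <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, 1)
    hdr <- c(hdr, ln)
    if (ln == "end_header") break
  }
  nV <- as.integer(sub("element vertex ", "", grep("element vertex", hdr,
                                                   value = TRUE)))
  nT <- as.integer(sub("element face ", "", grep("element face", hdr,
                                                 value = TRUE)))
  has_scalar <- any(grepl("lumen_distance", hdr))
  ncol <- 6L + has_scalar
  vdat <- matrix(readBin(con, "numeric", nV * ncol, size = 4,
                         endian = "little"),
                 ncol = ncol, byrow = TRUE)
  Tr <- matrix(0L, nT, 3)
  for (i in seq_len(nT)) {
    readBin(con, "integer", 1, size = 1)
    Tr[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
  }
  scalar <- if (has_scalar) { s <- vdat[, 7]; s[s < 0] <- NA; s }
  structure(list(vertices = vdat[, 1:3, drop = FALSE], triangles = Tr,
                 normals = vdat[, 4:6, drop = FALSE], scalar = scalar),
            class = "surface_mesh")
}
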