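# geometric fixture builders shared across the test files; everything is
# generated in code so the suite carries no binary data

# flat-ended cylinder along x, axis through a voxel center
cylinder_mask <- function(r = 3, length_um = 200, dims = c(64L, 64L, 256L),
                          center = c(32.5, 32.5), x0 = NULL) {
  if (is.null(x0)) x0 <- (dims[3] - length_um) / 2
  z <- (seq_len(dims[1]) - 0.5)
  y <- (seq_len(dims[2]) - 0.5)
  x <- (seq_len(dims[3]) - 0.5)
  rad2 <- outer((z - center[2])^2, (y - center[1])^2, `+`)
  inx <- x >= x0 & x <= x0 + length_um
  arr <- array(0L, dim = dims)
  disk <- rad2 <= r^2
  for (k in which(inx)) arr[, , k][disk] <- 1L
  vessel_mask(arr, c(1, 1, 1))
}

# capsule-rasterized tube from an explicit polyline
polyline_mask <- function(points, radii, dims, spacing = c(1, 1, 1)) {
  starts <- attr(points, "starts") %||% 1L
  arr <- vascmorph:::.rasterize_capsules(as.integer(dims),
                                         as.numeric(spacing),
                                         points, radii,
                                         as.integer(starts))
  vessel_mask(array(arr, dims), spacing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetric Y junction: trunk along +x, two children at +-theta in the
# xy plane
y_junction_mask <- function(theta_deg, trunk_len = 60, child_len = 36,
                            r = 3, dims = c(64L, 96L, 120L)) {
  th <- theta_deg * pi / 180
  P <- cbind(seq(10, 10 + trunk_len, 2), 48, 32)
  tip <- c(10 + trunk_len, 48, 32)
  d1 <- c(cos(th), sin(th), 0)
  d2 <- c(cos(th), -sin(th), 0)
  C1 <- t(vapply(seq(0, child_len, 2), function(s) tip + s * d1, numeric(3)))
  C2 <- t(vapply(seq(0, child_len, 2), function(s) tip + s * d2, numeric(3)))
  pts <- rbind(P, C1, C2)
  attr(pts, "starts") <- c(1L, nrow(P) + 1L, nrow(P) + nrow(C1) + 1L)
  polyline_mask(pts, rep(r, nrow(pts)), dims)
}

ball_mask <- function(R = 20, n = 48L) {
  c0 <- n / 2
  z <- (seq_len(n) - 0.5) - c0
  arr <- array(0L, dim = c(n, n, n))
  for (k in seq_len(n)) {
    arr[, , k] <- (outer(z^2, z^2, `+`) + z[k]^2 <= R^2) * 1L
  }
  vessel_mask(arr, c(1, 1, 1))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# synthetic vessel_graph from explicit polylines (rows: list of n x 3
# matrices), with node bookkeeping inferred from endpoints
make_graph <- function(polylines, node_tol = 1e-6) {
  nodes <- NULL
  find_node <- function(p) {
    if (!is.null(nodes)) {
      d <- sqrt((nodes$x - p[1])^2 + (nodes$y - p[2])^2 + (nodes$z - p[3])^2)
      i <- which(d < node_tol)
      if (length(i)) return(i[1])
    }
    nodes <<- rbind(nodes, data.frame(id = (nrow(nodes) %||% 0) + 1,
                                      x = p[1], y = p[2], z = p[3],
                                      type = "branch"))
    nrow(nodes)
  }
  segs <- lapply(seq_along(polylines), function(i) {
    P <- polylines[[i]]
    list(id = i, node_from = find_node(P[1, ]),
         node_to = find_node(P[nrow(P), ]),
         points = P, diameter = NULL, level = NA_integer_,
         parent = NA_integer_)
  })
  nodes$id <- seq_len(nrow(nodes))
  structure(list(nodes = nodes, segments = segs), class = "vessel_graph")
}

# straight polyline between two points, ~2 um steps
seg_pts <- function(from, to, step = 2) {
  L <- sqrt(sum((to - from)^2))
  s <- seq(0, L, length.out = max(2, ceiling(L / step) + 1))
  t(vapply(s / L, function(t) from + t * (to - from), numeric(3)))
}

# perfect binary tree of graph segments, depth levels below the root;
# branch lengths shrink per generation so tips of symmetric sub-trees
# never coincide (which would close cycles)
binary_tree_graph <- function(depth = 4, len = 40, spread = 45) {
  polylines <- list()
  grow <- function(origin, dirn, lev, l) {
    tip <- origin + l * dirn / sqrt(sum(dirn^2))
    polylines[[length(polylines) + 1L]] <<- seg_pts(origin, tip)
    if (lev >= depth) return(invisible())
    a <- spread * pi / 180
    base <- atan2(dirn[2], dirn[1])
    for (da in c(-a, a)) {
      d2 <- c(cos(base + da), sin(base + da), 0)
      grow(tip, d2, lev + 1, 0.55 * l)
    }
  }
  grow(c(0, 0, 0), c(1, 0, 0), 0, len)
  make_graph(polylines)
}

fft_stripe_magnitude <- function(v, axis, period) {
  prof <- apply(v$voxels, axis, mean)
  n <- length(prof)
  f <- abs(fft(prof - mean(prof)))
  f[round(n / period) + 1]
}

mask_centroid <- function(arr) {
  idx <- which(arr != 0)
  colMeans(arrayInd(idx, dim(arr)))
}
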