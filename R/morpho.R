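#' Morphometry report constructor
#'
#' Per-region summary of a vascular network: length-weighted mean diameter
#' (um), length density (m/mm^3, i.e. um of centerline per um^3 of tissue
#' times 10^3), volume fraction (%), maximum diameter over
#' junction-free centerline points, a per-segment mean-diameter histogram
#' in 1-um bins over 0--20 um (values above 20 um are clamped into the top
#' bin so counts always sum to the number of segments), and the percentage
#' of segments below 5 um.
#'
#' @param region region name.
#' @param mean_diameter,length_density,volume_fraction,max_diameter,total_length
#'   summary values (um, m/mm^3, \%, um, um).
#' @param segment_mean_diameters per-segment mean diameters (um), used for
#'   the histogram and the below-5-um percentage.
#' @param shrinkage_correction linear tissue-shrinkage factor s already
#'   applied (0 = none).
#' @param empty flag for an empty region.
#' @return An object of class \code{morphometry_report}.
#' @export
morphometry_report <- function(region = "whole",
                               mean_diameter = NA_real_,
                               length_density = 0,
                               volume_fraction = 0,
                               max_diameter = NA_real_,
                               segment_mean_diameters = numeric(0),
                               total_length = 0,
                               shrinkage_correction = 0,
                               empty = FALSE) {
  d <- segment_mean_diameters
  hist_counts <- if (length(d))
    tabulate(pmin(20L, 1L + floor(pmin(d, 19.999))), 20L) else integer(20)
  structure(list(region = region,
                 mean_diameter = mean_diameter,
                 length_density = length_density,
                 volume_fraction = volume_fraction,
                 max_diameter = max_diameter,
                 diameter_histogram = setNames(hist_counts,
                                               paste0(0:19, "-", 1:20)),
                 pct_below_5um = if (length(d)) 100 * mean(d < 5) else NA_real_,
                 n_segments = length(d),
                 segment_mean_diameters = d,
                 total_length = total_length,
                 shrinkage_correction = shrinkage_correction,
                 empty = empty),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf(
    paste0("morphometry_report [%s]%s: mean diameter %.2f um, ",
           "length density %.3f m/mm^3, volume fraction %.3f%%, ",
           "max diameter %.1f um, %d segments (%.1f%% < 5 um)\n"),
    x$region, if (x$empty) " (EMPTY)" else "",
    x$mean_diameter, x$length_density, x$volume_fraction, x$max_diameter,
    x$n_segments, x$pct_below_5um))
  invisible(x)
}

#' Measure local vessel diameters along a centerline graph
#'
#' The local diameter at each centerline point is twice the Euclidean
#' distance transform of the mask (anisotropy-aware, physical units),
#' sampled as the maximum over the 3x3x3 voxel neighbourhood of the point
#' (which re-centres skeleton voxels that sit one voxel off the medial
#' axis). Points within one local radius of a branch node are flagged
#' junction-influenced and excluded from maximum-diameter statistics.
#'
#' @param g a \code{vessel_graph}.
#' @param m the \code{vessel_mask} the graph was skeletonized from.
#' @return The graph with per-point \code{diameter} and \code{junction}
#'   flags on every segment.
#' @export
measure_diameters <- function(g, m) {
  e <- .edt3d(array(as.integer(m$voxels != 0), dim = dim(m$voxels)),
              m$spacing)
  d <- dim(m$voxels)
  sp <- m$spacing
  deg <- node_degrees(g)
  branch_pos <- as.matrix(g$nodes[deg >= 3, c("x", "y", "z"), drop = FALSE])
  for (i in seq_along(g$segments)) {
    s <- g$segments[[i]]
    P <- s$points
    np <- nrow(P)
    diam <- numeric(np)
    for (j in seq_len(np)) {
      iz <- min(d[1], max(1, ceiling(P[j, 3] / sp[1])))
      iy <- min(d[2], max(1, ceiling(P[j, 2] / sp[2])))
      ix <- min(d[3], max(1, ceiling(P[j, 1] / sp[3])))
      zz <- max(1, iz - 1):min(d[1], iz + 1)
      yy <- max(1, iy - 1):min(d[2], iy + 1)
      xx <- max(1, ix - 1):min(d[3], ix + 1)
      diam[j] <- 2 * max(e[zz, yy, xx])
    }
    junction <- rep(FALSE, np)
    if (nrow(branch_pos)) {
      for (j in seq_len(np)) {
        dd <- sqrt(colSums((t(branch_pos) - P[j, ])^2))
        junction[j] <- any(dd < diam[j] / 2)
      }
    }
    g$segments[[i]]$diameter <- diam
    g$segments[[i]]$junction <- junction
  }
  g
}

#' Assign branch levels by breadth-first traversal from a root segment
#'
#' The root segment (level 1) is, by default, the segment with the largest
#' mean diameter in each connected component (the trunk). At every node
#' the best-aligned downstream segment (divergence below
#' \code{cont_angle_deg} from the incoming direction) is treated as the
#' continuation of the same vessel and keeps its level -- a skeletonized
#' trunk is chopped into one graph segment per branch point, and counting
#' each piece as a new generation would make levels grow along an
#' unbranched vessel. All other downstream segments get the parent's
#' level plus one. Cycles are broken where the traversal meets an
#' already-levelled segment, with a warning.
#'
#' @param g a \code{vessel_graph} (diameters already measured for
#'   \code{root = "auto"}).
#' @param root root segment id, or \code{"auto"}.
#' @param cont_angle_deg divergence below which the best-aligned
#'   downstream segment continues the parent's level.
#' @return The graph with \code{level}, \code{parent} and an orientation
#'   marker \code{from_node} (the upstream node) on every segment.
#' @export
assign_branch_levels <- function(g, root = "auto", cont_angle_deg = 30) {
  ns <- length(g$segments)
  if (!ns) return(g)
  # segment connectivity via shared nodes
  node_segs <- vector("list", nrow(g$nodes))
  for (s in g$segments) {
    node_segs[[s$node_from]] <- c(node_segs[[s$node_from]], s$id)
    node_segs[[s$node_to]] <- c(node_segs[[s$node_to]], s$id)
  }
  level <- rep(NA_integer_, ns)
  parent <- rep(NA_integer_, ns)
  from_node <- rep(NA_integer_, ns)
  score <- vapply(g$segments, function(s) {
    if (!is.null(s$diameter)) mean(s$diameter) else segment_length(s)
  }, numeric(1))
  n_cycle <- 0L
  first <- TRUE
  deg <- node_degrees(g)
  has_open_end <- vapply(g$segments, function(s)
    deg[s$node_from] == 1 || deg[s$node_to] == 1, logical(1))
  repeat {
    todo <- which(is.na(level))
    if (!length(todo)) break
    if (first && !identical(root, "auto")) {
      r <- as.integer(root)
    } else {
      # prefer the thickest segment with a free (degree-1) end: the trunk
      # enters the volume through an open end, which anchors the flow
      # direction for the whole component. Junction-bulge stubs can read
      # thicker than the trunk, so insist on a substantial length when
      # such a candidate exists.
      cand <- todo[has_open_end[todo]]
      if (!length(cand)) cand <- todo
      lens <- vapply(cand, function(i) segment_length(g$segments[[i]]),
                     numeric(1))
      if (any(lens >= 10)) cand <- cand[lens >= 10]
      r <- cand[which.max(score[cand])]
    }
    first <- FALSE
    open_end_of <- function(id) {
      s <- g$segments[[id]]
      if (deg[s$node_from] == 1 && deg[s$node_to] == 1) {
        d <- g$segments[[id]]$diameter
        if (!is.null(d) && d[length(d)] > d[1]) s$node_to else s$node_from
      } else if (deg[s$node_to] < deg[s$node_from]) s$node_to else
        s$node_from
    }
    run_bfs <- function(r, fnode) {
      visited <- integer(0)
      level[r] <<- 1L
      from_node[r] <<- fnode
      parent[r] <<- NA_integer_
      queue <- r
      while (length(queue)) {
        cur <- queue[1]; queue <- queue[-1]
        visited <- c(visited, cur)
        s <- g$segments[[cur]]
        for (nd in unique(c(s$node_from, s$node_to))) {
          down <- integer(0)
          for (nxt in node_segs[[nd]]) {
            if (nxt == cur) next
            if (!is.na(level[nxt])) {
              related <- (!is.na(parent[cur]) && parent[cur] == nxt) ||
                (!is.na(parent[nxt]) && parent[nxt] == cur) ||
                (!is.na(parent[cur]) && !is.na(parent[nxt]) &&
                   parent[cur] == parent[nxt])
              if (!related) n_cycle <<- n_cycle + 1L
              next
            }
            down <- c(down, nxt)
          }
          if (!length(down)) next
          # divergence of each downstream segment from cur's direction
          tin <- segment_tangent_at_node(g$segments[[cur]], nd,
                                         incoming = TRUE)
          div <- vapply(down, function(nxt) {
            tout <- segment_tangent_at_node(g$segments[[nxt]], nd,
                                            incoming = FALSE)
            if (is.null(tin) || is.null(tout)) 180 else
              vec_angle_deg(tin, tout)
          }, numeric(1))
          cont <- if (min(div) < cont_angle_deg) down[which.min(div)] else 0L
          for (k in seq_along(down)) {
            nxt <- down[k]
            level[nxt] <<- if (nxt == cont) level[cur] else level[cur] + 1L
            parent[nxt] <<- cur
            from_node[nxt] <<- nd
            queue <- c(queue, nxt)
          }
        }
      }
      visited
    }
    comp <- run_bfs(r, open_end_of(r))
    # flow sanity: daughter vessels branch at acute angles to the flow, so
    # an obtuse mean divergence over the component means the root was
    # anchored at the distal end (taper is below diameter-measurement
    # noise at coarse voxel sizes); re-root at the far end of the level-1
    # chain and redo
    if (length(comp) > 1 && identical(root, "auto")) {
      div1 <- component_mean_divergence(g, comp, level, parent, from_node)
      if (!is.na(div1) && div1 > 90) {
        # flow may be anchored at the distal end: try re-rooting at the
        # deepest substantial open-ended segment and keep whichever
        # orientation gives the more acute branching (daughters diverge
        # forward along the flow)
        l1 <- comp[level[comp] == 1L]
        cand <- comp[has_open_end[comp]]
        alt <- if (length(cand)) {
          lens <- vapply(cand, function(i) segment_length(g$segments[[i]]),
                         numeric(1))
          deepc <- cand[lens >= 10]
          if (!length(deepc)) deepc <- cand
          deepc[which.max(level[deepc])]
        } else l1[length(l1)]
        if (alt != r) {
          snap <- list(level = level[comp], parent = parent[comp],
                       from_node = from_node[comp])
          level[comp] <- NA_integer_
          parent[comp] <- NA_integer_
          from_node[comp] <- NA_integer_
          run_bfs(alt, open_end_of(alt))
          div2 <- component_mean_divergence(g, comp, level, parent,
                                            from_node)
          if (is.na(div2) || div2 >= div1) {   # keep the original
            level[comp] <- snap$level
            parent[comp] <- snap$parent
            from_node[comp] <- snap$from_node
          }
        }
      }
    }
  }
  if (n_cycle > 0)
    warning(n_cycle, " cycle-closing adjacencies broken during level ",
            "assignment", call. = FALSE)
  for (i in seq_len(ns)) {
    g$segments[[i]]$level <- level[i]
    g$segments[[i]]$parent <- parent[i]
    g$segments[[i]]$from_node <- from_node[i]
  }
  g
}

#' Branch (divergence) angles at every branch node
#'
#' For each parent/child segment pair meeting at a node, the parent
#' direction is the unit tangent of the incoming segment estimated over a
#' window approaching the node (i.e. the parent's continuation direction),
#' the child direction is the tangent leaving the node, and the branch
#' angle is the arccosine of their dot product, in degrees. Because
#' centerlines cut the corner inside the junction bulge, tangent
#' estimation skips the first local junction radius (half the measured
#' diameter at the node, when diameters are available) before the window
#' starts. Segments shorter than two points are excluded (their count is
#' reported in the \code{"n_excluded"} attribute).
#'
#' @param g a \code{vessel_graph} with branch levels assigned.
#' @param tangent_window_um tangent estimation window, um.
#' @return Data frame: node, parent and child segment ids, child level,
#'   angle in degrees.
#' @export
branch_angles <- function(g, tangent_window_um = 15) {
  if (!length(g$segments)) return(angle_table(NULL, 0L))
  if (all(is.na(vapply(g$segments, `[[`, integer(1), "level"))))
    stop("assign_branch_levels() first")
  rows <- list()
  n_excl <- 0L
  for (s in g$segments) {
    if (is.na(s$parent)) next
    p <- g$segments[[s$parent]]
    nd <- s$from_node
    # child polyline oriented away from nd
    cp <- if (s$node_from == nd) s$points else
      s$points[rev(seq_len(nrow(s$points))), , drop = FALSE]
    cd <- if (s$node_from == nd) s$diameter else rev(s$diameter)
    # parent polyline oriented node-first (pointing upstream)
    ppo <- if (p$node_from == nd) p$points else
      p$points[rev(seq_len(nrow(p$points))), , drop = FALSE]
    pd <- if (p$node_from == nd) p$diameter else rev(p$diameter)
    # skip the junction bulge: 1.5 local radii at the node (the child's
    # centerline only leaves the parent's lumen after about
    # r_parent / sin(angle) of arc)
    skip <- 1.5 * max(if (!is.null(cd)) cd[1] / 2 else 0,
                      if (!is.null(pd)) pd[1] / 2 else 0)
    tc <- polyline_tangent_window(cp, skip, tangent_window_um)
    tup <- polyline_tangent_window(ppo, skip, tangent_window_um)
    if (is.null(tc) || is.null(tup)) { n_excl <- n_excl + 1L; next }
    # continuation follows the flow: normally the parent arrives AT the
    # node (-tup); if the child sits at the parent's own upstream node
    # (a root's first branch), flow leaves the node along the parent (+tup)
    tp <- if (!is.na(p$from_node) && p$from_node == nd) tup else -tup
    rows[[length(rows) + 1L]] <- data.frame(
      node = nd, parent = p$id, child = s$id, level = s$level,
      continuation = !is.na(p$level) && s$level == p$level,
      angle_deg = vec_angle_deg(tp, tc))
  }
  angle_table(rows, n_excl)
}

angle_table <- function(rows, n_excl) {
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), parent = integer(0), child = integer(0),
               level = integer(0), continuation = logical(0),
               angle_deg = numeric(0))
  attr(out, "n_excluded") <- n_excl
  out
}

polyline_total <- function(P) {
  arc <- polyline_arclength(P)
  arc[length(arc)]
}

# mean parent-child divergence angle over a component, given a candidate
# level/parent/orientation assignment (used to detect reversed flow)
component_mean_divergence <- function(g, comp, level, parent, from_node) {
  angs <- numeric(0)
  for (i in comp) {
    s <- g$segments[[i]]
    pid <- parent[i]
    if (is.na(pid) || level[i] == level[pid]) next
    nd <- from_node[i]
    tc <- segment_tangent_at_node(s, nd, incoming = FALSE)
    p <- g$segments[[pid]]
    tups <- segment_tangent_at_node(p, nd, incoming = FALSE)
    if (is.null(tc) || is.null(tups)) next
    tp <- if (!is.na(from_node[pid]) && from_node[pid] == nd) tups else -tups
    angs <- c(angs, vec_angle_deg(tp, tc))
  }
  if (length(angs)) mean(angs) else NA_real_
}

# unit tangent of a segment at one of its nodes; incoming = TRUE gives the
# direction of travel INTO the node, FALSE the direction leaving it
segment_tangent_at_node <- function(s, nd, incoming, window = 8) {
  P <- if (s$node_from == nd) s$points else
    s$points[rev(seq_len(nrow(s$points))), , drop = FALSE]
  d <- if (s$node_from == nd) s$diameter else rev(s$diameter)
  skip <- if (!is.null(d)) d[1] / 2 else 0
  t_out <- polyline_tangent_window(P, skip, window)   # away from the node
  if (is.null(t_out)) return(NULL)
  if (incoming) -t_out else t_out
}

#' Branch angles of a generative tree (analytic oracle)
#'
#' Recomputes divergence angles directly from the stored ground-truth
#' centerlines of a \code{vessel_tree}: the parent's forward tangent at
#' the attachment point versus the child's initial direction. Used to
#' validate both the generator and the measured-graph angle estimator.
#'
#' @param tree a \code{vessel_tree}.
#' @param tangent_window_um tangent estimation window, um.
#' @return Data frame: parent and child segment ids, child level, angle
#'   in degrees.
#' @export
tree_branch_angles <- function(tree, tangent_window_um = 10) {
  rows <- list()
  for (s in tree$segments) {
    if (is.na(s$parent)) next
    p <- tree$segments[[s$parent]]
    origin <- s$points[1, ]
    # parent tangent at the attachment, pointing forward (continuation)
    dd <- sqrt(rowSums((p$points - matrix(origin, nrow(p$points), 3,
                                          byrow = TRUE))^2))
    i <- which.min(dd)
    i0 <- max(1, i - 1); i1 <- min(nrow(p$points), i + 1)
    tp <- p$points[i1, ] - p$points[i0, ]
    tp <- tp / sqrt(sum(tp^2))
    tc <- polyline_end_tangent(s$points, tangent_window_um, "head")
    if (is.null(tc)) next
    rows[[length(rows) + 1L]] <- data.frame(
      parent = p$id, child = s$id, level = s$level,
      angle_deg = vec_angle_deg(tp, tc))
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(parent = integer(0), child = integer(0), level = integer(0),
               angle_deg = numeric(0))
}

#' Regional morphometry of a measured vessel graph
#'
#' Restricts centerline points and mask voxels to one labelled region (or
#' the whole volume) and reports: length density in m/mm^3
#' (\code{sum(L_um) / V_um^3 * 10^3}), volume fraction as
#' \code{100 * vessel voxels / region voxels}, length-weighted mean of the
#' local diameters, maximum diameter over junction-free points, the
#' per-segment mean-diameter histogram (1-um bins, 0--20 um) and the
#' percentage of segments below 5 um. An optional isotropic shrinkage
#' correction \code{s} rescales lengths and diameters by \code{1/(1-s)}
#' and volumes by \code{1/(1-s)^3} (tissue and vessel alike, so the
#' volume fraction is unchanged and the length density scales by
#' \code{(1-s)^2}).
#'
#' @param g a \code{vessel_graph} with measured diameters.
#' @param m the source \code{vessel_mask}.
#' @param region optional \code{\link{region_mask}}.
#' @param label region label (name or integer) when \code{region} is given.
#' @param shrinkage_correction linear shrinkage fraction s in [0, 1);
#'   0 (default) applies none.
#' @return A \code{\link{morphometry_report}}.
#' @export
region_morphometry <- function(g, m, region = NULL, label = NULL,
                               shrinkage_correction = 0) {
  d <- dim(m$voxels)
  sp <- m$spacing
  if (!is.null(region)) {
    lab <- region_label_value(region, label)
    if (!any(region$labels == lab))
      stop("label '", label, "' is empty; available: ",
           paste(names(region$names), collapse = ", "))
    sel <- region$labels == lab
    rname <- as.character(label)
  } else {
    sel <- NULL
    rname <- "whole"
  }
  in_region <- function(P) {
    if (is.null(sel)) return(rep(TRUE, nrow(P)))
    iz <- pmin(d[1], pmax(1, ceiling(P[, 3] / sp[1])))
    iy <- pmin(d[2], pmax(1, ceiling(P[, 2] / sp[2])))
    ix <- pmin(d[3], pmax(1, ceiling(P[, 1] / sp[3])))
    sel[cbind(iz, iy, ix)]
  }
  region_voxels <- if (is.null(sel)) prod(d) else sum(sel)
  vessel_voxels <- if (is.null(sel)) sum(m$voxels != 0) else
    sum(m$voxels[sel] != 0)
  V_um3 <- region_voxels * prod(sp)

  total_len <- 0; wsum <- 0; max_d <- NA_real_
  seg_means <- numeric(0)
  for (s in g$segments) {
    P <- s$points
    if (nrow(P) < 2 || is.null(s$diameter)) next
    keep_pt <- in_region(P)
    # each step belongs to the region of its midpoint, so summing over a
    # label partition reproduces the whole-volume totals exactly
    mids <- (P[-1, , drop = FALSE] + P[-nrow(P), , drop = FALSE]) / 2
    mid_keep <- in_region(mids)
    if (!any(keep_pt) && !any(mid_keep)) next
    ds <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
    dm <- (s$diameter[-1] + s$diameter[-length(s$diameter)]) / 2
    total_len <- total_len + sum(ds[mid_keep])
    wsum <- wsum + sum(dm[mid_keep] * ds[mid_keep])
    free <- keep_pt & !(s$junction %||% rep(FALSE, nrow(P)))
    if (any(free)) max_d <- max(max_d, s$diameter[free], na.rm = TRUE)
    if (any(keep_pt)) seg_means <- c(seg_means, mean(s$diameter[keep_pt]))
  }
  f <- 1 / (1 - shrinkage_correction)
  morphometry_report(
    region = rname,
    mean_diameter = if (total_len > 0) f * wsum / total_len else NA_real_,
    length_density = (f * total_len) / (f^3 * V_um3) * 1e3,
    volume_fraction = 100 * vessel_voxels / region_voxels,
    max_diameter = f * max_d,
    segment_mean_diameters = f * seg_means,
    total_length = f * total_len,
    shrinkage_correction = shrinkage_correction,
    empty = total_len == 0)
}

#' Extract the subtree downstream of a root segment
#'
#' Connected subgraph reachable through child links from \code{root};
#' levels are re-rooted at 1.
#'
#' @param g a \code{vessel_graph} with levels assigned.
#' @param root root segment id.
#' @param max_level keep segments up to this re-rooted level.
#' @return A \code{vessel_graph}.
#' @export
extract_subtree <- function(g, root, max_level = Inf) {
  lv <- vapply(g$segments, `[[`, integer(1), "level")
  if (all(is.na(lv))) stop("assign_branch_levels() first")
  base <- g$segments[[root]]$level
  keep <- rep(FALSE, length(g$segments))
  keep[root] <- TRUE
  repeat {
    grew <- FALSE
    for (s in g$segments) {
      if (keep[s$id] || is.na(s$parent) || !keep[s$parent]) next
      if (s$level - base + 1 > max_level) next
      keep[s$id] <- TRUE; grew <- TRUE
    }
    if (!grew) break
  }
  segs <- g$segments[keep]
  for (i in seq_along(segs)) segs[[i]]$level <- segs[[i]]$level - base + 1L
  old_ids <- vapply(segs, `[[`, integer(1), "id")
  remap <- setNames(seq_along(segs), old_ids)
  for (i in seq_along(segs)) {
    segs[[i]]$id <- i
    pp <- segs[[i]]$parent
    segs[[i]]$parent <- if (!is.na(pp) && as.character(pp) %in% names(remap))
      unname(remap[as.character(pp)]) else NA_integer_
  }
  out <- structure(list(nodes = g$nodes, segments = segs),
                   class = "vessel_graph")
  attributes(out)[c("iso_spacing", "mask_dim")] <-
    attributes(g)[c("iso_spacing", "mask_dim")]
  out
}
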