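#' Write a vessel tree or graph as SWC
#'
#' One SWC node per centerline point (type code 7, radius in um); each
#' polyline chains parent links internally, and the first point of a child
#' segment links to the nearest point of its parent segment. Root points
#' have parent -1.
#'
#' @param x a \code{vessel_tree} or \code{vessel_graph}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_swc <- function(x, file) {
  segs <- x$segments
  rows <- list()
  nid <- 0L
  first_id <- integer(length(segs))
  point_store <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    r <- if (!is.null(s$radius)) s$radius
         else if (!is.null(s$diameter)) s$diameter / 2
         else rep(1, nrow(s$points))
    ids <- nid + seq_len(nrow(s$points))
    nid <- nid + nrow(s$points)
    first_id[i] <- ids[1]
    point_store[[i]] <- list(ids = ids, P = s$points)
    parent_col <- c(-1L, ids[-length(ids)])
    rows[[i]] <- data.frame(id = ids, type = 7L,
                            x = s$points[, 1], y = s$points[, 2],
                            z = s$points[, 3], radius = r,
                            parent = parent_col)
  }
  # link child roots to the nearest parent point
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (is.null(s$parent) || is.na(s$parent)) next
    ps <- point_store[[s$parent]]
    d2 <- rowSums((ps$P - matrix(segs[[i]]$points[1, ], nrow(ps$P), 3,
                                 byrow = TRUE))^2)
    rows[[i]]$parent[1] <- ps$ids[which.min(d2)]
  }
  tab <- do.call(rbind, rows)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# SWC export: one node per centerline point, radius in um", con)
  write.table(format(tab, scientific = FALSE, trim = TRUE), con,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Write a per-segment summary table as CSV
#'
#' Columns: segment id, parent id, branch level, length (um), mean and max
#' diameter or radius-derived diameter (um), and the divergence angle to
#' the parent where available.
#'
#' @param x a \code{vessel_tree} or \code{vessel_graph}.
#' @param file output path.
#' @param angles optional angle table (from \code{\link{branch_angles}} or
#'   \code{\link{tree_branch_angles}}) to join on the child segment id.
#' @return \code{file}, invisibly.
#' @export
write_segment_csv <- function(x, file, angles = NULL) {
  rows <- lapply(x$segments, function(s) {
    diam <- if (!is.null(s$diameter)) s$diameter
            else if (!is.null(s$radius)) 2 * s$radius else NA_real_
    data.frame(id = s$id,
               parent = s$parent %||% NA_integer_,
               level = s$level %||% NA_integer_,
               length_um = polyline_total(s$points),
               mean_diameter_um = mean(diam),
               max_diameter_um = max(diam))
  })
  tab <- do.call(rbind, rows)
  tab$angle_to_parent_deg <- NA_real_
  if (!is.null(angles) && nrow(angles)) {
    m <- match(tab$id, angles$child)
    tab$angle_to_parent_deg <- angles$angle_deg[m]
  }
  write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' Write a binary vessel mask as an 8-bit TIFF (0/255)
#'
#' @param m a \code{vessel_mask}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(m, path) {
  v <- volume3d(array(ifelse(m$voxels != 0, 255, 0), dim = dim(m$voxels)),
                m$spacing, c(0, 255))
  write_volume(v, path, bits = 8L)
}

#' @importFrom utils write.table
NULL
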