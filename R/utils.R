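# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_odd <- function(k, what) {
  if (any(k < 1) || any(k %% 2 == 0))
    stop(what, " must be odd and >= 1, got ", paste(k, collapse = "x"),
         call. = FALSE)
  invisible(k)
}

# arc lengths of a polyline (n x 3 matrix); returns cumulative lengths from 0
polyline_arclength <- function(P) {
  if (nrow(P) < 2) return(0)
  steps <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
  c(0, cumsum(steps))
}

# linear resampling of a polyline at a fixed arc-length step (keeps both ends)
resample_polyline <- function(P, step) {
  arc <- polyline_arclength(P)
  total <- arc[length(arc)]
  if (total <= 0) return(P[1, , drop = FALSE])
  s <- unique(c(seq(0, total, by = step), total))
  out <- vapply(seq_len(3), function(j) approx(arc, P[, j], xout = s)$y,
                numeric(length(s)))
  matrix(out, ncol = 3)
}

# unit direction of a polyline at one end, estimated over a window (um).
# end = "head": direction pointing AWAY from the first point (leaving);
# end = "tail": direction pointing INTO the last point (arriving).
polyline_end_tangent <- function(P, window, end = c("head", "tail")) {
  end <- match.arg(end)
  if (nrow(P) < 2) return(NULL)
  arc <- polyline_arclength(P)
  total <- arc[length(arc)]
  w <- min(window, total)
  if (end == "head") {
    i <- which(arc >= w)[1]
    d <- P[i, ] - P[1, ]
  } else {
    i <- rev(which(arc <= total - w))[1]
    d <- P[nrow(P), ] - P[i, ]
  }
  n <- sqrt(sum(d^2))
  if (n == 0) return(NULL)
  d / n
}

# direction of a polyline (oriented with the reference end first) estimated
# over arc window [skip, skip + window], capped to stay on the line: a
# total-least-squares line fit through the window's points (robust to the
# 26-connected voxel jaggedness), oriented away from the first point
polyline_tangent_window <- function(P, skip, window) {
  arc <- polyline_arclength(P)
  tot <- arc[length(arc)]
  if (tot <= 0) return(NULL)
  s0 <- min(skip, 0.4 * tot)
  s1 <- min(s0 + window, tot)
  if (s1 - s0 < 1e-9) { s0 <- 0; s1 <- tot }
  keep <- arc >= s0 - 1e-9 & arc <= s1 + 1e-9
  Q <- P[keep, , drop = FALSE]
  # add exact interpolated window ends so short windows stay well-posed
  ends <- vapply(c(s0, s1), function(s)
    vapply(1:3, function(j) approx(arc, P[, j], xout = s)$y, numeric(1)),
    numeric(3))
  Q <- rbind(t(ends), Q)
  d <- if (nrow(Q) > 2) {
    ctr <- colMeans(Q)
    sv <- svd(sweep(Q, 2, ctr), nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (sum(v * (ends[, 2] - ends[, 1])) < 0) -v else v
  } else ends[, 2] - ends[, 1]
  n <- sqrt(sum(d^2))
  if (n == 0) return(NULL)
  d / n
}

# angle in degrees between two unit-ish vectors
vec_angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

# orthonormal basis perpendicular to unit vector t
perp_basis <- function(t) {
  ref <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(t[2] * ref[3] - t[3] * ref[2],
         t[3] * ref[1] - t[1] * ref[3],
         t[1] * ref[2] - t[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(t[2] * u[3] - t[3] * u[2],
         t[3] * u[1] - t[1] * u[3],
         t[1] * u[2] - t[2] * u[1])
  list(u = u, v = v)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @importFrom stats approx
NULL
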