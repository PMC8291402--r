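#' Two-tailed unpaired Student's t-test (pooled variance)
#'
#' The classic pooled-variance t statistic with \code{df = n1 + n2 - 2}
#' and a two-sided p-value from the t distribution. (Pooled, not Welch;
#' a Welch option is available.)
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param welch use the Welch unequal-variance form instead.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
ttest_unpaired <- function(x, y, welch = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per sample")
  v1 <- var(x); v2 <- var(y)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) stop("zero variance in both samples: t is undefined")
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    if (sp2 == 0) stop("zero pooled variance: t is undefined")
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Assemble a two-group morphometry study
#'
#' @param groups named list (length 2; first group is the reference, e.g.
#'   wild-type) of subject lists. Each subject is a list with
#'   \code{reports} (a named list of \code{\link{morphometry_report}}s, by
#'   region) and optionally \code{angles} (a \code{\link{branch_angles}}
#'   table).
#' @param alpha significance level.
#' @return An object of class \code{group_study}.
#' @export
group_study <- function(groups, alpha = 0.05) {
  if (length(groups) != 2 || is.null(names(groups)))
    stop("groups must be a named list of exactly two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 subjects for testing")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(groups = groups, alpha = alpha), class = "group_study")
}

#' Compare per-region morphometric metrics between two groups
#'
#' One pooled two-tailed t-test per (metric, region); group summaries are
#' mean and s.e.m. No multiple-testing correction is applied (each test is
#' reported at the study's alpha); interpret families of tests
#' accordingly.
#'
#' @param study a \code{\link{group_study}}.
#' @param metrics report fields to compare.
#' @return Data frame of class \code{comparison_result}: metric, region,
#'   per-group mean and s.e.m., t, df, two-sided p, significance flag at
#'   alpha, and direction of change of the second group versus the first
#'   (\code{"down"}, \code{"up"} or \code{"none"}).
#' @export
compare_regions <- function(study,
                            metrics = c("mean_diameter", "volume_fraction",
                                        "length_density", "pct_below_5um")) {
  g1 <- study$groups[[1]]; g2 <- study$groups[[2]]
  regions <- unique(unlist(lapply(c(g1, g2), function(s) names(s$reports))))
  rows <- list()
  for (metric in metrics) for (region in regions) {
    v1 <- subject_metric(g1, region, metric)
    v2 <- subject_metric(g2, region, metric)
    if (length(v1) < 2 || length(v2) < 2) next
    tt <- ttest_unpaired(v1, v2)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = metric, region = region,
      mean_1 = mean(v1), sem_1 = sd(v1) / sqrt(length(v1)),
      mean_2 = mean(v2), sem_2 = sd(v2) / sqrt(length(v2)),
      dispersion = "sem",
      n_1 = length(v1), n_2 = length(v2),
      t = tt$t, df = tt$df, p = tt$p,
      significant = tt$p < study$alpha,
      direction = if (mean(v2) < mean(v1)) "down"
                  else if (mean(v2) > mean(v1)) "up" else "none")
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_result", "data.frame")
  out
}

subject_metric <- function(group, region, metric) {
  v <- vapply(group, function(s) {
    r <- s$reports[[region]]
    if (is.null(r)) NA_real_ else as.numeric(r[[metric]])
  }, numeric(1))
  v[!is.na(v)]
}

#' Compare mean branch angles per branch level between two groups
#'
#' Each subject contributes its mean branch angle per level (levels with
#' fewer than \code{min_branches} branches in a subject are dropped for
#' that subject); a pooled t-test is run per level wherever both groups
#' retain at least two subjects. Levels beyond the data are reported as
#' absent, not zero. Dispersion is reported as s.d.
#'
#' @param study a \code{\link{group_study}} whose subjects carry
#'   \code{angles} tables.
#' @param max_level deepest branch level to consider.
#' @param min_branches minimum branches per subject and level.
#' @return Data frame: level, per-group mean and s.d., n, t, df, p,
#'   significance flag, direction; with an \code{"excluded"} attribute
#'   listing (group, subject, level) combinations dropped.
#' @export
compare_angle_by_level <- function(study, max_level = 8L, min_branches = 3L) {
  per_subject <- function(group) {
    lapply(group, function(s) {
      a <- s$angles
      if (!is.null(a) && !is.null(a$continuation)) a <- a[!a$continuation, ]
      if (is.null(a) || !nrow(a)) return(data.frame(level = integer(0),
                                                    angle = numeric(0),
                                                    n = integer(0)))
      agg <- aggregate(a$angle_deg, by = list(level = a$level),
                       FUN = function(z) c(mean(z), length(z)))
      data.frame(level = agg$level, angle = agg$x[, 1], n = agg$x[, 2])
    })
  }
  s1 <- per_subject(study$groups[[1]])
  s2 <- per_subject(study$groups[[2]])
  excluded <- list()
  level_values <- function(subs, lev, gname) {
    v <- numeric(0)
    for (i in seq_along(subs)) {
      row <- subs[[i]][subs[[i]]$level == lev, ]
      if (!nrow(row)) next
      if (row$n < min_branches) {
        excluded[[length(excluded) + 1L]] <<- data.frame(
          group = gname, subject = i, level = lev, n_branches = row$n)
        next
      }
      v <- c(v, row$angle)
    }
    v
  }
  rows <- list()
  gnames <- names(study$groups)
  for (lev in seq_len(max_level)) {
    v1 <- level_values(s1, lev, gnames[1])
    v2 <- level_values(s2, lev, gnames[2])
    if (length(v1) < 2 || length(v2) < 2) next
    tt <- ttest_unpaired(v1, v2)
    rows[[length(rows) + 1L]] <- data.frame(
      level = lev,
      mean_1 = mean(v1), sd_1 = sd(v1), n_1 = length(v1),
      mean_2 = mean(v2), sd_2 = sd(v2), n_2 = length(v2),
      dispersion = "sd",
      t = tt$t, df = tt$df, p = tt$p,
      significant = tt$p < study$alpha,
      direction = if (mean(v2) < mean(v1)) "down"
                  else if (mean(v2) > mean(v1)) "up" else "none")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = integer(0))
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' @importFrom stats aggregate median
NULL
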