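#' Acoustic field-of-view statistics
#'
#' Ensonified cone-base areas and area ratios, active-sonar detection
#' range, beamwidth-versus-range regression, and the cluster/ANOVA
#' comparison of beamwidth groups against distance to target.
#'
#' @name fov_stats
NULL

#' Ensonified area at a target range
#'
#' Base of a cone with height equal to the target range and opening angle
#' equal to the -3 dB beamwidth: A = pi (r tan(bw/2))^2.
#'
#' @param beamwidth_deg full -3 dB beamwidth, degrees (0-180).
#' @param range_m m (> 0).
#' @return m^2.
#' @export
ensonified_area <- function(beamwidth_deg, range_m) {
  if (any(beamwidth_deg <= 0) || any(beamwidth_deg >= 180) ||
      any(range_m <= 0))
    stop("need 0 < beamwidth < 180 deg and range > 0")
  pi * (range_m * tan(deg2rad(beamwidth_deg) / 2))^2
}

#' Measured-to-predicted ensonified-area ratios
#'
#' Ratio of the area measured at a given target range to the area
#' predicted for that range from the median beamwidth of long-range
#' clicks (> 2 m); the range cancels:
#' ratio = (tan(bw/2) / tan(bw_ref/2))^2.
#'
#' @param beamwidth_deg per-click beamwidths, degrees.
#' @param range_m per-click target ranges, m.
#' @param long_range_min m; clicks beyond this form the reference.
#' @return numeric vector with attribute `reference_deg`.
#' @export
area_ratio_series <- function(beamwidth_deg, range_m, long_range_min = 2) {
  ref_set <- beamwidth_deg[range_m > long_range_min]
  if (length(ref_set) == 0L)
    stop("no long-range clicks to form the reference beamwidth")
  ref <- stats::median(ref_set)
  ratio <- (tan(deg2rad(beamwidth_deg) / 2) / tan(deg2rad(ref) / 2))^2
  attr(ratio, "reference_deg") <- ref
  ratio
}

#' Active-sonar detection range
#'
#' Largest r with SL - 40 log10(r) + TS >= DT (two-way spherical
#' spreading): r = 10^((SL + TS - DT) / 40).  Defaults: detection
#' threshold 27 dB re 1 uPa^2 s, target strength -36 dB.
#'
#' @param source_level_db energy flux density source level, dB re
#'   1 uPa^2 s at 1 m.
#' @param detection_threshold_db dB re 1 uPa^2 s.
#' @param target_strength_db dB.
#' @return m (values below 1 m reported as-is).
#' @export
detection_range <- function(source_level_db, detection_threshold_db = 27,
                            target_strength_db = -36) {
  10^((source_level_db + target_strength_db - detection_threshold_db) / 40)
}

#' Beamwidth-versus-range regression
#'
#' Ordinary least squares of beamwidth on target range.
#'
#' @param beamwidth_deg per-click beamwidths, degrees.
#' @param range_m per-click target ranges, m.
#' @return list `slope` (deg/m), `intercept`, `f_statistic`, `r_squared`,
#'   `p_value`, `n`, `model` (the `lm` fit).
#' @export
beamwidth_range_regression <- function(beamwidth_deg, range_m) {
  if (length(beamwidth_deg) < 3L) stop("need >= 3 records")
  if (stats::var(range_m) == 0) stop("zero variance in range")
  fit <- stats::lm(beamwidth_deg ~ range_m)
  s <- summary(fit)
  f <- unname(s$fstatistic)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       f_statistic = f[1], r_squared = s$r.squared,
       p_value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
       n = length(beamwidth_deg), model = fit)
}

#' Beamwidth clusters versus distance to target
#'
#' Hierarchical cluster analysis (centroid linkage, non-standardized) of
#' the raw beamwidths cut at three clusters, followed by one-way ANOVA of
#' distance-to-target across the clusters and Tukey-Kramer pairwise
#' comparisons.
#'
#' @param beamwidth_deg per-click beamwidths, degrees (>= 3 distinct
#'   values).
#' @param range_m per-click distances to target, m.
#' @param k number of clusters.
#' @return list `clusters` (integer labels, 1 = narrowest-beam cluster by
#'   mean beamwidth), `anova_f`, `anova_p`, `tukey` (matrix of pairwise
#'   comparisons), `cluster_means` (beamwidth and range means per
#'   cluster), `degenerate`.
#' @export
cluster_anova <- function(beamwidth_deg, range_m, k = 3) {
  stopifnot(length(beamwidth_deg) == length(range_m))
  if (length(unique(beamwidth_deg)) < k) {
    return(list(clusters = rep(NA_integer_, length(beamwidth_deg)),
                anova_f = NA_real_, anova_p = NA_real_, tukey = NULL,
                cluster_means = NULL, degenerate = TRUE))
  }
  # centroid linkage expects squared Euclidean distances
  hc <- stats::hclust(stats::dist(beamwidth_deg)^2, method = "centroid")
  raw <- stats::cutree(hc, k = k)
  # relabel so cluster 1 has the narrowest mean beamwidth
  mw <- tapply(beamwidth_deg, raw, mean)
  relabel <- match(raw, as.integer(names(sort(mw))))
  grp <- factor(relabel, levels = seq_len(k))
  fit <- stats::aov(range_m ~ grp)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$grp
  list(clusters = relabel,
       anova_f = s[["F value"]][1], anova_p = s[["Pr(>F)"]][1],
       tukey = tk,
       cluster_means = data.frame(
         cluster = seq_len(k),
         beamwidth_deg = as.numeric(tapply(beamwidth_deg, grp, mean)),
         range_m = as.numeric(tapply(range_m, grp, mean)),
         n = as.integer(table(grp))),
       degenerate = FALSE)
}

#' Phase summary of beamwidths
#'
#' Means, medians and extremes of beamwidth by clicking phase.
#'
#' @param beamwidth_deg per-click beamwidths.
#' @param is_buzz logical per click.
#' @return data.frame with one row per phase.
#' @export
beamwidth_phase_summary <- function(beamwidth_deg, is_buzz) {
  phase <- factor(ifelse(is_buzz, "buzz", "regular"),
                  levels = c("regular", "buzz"))
  do.call(rbind, lapply(levels(phase), function(p) {
    x <- beamwidth_deg[phase == p]
    data.frame(phase = p, n = length(x), mean = mean(x),
               median = stats::median(x),
               min = suppressWarnings(min(x)),
               max = suppressWarnings(max(x)))
  }))
}
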