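#' Per-animal feature means by concentration
#'
#' Averages every feature over all windows recorded at the same
#' administered concentration for each animal (pooling repeated
#' segments at that concentration), the unit of observation for the
#' modulation tests. Animals missing a concentration are excluded from
#' that concentration with a warning.
#'
#' @param feature_table A cohort feature table.
#' @param features Feature columns to aggregate (default all).
#' @return A data.frame with `animal_id`, `conc_pct` and one mean per
#'   feature.
#' @export
per_animal_means <- function(feature_table,
                             features = feature_columns(feature_table)) {
  ft <- feature_table[, c("animal_id", "conc_pct", features)]
  agg <- stats::aggregate(ft[features],
                          by = list(animal_id = ft$animal_id,
                                    conc_pct = ft$conc_pct),
                          FUN = mean, na.rm = TRUE)
  n_conc <- length(unique(agg$conc_pct))
  counts <- table(agg$animal_id)
  missing <- names(counts)[counts < n_conc]
  if (length(missing) > 0)
    warning("animal(s) missing a concentration: ",
            paste(missing, collapse = ", "))
  agg[order(agg$animal_id, agg$conc_pct), ]
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test with mid-ranks for ties. The p-value is
#' exact (via the null permutation distribution) when the combined
#' sample size is at most 12 and no ties are present, otherwise the
#' normal approximation with tie correction and continuity correction
#' is used. Fully tied samples return p = 1.
#'
#' @param x,y Numeric samples.
#' @param alternative As in [stats::wilcox.test()].
#' @return A list with `U` (statistic for `x`) and `p`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0 || length(y) == 0) stop("samples must be nonempty")
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1))
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Step-up procedure at level `q`: rejects the `k` smallest p-values
#' where `k` is the largest index with `p_(k) <= k q / m`. Adjusted
#' p-values are `min over k' >= k of m p_(k') / k'`, capped at 1.
#'
#' @param p Vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return A list with `reject` (logical, original order) and
#'   `p_adjusted`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p, method = "BH")
  list(reject = p_adj <= q, p_adjusted = p_adj)
}

#' Feature-modulation report
#'
#' For every feature, tests each unordered pair of distinct
#' concentrations with a two-sided Mann-Whitney U test on the
#' per-animal means and applies Benjamini-Hochberg FDR control. The BH
#' family is, by default, the set of pairwise tests within one feature
#' (`family = "per_feature"`); `family = "per_pair"` instead controls
#' across features within each concentration pair. Per-concentration
#' medians of the per-animal means and the median relative
#' within-segment SD are reported alongside.
#'
#' @param feature_table A cohort feature table.
#' @param q FDR level.
#' @param family BH family structure, `"per_feature"` or `"per_pair"`.
#' @param features Feature columns to test.
#' @return A data.frame with one row per (feature, concentration pair):
#'   `feature`, `c1`, `c2`, `U`, `p`, `p_adjusted`, `reject`,
#'   `median_c1`, `median_c2`, `rel_sd_c1`, `rel_sd_c2`, plus
#'   attribute `bh_family` documenting the family choice.
#' @export
modulation_report <- function(feature_table, q = 0.05,
                              family = c("per_feature", "per_pair"),
                              features = feature_columns(feature_table)) {
  family <- match.arg(family)
  means <- suppressWarnings(per_animal_means(feature_table, features))
  concs <- sort(unique(means$conc_pct))
  n_animals <- length(unique(means$animal_id))
  degenerate <- n_animals < 2
  if (degenerate)
    warning("fewer than 2 animals: all p-values reported as 1")
  pairs <- utils::combn(concs, 2)

  # relative within-segment SD (sd/|mean| over windows of one segment),
  # median across animal-segments at each concentration
  rel_sd <- function(feat, conc) {
    sel <- feature_table$conc_pct == conc
    v <- tapply(feature_table[[feat]][sel],
                interaction(feature_table$animal_id[sel],
                            feature_table$segment[sel], drop = TRUE),
                function(z) {
                  m <- mean(z, na.rm = TRUE)
                  if (!is.finite(m) || m == 0) return(NA_real_)
                  stats::sd(z, na.rm = TRUE) / abs(m)
                })
    stats::median(unlist(v), na.rm = TRUE)
  }

  rows <- list()
  for (feat in features) {
    for (j in seq_len(ncol(pairs))) {
      c1 <- pairs[1, j]; c2 <- pairs[2, j]
      x <- means[[feat]][means$conc_pct == c1]
      y <- means[[feat]][means$conc_pct == c2]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (degenerate || length(x) == 0 || length(y) == 0) {
        mw <- list(U = NA_real_, p = 1)
      } else {
        mw <- mann_whitney_u(x, y)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = feat, c1 = c1, c2 = c2, U = mw$U, p = mw$p,
        median_c1 = stats::median(x), median_c2 = stats::median(y),
        rel_sd_c1 = rel_sd(feat, c1), rel_sd_c2 = rel_sd(feat, c2),
        stringsAsFactors = FALSE
      )
    }
  }
  rep <- do.call(rbind, rows)
  if (family == "per_feature") {
    groups <- rep$feature
  } else {
    groups <- paste(rep$c1, rep$c2)
  }
  rep$p_adjusted <- NA_real_
  rep$reject <- NA
  for (g in unique(groups)) {
    sel <- groups == g
    bh <- bh_fdr(rep$p[sel], q)
    rep$p_adjusted[sel] <- bh$p_adjusted
    rep$reject[sel] <- bh$reject
  }
  rep <- rep[, c("feature", "c1", "c2", "U", "p", "p_adjusted", "reject",
                 "median_c1", "median_c2", "rel_sd_c1", "rel_sd_c2")]
  attr(rep, "bh_family") <- family
  rep
}
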