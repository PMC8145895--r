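# Two-condition differential analysis of ncAA sites: signed fold-change
# ratios, two-tailed t-tests on spectral counts, the significance gate,
# and per-protein aggregation.

#' Significance gate for ncAA calls
#'
#' A site is called significant only when its parent cluster's Gaussian
#' goodness of fit exceeds `r2_threshold`, its absolute signed ratio
#' exceeds `ratio_threshold`, and its p-value is below `alpha`.
#'
#' @param ratio_threshold Fold-change bound (default 2).
#' @param alpha p-value bound (default 0.05).
#' @param r2_threshold Cluster goodness-of-fit bound (default 0.5).
#' @return Named list.
#' @export
significance_gate <- function(ratio_threshold = 2, alpha = 0.05,
                              r2_threshold = 0.5) {
  stopifnot(ratio_threshold > 0, alpha > 0, alpha < 1, r2_threshold > 0)
  list(ratio_threshold = ratio_threshold, alpha = alpha,
       r2_threshold = r2_threshold)
}

#' Signed fold-change ratio
#'
#' With `a = mean_case + pseudocount` and `b = mean_control + pseudocount`,
#' the ratio is `a/b` when `a >= b` and `-b/a` otherwise, so that
#' `|ratio| >= 1` always, a negative ratio means higher in control
#' (downregulated in the case condition), and
#' `signed_ratio(a, b) = -signed_ratio(b, a)` up to the sign convention at
#' equality. The pseudocount guards against zero counts at small n.
#'
#' @param mean_case,mean_control Non-negative per-condition mean counts
#'   (vectorized).
#' @param pseudocount Added to both means (default 0.5).
#' @return Numeric vector of signed ratios.
#' @export
#' @examples
#' signed_ratio(8, 2)  # 3.4
signed_ratio <- function(mean_case, mean_control, pseudocount = 0.5) {
  stopifnot(all(mean_case >= 0), all(mean_control >= 0), pseudocount > 0)
  a <- mean_case + pseudocount
  b <- mean_control + pseudocount
  ifelse(a >= b, a / b, -b / a)
}

#' Two-tailed t-test on per-sample site counts
#'
#' Two-sample two-tailed Student's t-test (equal variance by default;
#' Welch via `var_equal = FALSE`) on optionally normalized spectral
#' counts. Degenerate inputs follow the convention: zero variance in both
#' groups with equal means gives p = 1; zero variance with unequal means
#' gives p = 0, flagged via the `"degenerate"` attribute.
#'
#' @param case_counts,control_counts Per-sample counts (>= 2 samples
#'   each).
#' @param normalizers Optional per-sample normalizers, a list with
#'   elements `case` and `control` (e.g. total filtered PSM counts);
#'   counts are divided by them and rescaled by the mean normalizer so
#'   values stay on the count scale.
#' @param var_equal Pool variances (classic Student test, default TRUE).
#' @return p-value in `[0, 1]`.
#' @export
site_test <- function(case_counts, control_counts, normalizers = NULL,
                      var_equal = TRUE) {
  stopifnot(length(case_counts) >= 2, length(control_counts) >= 2)
  x <- as.numeric(case_counts)
  y <- as.numeric(control_counts)
  if (!is.null(normalizers)) {
    scale <- mean(c(normalizers$case, normalizers$control))
    x <- x / normalizers$case * scale
    y <- y / normalizers$control * scale
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  stats::t.test(x, y, var.equal = var_equal,
                alternative = "two.sided")$p.value
}

#' Build the per-site ncAA table from clustered observations
#'
#' Groups clustered observations by modified site (protein, position,
#' residue) within each cluster and tabulates per-sample spectral counts.
#' Samples absent for a site contribute a zero count; the sample roster
#' and condition labels are taken from the full observation table (or an
#' explicit `samples` data frame for samples with no observations at
#' all).
#'
#' @param observations Observation data frame, see [delta_observations()].
#' @param clusters A `delta_clusters` object for the same observations.
#' @param condition_map Named character vector mapping the two condition
#'   labels to roles, default `c(case = "ischemia", control = "control")`.
#' @param samples Optional data frame `sample_id`, `condition` overriding
#'   the roster derived from the observations.
#' @return List with `sites` (data frame: site key columns, `cluster_id`,
#'   cluster `delta_mass`, per-condition n), `counts` (matrix sites x
#'   samples), and `samples` (roster with roles).
#' @export
site_counts <- function(observations, clusters,
                        condition_map = c(case = "ischemia",
                                          control = "control"),
                        samples = NULL) {
  stopifnot(inherits(clusters, "delta_clusters"),
            nrow(observations) == clusters$n_obs)
  if (is.null(samples)) {
    samples <- unique(observations[c("sample_id", "condition")])
  }
  samples$role <- names(condition_map)[match(samples$condition,
                                             condition_map)]
  if (anyNA(samples$role)) {
    stop("condition label(s) not covered by condition_map: ",
         paste(unique(samples$condition[is.na(samples$role)]),
               collapse = ", "), call. = FALSE)
  }
  samples <- samples[order(samples$role, samples$sample_id), ]

  keep <- !is.na(clusters$assignment)
  obs <- observations[keep, , drop = FALSE]
  cid <- clusters$assignment[keep]
  if (nrow(obs) == 0L) {
    sites <- data.frame(protein_acc = character(0),
                        site_position = integer(0),
                        site_residue = character(0),
                        cluster_id = integer(0), delta_mass = numeric(0),
                        stringsAsFactors = FALSE)
    counts <- matrix(0L, nrow = 0, ncol = nrow(samples),
                     dimnames = list(NULL, samples$sample_id))
    return(list(sites = sites, counts = counts, samples = samples))
  }
  site_key <- paste(format_site_notation(obs$protein_acc, obs$site_position,
                                         obs$site_residue), cid, sep = "|")
  usites <- !duplicated(site_key)
  sites <- data.frame(
    protein_acc = obs$protein_acc[usites],
    site_position = obs$site_position[usites],
    site_residue = obs$site_residue[usites],
    cluster_id = cid[usites],
    stringsAsFactors = FALSE
  )
  sites$delta_mass <- clusters$clusters$delta_mass[
    match(sites$cluster_id, clusters$clusters$cluster_id)]
  key_u <- site_key[usites]

  counts <- matrix(0L, nrow = nrow(sites), ncol = nrow(samples),
                   dimnames = list(key_u, samples$sample_id))
  tab <- table(factor(site_key, levels = key_u),
               factor(obs$sample_id, levels = samples$sample_id))
  counts[] <- as.integer(tab)
  list(sites = sites, counts = counts, samples = samples)
}

#' Call significant ncAA sites
#'
#' Computes, for every modified site, the per-condition mean counts, the
#' signed fold-change ratio, the two-tailed t-test p-value, and the
#' direction call under the significance gate: `up` when
#' `ratio > ratio_threshold` and `p < alpha`, `down` when
#' `ratio < -ratio_threshold` and `p < alpha`, `ns` otherwise — and in
#' all cases only when the parent cluster's R-squared exceeds
#' `r2_threshold`. A Benjamini-Hochberg adjusted p-value column is
#' emitted for information; the gate itself uses the raw p-values.
#'
#' @param observations,clusters,condition_map,samples See [site_counts()].
#' @param gate See [significance_gate()].
#' @param normalization `"none"` (raw spectral counts, the default),
#'   `"total_psm"` (scale each sample by its total observation count,
#'   rescaled to the mean total), or `"median"` (scale by the median
#'   ratio to the across-sample mean profile).
#' @param pseudocount See [signed_ratio()].
#' @param var_equal See [site_test()].
#' @return Data frame with one row per site: site columns, `site` (the
#'   rendered notation), `cluster_id`, `delta_mass`, `cluster_r_squared`,
#'   `mean_case`, `mean_control`, `ratio`, `p_value`, `p_adj_bh`,
#'   `n_case`, `n_control`, `n_total`, `direction`.
#' @export
call_significance <- function(observations, clusters,
                              gate = significance_gate(),
                              condition_map = c(case = "ischemia",
                                                control = "control"),
                              normalization = c("none", "total_psm",
                                                "median"),
                              pseudocount = 0.5, var_equal = TRUE,
                              samples = NULL) {
  normalization <- match.arg(normalization)
  sc <- site_counts(observations, clusters, condition_map, samples)
  if (nrow(sc$sites) == 0L) {
    return(cbind(sc$sites, data.frame(
      site = character(0), cluster_r_squared = numeric(0),
      mean_case = numeric(0), mean_control = numeric(0),
      ratio = numeric(0), p_value = numeric(0), p_adj_bh = numeric(0),
      n_case = integer(0), n_control = integer(0), n_total = integer(0),
      direction = character(0))))
  }
  counts <- sc$counts
  case_ids <- sc$samples$sample_id[sc$samples$role == "case"]
  ctrl_ids <- sc$samples$sample_id[sc$samples$role == "control"]
  if (length(case_ids) < 2 || length(ctrl_ids) < 2) {
    stop("need at least 2 samples per condition", call. = FALSE)
  }

  norm_counts <- counts
  if (normalization == "total_psm") {
    totals <- colSums(counts)
    totals[totals == 0] <- 1
    norm_counts <- sweep(counts, 2, totals, "/") * mean(totals)
  } else if (normalization == "median") {
    ref <- rowMeans(counts)
    f <- apply(counts, 2, function(cc) {
      ok <- ref > 0 & cc > 0
      if (!any(ok)) 1 else stats::median(cc[ok] / ref[ok])
    })
    f[f == 0 | !is.finite(f)] <- 1
    norm_counts <- sweep(counts, 2, f, "/")
  }

  res <- sc$sites
  res$site <- format_site_notation(res$protein_acc, res$site_position,
                                   res$site_residue)
  res$cluster_r_squared <- clusters$clusters$r_squared[
    match(res$cluster_id, clusters$clusters$cluster_id)]
  res$mean_case <- rowMeans(norm_counts[, case_ids, drop = FALSE])
  res$mean_control <- rowMeans(norm_counts[, ctrl_ids, drop = FALSE])
  res$ratio <- signed_ratio(res$mean_case, res$mean_control, pseudocount)
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    as.numeric(site_test(norm_counts[i, case_ids],
                         norm_counts[i, ctrl_ids],
                         var_equal = var_equal))
  }, numeric(1))
  res$p_adj_bh <- stats::p.adjust(res$p_value, method = "BH")
  res$n_case <- as.integer(rowSums(counts[, case_ids, drop = FALSE]))
  res$n_control <- as.integer(rowSums(counts[, ctrl_ids, drop = FALSE]))
  res$n_total <- res$n_case + res$n_control

  r2_ok <- !is.na(res$cluster_r_squared) &
    res$cluster_r_squared > gate$r2_threshold
  sig <- r2_ok & res$p_value < gate$alpha
  res$direction <- ifelse(sig & res$ratio > gate$ratio_threshold, "up",
                   ifelse(sig & res$ratio < -gate$ratio_threshold, "down",
                          "ns"))
  rownames(res) <- NULL
  res
}

#' Aggregate significant sites into protein lists
#'
#' Distinct proteins per direction; a protein carrying both an up and a
#' down site appears in both lists.
#'
#' @param sites Site table from [call_significance()].
#' @return List with data frames `up` and `down`, each with
#'   `protein_acc`, `n_sites`, `sites` (semicolon-joined site notation).
#' @export
aggregate_proteins <- function(sites) {
  one_dir <- function(dir) {
    s <- sites[sites$direction == dir, , drop = FALSE]
    if (nrow(s) == 0L) {
      return(data.frame(protein_acc = character(0), n_sites = integer(0),
                        sites = character(0), stringsAsFactors = FALSE))
    }
    sp <- split(s$site, s$protein_acc)
    out <- data.frame(
      protein_acc = names(sp),
      n_sites = lengths(sp),
      sites = vapply(sp, paste, character(1), collapse = "; "),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out[order(-out$n_sites, out$protein_acc), , drop = FALSE]
  }
  list(up = one_dir("up"), down = one_dir("down"))
}
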