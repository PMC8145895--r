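# Annotation of clustered delta masses against the chemistry catalog, and
# the acceptance rules for matched and unmatched clusters.

.CLASS_ORDER <- c(PTM = 1L, substitution = 2L, adduct = 3L, loss = 4L)

#' Match one clustered delta mass against a catalog
#'
#' Returns every catalog record whose `delta_mass` lies within `tolerance`
#' of the cluster's peak value, sorted by ascending absolute error; ties
#' are broken by chemistry class (PTM before substitution before adduct
#' before loss) and then by name. The default tolerance (0.0025 Da) admits
#' the largest error seen in practice for instrument-scale dispersion
#' while excluding next-nearest catalog masses.
#'
#' @param mu Clustered delta mass (Da).
#' @param catalog Catalog data frame, see [builtin_catalog()].
#' @param tolerance Maximum absolute mass error (Da), > 0.
#' @return Data frame of matches: catalog columns plus `error`
#'   (`|mu - delta_mass|`).
#' @export
#' @examples
#' m <- match_cluster(14.0172, builtin_catalog())
#' round(m$error[m$name == "Methylation"], 4)  # 0.0016
match_cluster <- function(mu, catalog, tolerance = 0.0025) {
  stopifnot(is.numeric(mu), length(mu) == 1L, tolerance > 0)
  if (is.null(catalog) || nrow(catalog) == 0L) {
    stop("empty catalog", call. = FALSE)
  }
  err <- abs(mu - catalog$delta_mass)
  hits <- catalog[err <= tolerance, , drop = FALSE]
  hits$error <- err[err <= tolerance]
  # round for ordering so records identical in exact arithmetic (e.g.
  # methylation vs a G>A substitution) tie and fall through to the class
  # ordering, instead of being separated by float noise
  ord <- order(round(hits$error, 9),
               .CLASS_ORDER[hits$class],
               hits$name)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify a cluster as matched, assigned-unmatched, or rejected
#'
#' A cluster with at least one catalog match within tolerance is
#' `"matched"` and treated as a true delta mass. An unmatched cluster is
#' `"assigned_unmatched"` (kept with confidence) only when its Gaussian
#' goodness of fit exceeds 0.5 or it is predominantly associated with a
#' single amino acid (> 50 percent of members); the two branches are
#' combined as an inclusive OR. Otherwise it is `"rejected"` but retained
#' in output with the reason. The classification is a pure function of its
#' three arguments.
#'
#' @param matches Match data frame from [match_cluster()] (possibly empty).
#' @param r_squared Gaussian-regression goodness of fit (`NA` if
#'   undefined).
#' @param dominant_residue_fraction Fraction of members at the most common
#'   residue.
#' @return List with `status` and `reason`.
#' @export
classify_cluster <- function(matches, r_squared, dominant_residue_fraction) {
  if (!is.null(matches) && nrow(matches) > 0L) {
    return(list(status = "matched", reason = "catalog match within tolerance"))
  }
  r2_ok <- !is.na(r_squared) && r_squared > 0.5
  res_ok <- !is.na(dominant_residue_fraction) &&
    dominant_residue_fraction > 0.5
  if (r2_ok || res_ok) {
    reason <- c(if (r2_ok) "R-squared > 0.5",
                if (res_ok) "single dominant residue (> 50%)")
    return(list(status = "assigned_unmatched",
                reason = paste(reason, collapse = " and ")))
  }
  list(status = "rejected",
       reason = "unmatched, R-squared <= 0.5 and no dominant residue")
}

#' Residue-level consistency of a chemistry match
#'
#' A mass match is chemically consistent only when the cluster's dominant
#' residue is a valid target of the matched record: a -33.9858 Da cluster
#' on cysteine is consistent with loss of H2S (cysteine to
#' dehydroalanine) but not with an F-to-L substitution, whose source
#' residue is phenylalanine. Records with target `"any"` are consistent
#' with every residue.
#'
#' @param dominant_residue One-letter code of the cluster's dominant
#'   residue.
#' @param record A single catalog record (one-row data frame or list with
#'   `name` and `targets`).
#' @return List with `consistent` (logical) and `note` (the reasoning).
#' @export
chemistry_consistency <- function(dominant_residue, record) {
  targets <- record$targets
  if (identical(targets, "any")) {
    return(list(consistent = TRUE,
                note = sprintf("%s can occur at any residue", record$name)))
  }
  allowed <- strsplit(targets, ",", fixed = TRUE)[[1]]
  ok <- dominant_residue %in% allowed
  note <- if (ok) {
    sprintf("dominant residue %s is a valid target of %s",
            dominant_residue, record$name)
  } else {
    sprintf("dominant residue %s is not a target of %s (targets: %s)",
            dominant_residue, record$name, targets)
  }
  list(consistent = ok, note = note)
}

#' Annotate a set of delta-mass clusters
#'
#' Runs [match_cluster()], [classify_cluster()] and
#' [chemistry_consistency()] over every cluster of a
#' [cluster_deltas()] result and assembles the machine-readable analog of
#' a published cluster table: peak mass, best match and its calculated
#' mass and error, all matches, status, and the consistency flag of the
#' best match.
#'
#' @param clusters A `delta_clusters` object or its `clusters` data frame.
#' @param catalog Catalog data frame (default [builtin_catalog()]).
#' @param tolerance Mass tolerance in Da, see [match_cluster()].
#' @return Data frame with one row per cluster: `cluster_id`,
#'   `delta_mass`, `calculated_mass`, `error`, `best_match`,
#'   `match_class`, `all_matches` (semicolon-joined), `n_matches`,
#'   `status`, `reason`, `consistent`, `consistency_note`, plus the
#'   cluster bookkeeping columns (`sd`, `r_squared`, `freq`, `counts`,
#'   `dominant_residue`, `dominant_residue_fraction`).
#' @export
annotate_clusters <- function(clusters, catalog = builtin_catalog(),
                              tolerance = 0.0025) {
  cl <- if (inherits(clusters, "delta_clusters")) clusters$clusters else clusters
  out <- lapply(seq_len(nrow(cl)), function(i) {
    row <- cl[i, ]
    m <- match_cluster(row$delta_mass, catalog, tolerance)
    cls <- classify_cluster(m, row$r_squared, row$dominant_residue_fraction)
    if (nrow(m) > 0L) {
      best <- m[1, ]
      cons <- chemistry_consistency(row$dominant_residue, best)
      data.frame(
        cluster_id = row$cluster_id, delta_mass = row$delta_mass,
        calculated_mass = best$delta_mass, error = best$error,
        best_match = best$name, match_class = best$class,
        all_matches = paste(m$name, collapse = "; "), n_matches = nrow(m),
        status = cls$status, reason = cls$reason,
        consistent = cons$consistent, consistency_note = cons$note,
        sd = row$sd, r_squared = row$r_squared, freq = row$freq,
        counts = row$counts, dominant_residue = row$dominant_residue,
        dominant_residue_fraction = row$dominant_residue_fraction,
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        cluster_id = row$cluster_id, delta_mass = row$delta_mass,
        calculated_mass = NA_real_, error = NA_real_,
        best_match = NA_character_, match_class = NA_character_,
        all_matches = "", n_matches = 0L,
        status = cls$status, reason = cls$reason,
        consistent = NA, consistency_note = "",
        sd = row$sd, r_squared = row$r_squared, freq = row$freq,
        counts = row$counts, dominant_residue = row$dominant_residue,
        dominant_residue_fraction = row$dominant_residue_fraction,
        stringsAsFactors = FALSE
      )
    }
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(cluster_id = integer(0))
  }
  rownames(res) <- NULL
  res
}
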