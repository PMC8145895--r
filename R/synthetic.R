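# Synthetic PSM generator with planted ground truth. Emulates the
# statistical structure the pipeline assumes: Gaussian delta-mass peaks
# at known chemistry masses with instrument-scale dispersion, a uniform
# background of spurious deltas, lognormal per-sample spectral counts
# with planted fold changes across 3 case vs 3 control samples, and a
# configurable fraction of PSMs failing the score filters.

#' Default planted chemistries
#'
#' One planted modification per curated chemistry of the bundled catalog,
#' each at a chemically sensible target residue, with a mix of
#' upregulated (+4), downregulated (-4) and unregulated (fold 1)
#' plantings.
#'
#' @return Data frame `name`, `delta_mass`, `residue`, `n_sites`,
#'   `mean_count`, `fold_change`.
#' @export
default_planted_mods <- function() {
  chem <- builtin_catalog(substitutions = FALSE)
  residues <- c(
    "Methylation" = "V", "+Carbon" = "G",
    "Aminoethylbenzene-sulfonylation" = "S", "C>deHA (H2S loss)" = "C",
    "Formylation" = "S", "Arg addition" = "K",
    "Deamination, pyroglutamate" = "Q", "Glutathione disulfide" = "C",
    "Acetylation" = "S", "Dioxidation" = "M", "Didehydro (-2H)" = "V",
    "Carboxylation" = "A"
  )
  folds <- c(
    "Methylation" = 4, "+Carbon" = -4,
    "Aminoethylbenzene-sulfonylation" = 4, "C>deHA (H2S loss)" = -4,
    "Formylation" = 1, "Arg addition" = 4,
    "Deamination, pyroglutamate" = -4, "Glutathione disulfide" = 1,
    "Acetylation" = 1, "Dioxidation" = 4, "Didehydro (-2H)" = -4,
    "Carboxylation" = 1
  )
  data.frame(
    name = chem$name,
    delta_mass = chem$delta_mass,
    residue = unname(residues[chem$name]),
    n_sites = 3L,
    mean_count = 3,
    fold_change = unname(folds[chem$name]),
    stringsAsFactors = FALSE
  )
}

#' Synthetic dataset configuration
#'
#' @param seed Integer RNG seed; the generated table is a deterministic
#'   function of the full configuration.
#' @param n_case,n_control Samples per condition (default 3 and 3).
#' @param proteins Data frame `accession`, `length`; defaults to 20
#'   synthetic proteins (`SYNP001`...).
#' @param planted_mods Data frame as in [default_planted_mods()]:
#'   chemistry name, true delta mass, target residue, number of modified
#'   sites, mean spectral count per sample at an unregulated site, and
#'   signed fold change (positive = higher in case, negative = higher in
#'   control, 1 = unregulated; 0 is invalid).
#' @param mass_error_sd SD of the Gaussian mass error around each true
#'   delta (default 0.002 Da, instrument-scale dispersion).
#' @param background_rate Fraction of observations drawn from a uniform
#'   delta background over the full window range (default 0.05).
#' @param count_noise Within-group coefficient of variation of the
#'   lognormal count model (default 0.2).
#' @param fail_rate Fraction of additional PSM rows that violate exactly
#'   one filter criterion, to exercise the filtering stage (default 0.1).
#' @param condition_labels Labels written to the table, default
#'   `c(case = "ischemia", control = "control")`.
#' @return Validated configuration list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_case = 3L, n_control = 3L,
                             proteins = NULL,
                             planted_mods = default_planted_mods(),
                             mass_error_sd = 0.002,
                             background_rate = 0.05,
                             count_noise = 0.2,
                             fail_rate = 0.1,
                             condition_labels = c(case = "ischemia",
                                                  control = "control")) {
  if (is.null(proteins)) {
    proteins <- data.frame(accession = sprintf("SYNP%03d", 1:20),
                           length = 300L + (1:20) * 17L,
                           stringsAsFactors = FALSE)
  }
  stopifnot(mass_error_sd > 0, background_rate >= 0, background_rate < 1,
            count_noise >= 0, fail_rate >= 0,
            all(planted_mods$fold_change != 0),
            all(planted_mods$mean_count >= 0),
            all(c("case", "control") %in% names(condition_labels)))
  if (nrow(planted_mods) == 0L && background_rate == 0) {
    stop("nothing to generate: no planted modifications and no background",
         call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_case = as.integer(n_case),
    n_control = as.integer(n_control), proteins = proteins,
    planted_mods = planted_mods, mass_error_sd = mass_error_sd,
    background_rate = background_rate, count_noise = count_noise,
    fail_rate = fail_rate, condition_labels = condition_labels
  ), class = "synthetic_config")
}

# lognormal draw with mean m and coefficient of variation cv, rounded
.rlnorm_count <- function(n, m, cv) {
  if (m <= 0) return(rep(0L, n))
  if (cv <= 0) return(rep(as.integer(round(m)), n))
  sdlog <- sqrt(log(1 + cv^2))
  as.integer(round(stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2,
                                 sdlog = sdlog)))
}

#' Generate a synthetic PSM table with ground truth
#'
#' Deterministic given the configuration (the RNG state is saved and
#' restored). Site delta masses are Normal(true delta, `mass_error_sd`);
#' per-sample spectral counts are rounded lognormals with the configured
#' CV, condition means scaled by the planted fold change; background
#' observations have uniform deltas over the window range; an additional
#' `fail_rate` fraction of rows each violate one filter criterion.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory; when given, `psms.tsv`,
#'   `truth_sites.tsv` and `truth_observations.tsv` are written there.
#' @return List of class `synthetic_psm_data` with `psms` (PSM data
#'   frame in the generic dialect), `truth_sites` (per planted site:
#'   site key columns, chemistry, true delta, fold, expected direction),
#'   `truth_observations` (per PSM row of the signal+background set: the
#'   chemistry label or `"background"`), and `config`.
#' @export
generate_psm_data <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  samples <- data.frame(
    sample_id = c(sprintf("case%d", seq_len(config$n_case)),
                  sprintf("ctrl%d", seq_len(config$n_control))),
    condition = c(rep(config$condition_labels[["case"]], config$n_case),
                  rep(config$condition_labels[["control"]],
                      config$n_control)),
    role = c(rep("case", config$n_case),
             rep("control", config$n_control)),
    stringsAsFactors = FALSE
  )

  pm <- config$planted_mods
  truth_sites <- list()
  rows <- list()

  for (i in seq_len(nrow(pm))) {
    prot_idx <- sample.int(nrow(config$proteins), pm$n_sites[i],
                           replace = pm$n_sites[i] > nrow(config$proteins))
    for (s in seq_len(pm$n_sites[i])) {
      acc <- config$proteins$accession[prot_idx[s]]
      pos <- sample.int(config$proteins$length[prot_idx[s]], 1L)
      f <- pm$fold_change[i]
      m_case <- if (f >= 1) pm$mean_count[i] * f else pm$mean_count[i]
      m_ctrl <- if (f <= -1) pm$mean_count[i] * abs(f) else pm$mean_count[i]
      expected <- if (f > 1) "up" else if (f < -1) "down" else "ns"
      truth_sites[[length(truth_sites) + 1L]] <- data.frame(
        protein_acc = acc, site_position = pos,
        site_residue = pm$residue[i], chemistry = pm$name[i],
        true_delta = pm$delta_mass[i], fold_change = f,
        expected_direction = expected, stringsAsFactors = FALSE
      )
      for (j in seq_len(nrow(samples))) {
        m <- if (samples$role[j] == "case") m_case else m_ctrl
        cnt <- .rlnorm_count(1L, m, config$count_noise)
        if (cnt == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = samples$sample_id[j],
          condition = samples$condition[j],
          protein_acc = acc, site_position = pos,
          site_residue = pm$residue[i],
          delta_mass = stats::rnorm(cnt, pm$delta_mass[i],
                                    config$mass_error_sd),
          truth = pm$name[i], stringsAsFactors = FALSE
        )
      }
    }
  }
  signal <- if (length(rows)) do.call(rbind, rows) else NULL
  n_signal <- if (is.null(signal)) 0L else nrow(signal)

  n_bg <- if (config$background_rate > 0) {
    as.integer(round(config$background_rate / (1 - config$background_rate) *
                       max(n_signal, 1L)))
  } else 0L
  if (n_bg > 0L) {
    prot_idx <- sample.int(nrow(config$proteins), n_bg, replace = TRUE)
    bg <- data.frame(
      sample_id = sample(samples$sample_id, n_bg, replace = TRUE),
      condition = NA_character_,
      protein_acc = config$proteins$accession[prot_idx],
      site_position = vapply(prot_idx, function(k) {
        sample.int(config$proteins$length[k], 1L)
      }, integer(1)),
      site_residue = sample(rownames(.RESIDUE_FORMULAS), n_bg,
                            replace = TRUE),
      delta_mass = stats::runif(n_bg, .WINDOW_MIN - 0.5, .WINDOW_MAX + 0.5),
      truth = "background", stringsAsFactors = FALSE
    )
    bg$condition <- samples$condition[match(bg$sample_id,
                                            samples$sample_id)]
    signal <- rbind(signal, bg)
  }
  # avoid deltas the filter would drop as effectively unmodified
  small <- abs(signal$delta_mass) <= 0.0105
  if (any(small)) signal$delta_mass[small] <- 0.0106 * sign(
    ifelse(signal$delta_mass[small] == 0, 1, signal$delta_mass[small]))

  n <- nrow(signal)
  psms <- data.frame(
    spectrum_id = sprintf("sp%06d", seq_len(n)),
    sample_id = signal$sample_id,
    condition = signal$condition,
    protein_acc = signal$protein_acc,
    peptide = "SYNTHETIC",
    site_position = signal$site_position,
    site_residue = signal$site_residue,
    delta_mass = signal$delta_mass,
    score = stats::runif(n, 320, 620),
    delta_mods_score = stats::runif(n, 12, 60),
    fdr2d = stats::runif(n, 0, 0.01),
    fdr_uniq2d = stats::runif(n, 0, 0.01),
    stringsAsFactors = FALSE
  )

  n_fail <- as.integer(round(config$fail_rate * n))
  if (n_fail > 0L) {
    pick <- sample.int(n, n_fail, replace = TRUE)
    fail <- psms[pick, , drop = FALSE]
    fail$spectrum_id <- sprintf("spF%05d", seq_len(n_fail))
    mode <- sample(c("score", "dms", "fdr", "delta"), n_fail,
                   replace = TRUE)
    fail$score[mode == "score"] <- stats::runif(sum(mode == "score"),
                                                50, 299)
    fail$delta_mods_score[mode == "dms"] <- stats::runif(sum(mode == "dms"),
                                                         0, 9.9)
    fail$fdr2d[mode == "fdr"] <- stats::runif(sum(mode == "fdr"),
                                              0.011, 0.2)
    fail$delta_mass[mode == "delta"] <- stats::runif(sum(mode == "delta"),
                                                     -0.01, 0.01)
    psms <- rbind(psms, fail)
    rownames(psms) <- NULL
  }

  truth_sites <- if (length(truth_sites)) {
    do.call(rbind, truth_sites)
  } else {
    data.frame(protein_acc = character(0), site_position = integer(0),
               site_residue = character(0), chemistry = character(0),
               true_delta = numeric(0), fold_change = numeric(0),
               expected_direction = character(0))
  }
  truth_obs <- data.frame(spectrum_id = sprintf("sp%06d", seq_len(n)),
                          truth = signal$truth, stringsAsFactors = FALSE)

  out <- structure(list(psms = psms, truth_sites = truth_sites,
                        truth_observations = truth_obs, config = config),
                   class = "synthetic_psm_data")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.table(psms, file.path(dir, "psms.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth_sites, file.path(dir, "truth_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth_obs, file.path(dir, "truth_observations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Score pipeline recovery against the planted ground truth
#'
#' A planted chemistry counts as recovered when some reported cluster
#' peak lies within `mass_tol` of its true delta mass; precision is the
#' fraction of reported clusters within `mass_tol` of some planted mass;
#' the mass RMSE is taken over recovered (cluster, truth) pairs. When a
#' site table from [call_significance()] is supplied, direction
#' sensitivity (regulated sites called in the correct direction) and the
#' false-call rate on unregulated sites are scored as well.
#'
#' @param clusters A `delta_clusters` object fit to the generated data.
#' @param truth A `synthetic_psm_data` object (or its `truth_sites`).
#' @param sites Optional site table from [call_significance()].
#' @param mass_tol Mass tolerance in Da (default 0.005).
#' @return List with `cluster_recall`, `cluster_precision`,
#'   `mass_rmse`, and (when `sites` is given) `sensitivity`,
#'   `false_call_rate`, `n_regulated`, `n_null`.
#' @export
score_recovery <- function(clusters, truth, sites = NULL,
                           mass_tol = 0.005) {
  ts <- if (inherits(truth, "synthetic_psm_data")) truth$truth_sites else truth
  planted <- unique(ts[c("chemistry", "true_delta")])
  mus <- clusters$clusters$delta_mass
  recovered <- vapply(planted$true_delta, function(m) {
    any(abs(mus - m) <= mass_tol)
  }, logical(1))
  matched_mu <- vapply(mus, function(m) {
    d <- abs(planted$true_delta - m)
    if (any(d <= mass_tol)) planted$true_delta[which.min(d)] else NA_real_
  }, numeric(1))
  rmse <- if (any(!is.na(matched_mu))) {
    sqrt(mean((mus[!is.na(matched_mu)] -
                 matched_mu[!is.na(matched_mu)])^2))
  } else NA_real_

  out <- list(
    cluster_recall = if (nrow(planted)) mean(recovered) else NA_real_,
    cluster_precision = if (length(mus)) mean(!is.na(matched_mu)) else NA_real_,
    mass_rmse = rmse
  )
  if (!is.null(sites)) {
    key <- function(d) format_site_notation(d$protein_acc, d$site_position,
                                            d$site_residue)
    called <- sites$direction[match(key(ts), key(sites))]
    called[is.na(called)] <- "ns"
    reg <- ts$expected_direction != "ns"
    out$sensitivity <- if (any(reg)) {
      mean(called[reg] == ts$expected_direction[reg])
    } else NA_real_
    out$false_call_rate <- if (any(!reg)) {
      mean(called[!reg] != "ns")
    } else NA_real_
    out$n_regulated <- sum(reg)
    out$n_null <- sum(!reg)
  }
  out
}
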