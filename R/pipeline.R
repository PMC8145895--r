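# End-to-end orchestration: configuration, the seven-table output
# contract, provenance (config hash + seed footers), and the
# publication-style report.

#' Pipeline run configuration
#'
#' Bundles every tunable of the pipeline stages. The configuration is
#' serialized (and hashed) into the output directory alongside the
#' results, so a run is reproducible from its own outputs.
#'
#' @param input Path to a PSM table, or a PSM data frame.
#' @param output_dir Output directory.
#' @param dialect PSM column dialect, see [psm_dialect()].
#' @param filter Filter thresholds, see [default_psm_filter()].
#' @param constraints Clustering constraints, see
#'   [clustering_constraints()].
#' @param catalog Chemistry catalog (default [builtin_catalog()]); a path
#'   to a catalog TSV is also accepted.
#' @param tolerance Annotation mass tolerance (Da).
#' @param gate Significance gate, see [significance_gate()].
#' @param condition_map Condition label mapping, see [site_counts()].
#' @param normalization Count normalization, see [call_significance()].
#' @param pseudocount Ratio pseudocount.
#' @param seed Integer seed recorded with the outputs.
#' @return List of class `run_config`.
#' @export
run_config <- function(input, output_dir, dialect = "generic",
                       filter = default_psm_filter(),
                       constraints = clustering_constraints(),
                       catalog = NULL, tolerance = 0.0025,
                       gate = significance_gate(),
                       condition_map = c(case = "ischemia",
                                         control = "control"),
                       normalization = "none", pseudocount = 0.5,
                       seed = 1L) {
  if (is.character(catalog)) catalog <- read_catalog(catalog)
  structure(list(
    input = input, output_dir = output_dir, dialect = dialect,
    filter = filter, constraints = constraints, catalog = catalog,
    tolerance = tolerance, gate = gate, condition_map = condition_map,
    normalization = normalization, pseudocount = pseudocount,
    seed = as.integer(seed)
  ), class = "run_config")
}

# stable textual serialization of a config (input data/catalog excluded
# from the text, included in the hash via their own serialization)
.config_text <- function(config) {
  flat <- c(
    dialect = paste(config$dialect, collapse = ","),
    unlist(config$filter), unlist(config$constraints),
    tolerance = config$tolerance, unlist(config$gate),
    condition_case = unname(config$condition_map[["case"]]),
    condition_control = unname(config$condition_map[["control"]]),
    normalization = config$normalization,
    pseudocount = config$pseudocount, seed = config$seed
  )
  paste0(names(flat), "=", unname(flat))
}

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(.config_text(config), tf)
  unname(tools::md5sum(tf))
}

# TSV writer with the provenance footer every output table carries
.write_table <- function(df, path, hash, seed) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  cat(sprintf("# config_hash=%s seed=%d\n", hash, seed),
      file = path, append = TRUE)
  invisible(path)
}

.read_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Run the full ncAA discovery pipeline
#'
#' Reads (or takes) a PSM table, filters it, extracts delta-mass
#' observations, clusters them, annotates the clusters against the
#' catalog, calls differential sites under the significance gate, and
#' writes seven TSVs plus a run log to the output directory:
#' `filtered_psms.tsv`, `observations.tsv`, `clusters.tsv`,
#' `annotated_clusters.tsv`, `sites.tsv`, `proteins_up.tsv`,
#' `proteins_down.tsv`, `gene_list.tsv` (accessions of significant
#' proteins, for external enrichment services), `config.txt` and
#' `run_log.txt`. Every table carries a provenance footer with the config
#' hash and seed; re-running an identical configuration reproduces
#' identical tables.
#'
#' @param config A [run_config()].
#' @return The output directory, invisibly; the in-memory results are
#'   attached as the `results` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  log_lines <- c(
    sprintf("ncaadelta %s", as.character(utils::packageVersion("ncaadelta"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("config_hash %s", hash),
    sprintf("seed %d", config$seed)
  )
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  psms <- stage("ingest", {
    if (is.character(config$input)) {
      read_psm_table(config$input, config$dialect)
    } else {
      validate_psms(config$input)
    }
  })
  log_lines <- c(log_lines,
                 sprintf("ingest: %d records, %d malformed", nrow(psms),
                         attr(psms, "n_malformed") %||% 0L))

  filtered <- stage("filter", filter_psms(psms, config$filter))
  obs <- stage("observations", delta_observations(filtered))
  log_lines <- c(log_lines,
                 sprintf("filter: %d of %d PSMs pass", nrow(filtered),
                         nrow(psms)))

  clusters <- stage("cluster",
                    cluster_deltas(obs, config$constraints, config$seed))
  catalog <- config$catalog %||% builtin_catalog()
  annotated <- stage("annotate",
                     annotate_clusters(clusters, catalog, config$tolerance))
  sites <- stage("differential",
                 call_significance(obs, clusters, config$gate,
                                   config$condition_map,
                                   config$normalization,
                                   config$pseudocount))
  proteins <- stage("aggregate", aggregate_proteins(sites))
  log_lines <- c(log_lines,
                 sprintf("cluster: %d clusters", nrow(clusters$clusters)),
                 sprintf("differential: %d up / %d down sites",
                         sum(sites$direction == "up"),
                         sum(sites$direction == "down")))

  w <- function(df, name) .write_table(df, file.path(config$output_dir, name),
                                       hash, config$seed)
  w(filtered, "filtered_psms.tsv")
  w(obs, "observations.tsv")
  w(clusters$clusters, "clusters.tsv")
  w(annotated, "annotated_clusters.tsv")
  w(sites, "sites.tsv")
  w(proteins$up, "proteins_up.tsv")
  w(proteins$down, "proteins_down.tsv")
  gene_list <- data.frame(
    protein_acc = c(proteins$up$protein_acc, proteins$down$protein_acc),
    direction = c(rep("up", nrow(proteins$up)),
                  rep("down", nrow(proteins$down))),
    stringsAsFactors = FALSE
  )
  w(gene_list, "gene_list.tsv")
  writeLines(.config_text(config), file.path(config$output_dir,
                                             "config.txt"))
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))

  out <- config$output_dir
  attr(out, "results") <- list(psms = psms, filtered = filtered, obs = obs,
                               clusters = clusters, annotated = annotated,
                               sites = sites, proteins = proteins)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a human-readable report from pipeline outputs
#'
#' Reads the tables written by [run_pipeline()] and renders the cluster
#' table (Delta Mass Cluster, Calculated Mass, Error, Possible Chemistry,
#' Freq, Counts) and the up/down protein lists. Deterministic: the same
#' outputs always render byte-identical report text.
#'
#' @param output_dir Directory written by [run_pipeline()].
#' @param file Optional path to also write the report to.
#' @return Character vector of report lines, invisibly when `file` is
#'   given.
#' @export
make_report <- function(output_dir, file = NULL) {
  need <- c("annotated_clusters.tsv", "proteins_up.tsv",
            "proteins_down.tsv")
  for (f in need) {
    if (!file.exists(file.path(output_dir, f))) {
      stop("missing pipeline output: ", f, call. = FALSE)
    }
  }
  ann <- .read_table(file.path(output_dir, "annotated_clusters.tsv"))
  up <- .read_table(file.path(output_dir, "proteins_up.tsv"))
  down <- .read_table(file.path(output_dir, "proteins_down.tsv"))

  lines <- c("Delta-mass cluster table",
             paste("Delta Mass Cluster", "Calculated Mass", "Error",
                   "Possible Chemistry", "Freq", "Counts", sep = "\t"))
  if (nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      lines <- c(lines, paste(
        sprintf("%.4f", ann$delta_mass[i]),
        ifelse(is.na(ann$calculated_mass[i]), "-",
               sprintf("%.4f", ann$calculated_mass[i])),
        ifelse(is.na(ann$error[i]), "-", sprintf("%.4f", ann$error[i])),
        ifelse(is.na(ann$best_match[i]) | ann$all_matches[i] == "", "-",
               ann$all_matches[i]),
        ann$freq[i], ann$counts[i], sep = "\t"))
    }
  } else {
    lines <- c(lines, "(no clusters)")
  }
  lines <- c(lines, "",
             sprintf("Upregulated ncAA-containing proteins: %d", nrow(up)))
  if (nrow(up)) lines <- c(lines, paste0("  ", up$protein_acc))
  lines <- c(lines,
             sprintf("Downregulated ncAA-containing proteins: %d",
                     nrow(down)))
  if (nrow(down)) lines <- c(lines, paste0("  ", down$protein_acc))
  if (nrow(up) + nrow(down) == 0L) {
    lines <- c(lines, "No significant clusters or sites under the gate.")
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
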