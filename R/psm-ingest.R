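# Ingestion, validation and filtering of open-search PSM tables, and the
# site-frequency bookkeeping behind the cluster table's Freq/Counts columns.

.PSM_COLUMNS <- c(
  "spectrum_id", "sample_id", "condition", "protein_acc", "peptide",
  "site_position", "site_residue", "delta_mass", "score",
  "delta_mods_score", "fdr2d", "fdr_uniq2d"
)

#' Column dialects for PSM exports
#'
#' A dialect maps the canonical column names to the column headers of a
#' particular export. `"generic"` expects the canonical names themselves;
#' `"byonic"` maps a Byonic-style wildcard-search CSV export
#' (`Spectrum`, `Sample`, `Condition`, `Accession`, `Peptide`, `ModPos`,
#' `ModAA`, `DeltaMass`, `Score`, `DeltaModsScore`, `FDR2D`, `FDR_uniq2D`).
#'
#' @param name Dialect name, or a named character vector giving a custom
#'   mapping canonical name -> file column.
#' @return Named character vector mapping canonical -> file column names.
#' @export
psm_dialect <- function(name = "generic") {
  if (is.character(name) && length(name) > 1L) {
    miss <- setdiff(.PSM_COLUMNS, names(name))
    if (length(miss)) stop("custom dialect missing mapping for: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    return(name[.PSM_COLUMNS])
  }
  switch(name,
    generic = stats::setNames(.PSM_COLUMNS, .PSM_COLUMNS),
    byonic = stats::setNames(
      c("Spectrum", "Sample", "Condition", "Accession", "Peptide",
        "ModPos", "ModAA", "DeltaMass", "Score", "DeltaModsScore",
        "FDR2D", "FDR_uniq2D"),
      .PSM_COLUMNS),
    stop("unknown dialect: ", name, call. = FALSE)
  )
}

#' Read an open-search PSM table
#'
#' Reads a TSV or CSV export of a wildcard database search, one row per
#' peptide-spectrum match with its site-level mass shift and search scores.
#' Rows violating the record invariants (site position < 1, non-standard
#' residue code, non-finite numerics, empty condition) are dropped,
#' counted, and reported via a message and the `n_malformed` attribute —
#' never silently. Unmapped extra columns are ignored.
#'
#' @param path Path to the table. Separator is inferred from the extension
#'   (`.csv` -> comma, otherwise tab) unless `sep` is given.
#' @param dialect Dialect name or mapping, see [psm_dialect()].
#' @param sep Field separator override.
#' @return Data frame of validated PSM records with the canonical columns,
#'   attribute `n_malformed` carrying the number of rejected rows.
#' @export
read_psm_table <- function(path, dialect = "generic", sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  map <- psm_dialect(dialect)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty PSM table: ", path, call. = FALSE)
  miss <- setdiff(unname(map), names(raw))
  if (length(miss)) {
    stop("PSM table missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  psms <- stats::setNames(raw[unname(map)], names(map))
  validate_psms(psms, context = path)
}

#' Validate PSM records already in memory
#'
#' Applies the row invariants of [read_psm_table()] to a data frame that
#' already has the canonical columns: rejected rows are counted and
#' reported, never silently lost.
#'
#' @param psms PSM data frame with canonical columns.
#' @param context Label used in the rejection message.
#' @return Validated PSM data frame with attribute `n_malformed`.
#' @export
validate_psms <- function(psms, context = "psm table") {
  num_cols <- c("site_position", "delta_mass", "score",
                "delta_mods_score", "fdr2d", "fdr_uniq2d")
  for (cc in num_cols) psms[[cc]] <- suppressWarnings(as.numeric(psms[[cc]]))
  ok <- !is.na(psms$site_position) & psms$site_position >= 1 &
    psms$site_position == round(psms$site_position) &
    psms$site_residue %in% .AMINO_ACIDS &
    !is.na(psms$condition) & nzchar(psms$condition) &
    !is.na(psms$sample_id) & nzchar(as.character(psms$sample_id))
  for (cc in setdiff(num_cols, "site_position")) ok <- ok & is.finite(psms[[cc]])
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    message(sprintf("%s: rejected %d malformed row(s) (rows %s)", context,
                    n_bad, paste(utils::head(which(!ok), 10), collapse = ", ")))
  }
  out <- psms[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- n_bad
  out
}

#' Default PSM filter thresholds
#'
#' Score >= 300, DeltaModsScore >= 10, FDR2D <= 0.01, FDR_uniq2D <= 0.01,
#' and a nonzero delta mass defined as |delta| strictly greater than
#' 0.01 Da.
#'
#' @param min_score,min_delta_mods_score Lower bounds (inclusive).
#' @param max_fdr2d,max_fdr_uniq2d Upper bounds (inclusive).
#' @param min_abs_delta Strict lower bound on |delta mass| in Da.
#' @return Named list of thresholds.
#' @export
default_psm_filter <- function(min_score = 300, min_delta_mods_score = 10,
                               max_fdr2d = 0.01, max_fdr_uniq2d = 0.01,
                               min_abs_delta = 0.01) {
  list(min_score = min_score, min_delta_mods_score = min_delta_mods_score,
       max_fdr2d = max_fdr2d, max_fdr_uniq2d = max_fdr_uniq2d,
       min_abs_delta = min_abs_delta)
}

#' Filter PSM records
#'
#' Keeps exactly the records satisfying all thresholds. Boundary semantics:
#' scores are inclusive lower bounds, FDRs inclusive upper bounds, and the
#' nonzero-delta criterion is strict (`|delta| > min_abs_delta`). The
#' operation is idempotent.
#'
#' @param psms PSM data frame (see [read_psm_table()]).
#' @param thresholds Threshold list, see [default_psm_filter()].
#' @return Filtered PSM data frame.
#' @export
filter_psms <- function(psms, thresholds = default_psm_filter()) {
  keep <- psms$score >= thresholds$min_score &
    psms$delta_mods_score >= thresholds$min_delta_mods_score &
    psms$fdr2d <= thresholds$max_fdr2d &
    psms$fdr_uniq2d <= thresholds$max_fdr_uniq2d &
    abs(psms$delta_mass) > thresholds$min_abs_delta
  out <- psms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract delta-mass observations from filtered PSMs
#'
#' One observation per PSM site: the protein residue, its observed delta
#' mass, and the delta rounded (half-even) to four decimals — the rounding
#' is applied once here, so downstream occurrence tallies are
#' deterministic.
#'
#' @param psms Filtered PSM data frame.
#' @return Data frame with columns `protein_acc`, `site_position`,
#'   `site_residue`, `delta_mass`, `delta_rounded`, `sample_id`,
#'   `condition`.
#' @export
delta_observations <- function(psms) {
  if (nrow(psms) && any(abs(psms$delta_mass) <= 0.01)) {
    stop("delta_observations() expects filtered PSMs (|delta| > 0.01)",
         call. = FALSE)
  }
  data.frame(
    protein_acc = psms$protein_acc,
    site_position = as.integer(psms$site_position),
    site_residue = psms$site_residue,
    delta_mass = psms$delta_mass,
    delta_rounded = round(psms$delta_mass, 4),
    sample_id = as.character(psms$sample_id),
    condition = psms$condition,
    stringsAsFactors = FALSE
  )
}

#' Tally occurrence of rounded delta masses
#'
#' For each 4-decimal delta mass: `counts` is the total number of
#' observations (the number of redundancies) and `freq` the number of
#' distinct modified sites (protein\@position-residue keys) carrying it.
#' Counts summed over all delta masses equal the number of observations.
#'
#' @param observations Observation data frame, see [delta_observations()].
#' @return Data frame `delta_rounded`, `freq`, `counts`, sorted by
#'   decreasing `counts`.
#' @export
#' @examples
#' obs <- data.frame(protein_acc = "A", site_position = c(5, 5, 9),
#'                   site_residue = c("K", "K", "E"),
#'                   delta_mass = 14.0172, delta_rounded = 14.0172,
#'                   sample_id = "s1", condition = "ischemia")
#' tally_frequencies(obs)  # freq 2, counts 3
tally_frequencies <- function(observations) {
  if (nrow(observations) == 0L) {
    return(data.frame(delta_rounded = numeric(0), freq = integer(0),
                      counts = integer(0)))
  }
  key <- format_site_notation(observations$protein_acc,
                              observations$site_position,
                              observations$site_residue)
  tab <- split(key, format(observations$delta_rounded, nsmall = 4, trim = TRUE,
                           scientific = FALSE))
  out <- data.frame(
    delta_rounded = as.numeric(names(tab)),
    freq = vapply(tab, function(k) length(unique(k)), integer(1)),
    counts = lengths(tab),
    row.names = NULL
  )
  out[order(-out$counts, out$delta_rounded), , drop = FALSE]
}

## ---- site notation ----

# accepts both ASCII "-" and the typographic minus U+2212; emits ASCII
.SITE_RE <- "^([A-Za-z0-9_.-]+?)@([0-9]+)([A-Z])(([+−-])([0-9]+(\\.[0-9]+)?))?$"

#' Parse and format site notation
#'
#' Modified sites are written `ACC@PosRes`, optionally with the delta mass
#' appended as a signed decimal: `P02770@431V+14.0172`. Both the ASCII
#' hyphen-minus and the typographic minus sign are accepted on parse; the
#' ASCII form is emitted, and `format_site_notation(parse_site_notation(x))`
#' reproduces `x` for ASCII inputs.
#'
#' @param text A site string.
#' @return `parse_site_notation()`: list with `protein_acc`,
#'   `site_position`, `site_residue`, `delta` (NA when absent).
#' @export
#' @examples
#' parse_site_notation("P02770@431V+14.0172")
parse_site_notation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regexec(.SITE_RE, text)[[1]]
  if (m[1] == -1L) {
    # locate the first offending character for the error message
    at <- regexpr("@", text)
    pos <- if (at == -1L) 1L else as.integer(at)
    stop(sprintf("malformed site notation %s (parse failed at character %d)",
                 dQuote(text), pos), call. = FALSE)
  }
  g <- regmatches(text, regexec(.SITE_RE, text))[[1]]
  delta <- NA_real_
  if (nzchar(g[5])) {
    sign <- if (g[6] == "+") 1 else -1
    delta <- sign * as.numeric(g[7])
  }
  list(protein_acc = g[2], site_position = as.integer(g[3]),
       site_residue = g[4], delta = delta)
}

#' @rdname parse_site_notation
#' @param protein_acc,site_position,site_residue Site components
#'   (vectorized).
#' @param delta Optional delta mass to append, `NA` for none.
#' @param digits Decimals used for the delta suffix (default 4).
#' @export
format_site_notation <- function(protein_acc, site_position, site_residue,
                                 delta = NA, digits = 4) {
  base <- paste0(protein_acc, "@", site_position, site_residue)
  suffix <- ifelse(is.na(delta), "",
                   sprintf(paste0("%+.", digits, "f"), delta))
  paste0(base, suffix)
}
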