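# Independent oracles used across tests. Each is derived by a different
# route than the implementation it checks.

# Standard genetic code rebuilt from the classic codon-table string
# (b1 major, then b2, then b3; bases ordered T, C, A, G), independent of
# the table hard-coded in the package.
oracle_genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aa, codons)
}

# Brute-force reachability over all 61 x 61 sense-codon pairs.
oracle_reachability_matrix <- function() {
  code <- oracle_genetic_code()
  sense <- code[code != "*"]
  aas <- sort(unique(sense))
  m <- matrix(FALSE, length(aas), length(aas), dimnames = list(aas, aas))
  split_codons <- strsplit(names(sense), "")
  for (i in seq_along(sense)) {
    for (j in seq_along(sense)) {
      if (sense[i] == sense[j]) next
      if (sum(split_codons[[i]] != split_codons[[j]]) == 1L) {
        m[sense[i], sense[j]] <- TRUE
      }
    }
  }
  m
}

# Exact permutation p-value for a 3-vs-3 two-sample comparison: all
# choose(6, 3) = 20 group assignments, statistic = |difference of means|.
perm_test_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  obs <- abs(mean(x) - mean(y))
  splits <- utils::combn(length(pooled), n)
  stats <- apply(splits, 2, function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  mean(stats >= obs - 1e-12)
}

# Element masses restated independently for catalog arithmetic checks.
oracle_element_masses <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
                           O = 15.9949146221, S = 31.97207069)

# A small hand-checkable PSM fixture in the generic dialect.
make_psm_fixture <- function(n = 5, delta = 14.0172, score = 400,
                             dms = 20, fdr = 0.005, residue = "V",
                             condition = "ischemia", sample_id = "case1",
                             position = seq_len(n) + 10) {
  data.frame(
    spectrum_id = sprintf("fx%03d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    condition = rep_len(condition, n),
    protein_acc = rep_len("P02770", n),
    peptide = rep_len("PEPTIDEK", n),
    site_position = rep_len(position, n),
    site_residue = rep_len(residue, n),
    delta_mass = rep_len(delta, n),
    score = rep_len(score, n),
    delta_mods_score = rep_len(dms, n),
    fdr2d = rep_len(fdr, n),
    fdr_uniq2d = rep_len(fdr, n),
    stringsAsFactors = FALSE
  )
}

write_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}
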