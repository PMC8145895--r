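# Monoisotopic mass constants and the candidate-chemistry catalog used to
# annotate delta-mass clusters: PTMs, adducts, losses, all 380 amino-acid
# substitutions, and single-nucleotide codon reachability.

# Monoisotopic masses, >= 6 decimals so 4-decimal catalog values are exact.
.ELEMENT_MASSES <- c(
  H = 1.007825,
  C = 12.000000,
  N = 14.003074,
  O = 15.994915,
  S = 31.972071
)

# Elemental composition of the 20 standard amino-acid *residues*
# (free amino acid minus H2O), rows H,C,N,O,S.
.RESIDUE_FORMULAS <- {
  f <- rbind(
    G = c(3, 2, 1, 1, 0),
    A = c(5, 3, 1, 1, 0),
    S = c(5, 3, 1, 2, 0),
    P = c(7, 5, 1, 1, 0),
    V = c(9, 5, 1, 1, 0),
    T = c(7, 4, 1, 2, 0),
    C = c(5, 3, 1, 1, 1),
    L = c(11, 6, 1, 1, 0),
    I = c(11, 6, 1, 1, 0),
    N = c(6, 4, 2, 2, 0),
    D = c(5, 4, 1, 3, 0),
    Q = c(8, 5, 2, 2, 0),
    K = c(12, 6, 2, 1, 0),
    E = c(7, 5, 1, 3, 0),
    M = c(9, 5, 1, 1, 1),
    H = c(7, 6, 3, 1, 0),
    F = c(9, 9, 1, 1, 0),
    R = c(12, 6, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    W = c(10, 11, 2, 1, 0)
  )
  colnames(f) <- c("H", "C", "N", "O", "S")
  f
}

.AMINO_ACIDS <- rownames(.RESIDUE_FORMULAS)

#' Monoisotopic element masses
#'
#' Returns the monoisotopic masses (Da) of the elements underlying every
#' catalog mass: H, C, N, O, S. Carbon is exactly 12 Da by definition of
#' the dalton.
#'
#' @return Named numeric vector of monoisotopic masses in Da.
#' @export
#' @examples
#' element_masses()[["C"]]  # 12
element_masses <- function() .ELEMENT_MASSES

#' Monoisotopic residue masses of the 20 standard amino acids
#'
#' Residue masses (peptide-bond residues, i.e. the free amino acid minus
#' water), computed from the elemental formulas and [element_masses()].
#' Isoleucine and leucine are isomeric and share a mass.
#'
#' @return Named numeric vector of length 20, names are one-letter codes.
#' @export
residue_masses <- function() {
  drop(.RESIDUE_FORMULAS %*% .ELEMENT_MASSES[colnames(.RESIDUE_FORMULAS)])
}

#' Monoisotopic mass of one residue
#'
#' @param aa One-letter code of a standard amino acid.
#' @return Residue mass in Da.
#' @export
#' @examples
#' residue_mass("G")  # 57.02146
residue_mass <- function(aa) {
  if (length(aa) != 1L || !is.character(aa) || !(aa %in% .AMINO_ACIDS)) {
    stop("unknown amino acid code: ", deparse(aa), call. = FALSE)
  }
  residue_masses()[[aa]]
}

#' Mass of a signed elemental formula
#'
#' Formulas are written as element symbols each followed by a signed integer
#' count, e.g. `"C1H2"` (methylation, +CH2) or `"H-2S-1"` (loss of H2S).
#'
#' @param formula Formula string; `NA` returns `NA`.
#' @return Monoisotopic mass change in Da.
#' @export
#' @examples
#' formula_mass("C1H2")    #  14.01565
#' formula_mass("H-2S-1")  # -33.987721
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- gregexpr("([A-Z][a-z]?)(-?[0-9]+)", f)[[1]]
    if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(f)) {
      stop("malformed formula: ", f, call. = FALSE)
    }
    parts <- regmatches(f, gregexpr("([A-Z][a-z]?)(-?[0-9]+)", f))[[1]]
    el <- sub("-?[0-9]+$", "", parts)
    n <- as.integer(sub("^[A-Z][a-z]?", "", parts))
    unknown <- setdiff(el, names(.ELEMENT_MASSES))
    if (length(unknown)) stop("unknown element: ", unknown[1], call. = FALSE)
    sum(.ELEMENT_MASSES[el] * n)
  }, numeric(1), USE.NAMES = FALSE)
}

# signed formula string for the elemental difference b - a (residues)
.residue_formula_diff <- function(a, b) {
  d <- .RESIDUE_FORMULAS[b, ] - .RESIDUE_FORMULAS[a, ]
  d <- d[d != 0]
  if (!length(d)) return("")
  paste0(names(d), d, collapse = "")
}

.new_catalog <- function(name, class, delta_mass, formula, targets, source) {
  data.frame(
    name = name, class = class, delta_mass = delta_mass,
    formula = formula, targets = targets, source = source,
    stringsAsFactors = FALSE
  )
}

#' All ordered amino-acid substitution chemistries
#'
#' One record per ordered pair (a, b), a != b, with
#' `delta_mass = mass(b) - mass(a)`. Pairs indistinguishable by mass
#' (targets I vs L) are retained as separate records but share a rounded
#' mass. The `targets` field is the source residue (the residue at which
#' such a delta would be observed).
#'
#' @return Data frame of 380 modification records with columns
#'   `name`, `class`, `delta_mass`, `formula`, `targets`, `source`.
#' @export
#' @examples
#' s <- substitution_deltas()
#' round(s$delta_mass[s$name == "G>A"], 4)  # 14.0156
substitution_deltas <- function() {
  rm <- residue_masses()
  pairs <- expand.grid(to = .AMINO_ACIDS, from = .AMINO_ACIDS,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, c("from", "to")]
  cat <- .new_catalog(
    name = paste0(pairs$from, ">", pairs$to),
    class = "substitution",
    delta_mass = rm[pairs$to] - rm[pairs$from],
    formula = mapply(.residue_formula_diff, pairs$from, pairs$to,
                     USE.NAMES = FALSE),
    targets = pairs$from,
    source = "builtin"
  )
  rownames(cat) <- NULL
  cat
}

# The non-substitution chemistries of the bundled catalog. Where a standard
# elemental formula exists it is stored and the mass derived from it;
# aminoethylbenzene-sulfonylation is carried by mass only.
.builtin_chemistries <- function() {
  chem <- .new_catalog(
    name = c(
      "Methylation", "+Carbon", "Aminoethylbenzene-sulfonylation",
      "C>deHA (H2S loss)", "Formylation", "Arg addition",
      "Deamination, pyroglutamate", "Glutathione disulfide",
      "Acetylation", "Dioxidation", "Didehydro (-2H)", "Carboxylation"
    ),
    class = c(
      "PTM", "adduct", "adduct",
      "loss", "PTM", "adduct",
      "loss", "PTM",
      "PTM", "PTM", "loss", "PTM"
    ),
    delta_mass = NA_real_,
    formula = c(
      "C1H2", "C1", NA,
      "H-2S-1", "C1O1", "C6H12N4O1",
      "N-1H-3", "C10H15N3O6S1",
      "C2H2O1", "O2", "H-2", "C1O2"
    ),
    targets = c(
      "any", "any", "any",
      "C", "any", "any",
      "N,Q,K,R", "C",
      "any", "any", "any", "any"
    ),
    source = "builtin"
  )
  chem$delta_mass <- ifelse(is.na(chem$formula), 183.0354,
                            formula_mass(chem$formula))
  chem
}

#' The bundled candidate-chemistry catalog
#'
#' The static modification catalog used to annotate delta-mass clusters:
#' twelve curated chemistries (methylation, formylation, acetylation,
#' dioxidation, carboxylation, carbon and arginine adducts,
#' aminoethylbenzene-sulfonylation, glutathione disulfide, deamination,
#' didehydrogenation, and loss of H2S from cysteine yielding
#' dehydroalanine) plus, optionally, all 380 amino-acid substitutions.
#' It stands in for live queries against modification databases such as
#' UniMod, RESID, ExPASy and ABRF.
#'
#' Masses are derived from [element_masses()] where a formula exists and
#' agree with it within 1e-6 Da. Display rounding is round-half-even to
#' 4 decimals; boundary values (methylation, CH2 = 14.01565 Da) may print
#' as 14.0156 or 14.0157 depending on constant precision, so comparisons
#' always use a mass tolerance, never string equality.
#'
#' @param substitutions Include the 380 substitution records (default TRUE).
#' @return Data frame of modification records (see [substitution_deltas()]
#'   for the columns).
#' @export
builtin_catalog <- function(substitutions = TRUE) {
  cat <- .builtin_chemistries()
  if (substitutions) cat <- rbind(cat, substitution_deltas())
  rownames(cat) <- NULL
  cat
}

#' Read / write / merge catalog TSVs
#'
#' Catalogs are plain TSVs with columns `name`, `class`, `delta_mass`,
#' `formula`, `targets`, `source`. On read, every record carrying a formula
#' is checked against [element_masses()] (tolerance 1e-6 Da).
#'
#' @param path File path.
#' @param catalog A catalog data frame.
#' @param ... Further catalogs to merge after `catalog`.
#' @return `read_catalog()` and `merge_catalogs()` return a catalog data
#'   frame; `write_catalog()` returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           na.strings = c("NA", ""))
  need <- c("name", "class", "delta_mass", "formula", "targets", "source")
  miss <- setdiff(need, names(cat))
  if (length(miss)) stop("catalog missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  validate_catalog(cat[need])
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_catalog
#' @export
merge_catalogs <- function(catalog, ...) {
  merged <- do.call(rbind, c(list(catalog), list(...)))
  merged <- merged[!duplicated(merged[c("name", "class", "targets")]), ]
  rownames(merged) <- NULL
  validate_catalog(merged)
}

# formula-vs-mass consistency check; returns the catalog or stops
validate_catalog <- function(catalog) {
  has_f <- !is.na(catalog$formula) & nzchar(catalog$formula)
  if (any(has_f)) {
    fm <- formula_mass(catalog$formula[has_f])
    bad <- abs(fm - catalog$delta_mass[has_f]) > 1e-6
    if (any(bad)) {
      stop("catalog record(s) inconsistent with element masses: ",
           paste(catalog$name[has_f][bad], collapse = ", "), call. = FALSE)
    }
  }
  catalog
}

## ---- standard genetic code and codon reachability ----

# bases ordered T, C, A, G so codon lists come out in codon-table order
# (this makes the V -> I witness pair (GTT, ATT))
.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Standard genetic code
#'
#' @return Named character vector mapping the 64 codons (DNA alphabet) to
#'   one-letter amino-acid codes, `"*"` for stop.
#' @export
genetic_code <- function() .GENETIC_CODE

.codons_for <- function(aa) names(.GENETIC_CODE)[.GENETIC_CODE == aa]

.hamming1 <- function(c1, c2) {
  sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]]) == 1L
}

#' Single-nucleotide reachability of an amino-acid substitution
#'
#' Tests whether a substitution `aa_from -> aa_to` can arise from a missense
#' point mutation, i.e. whether some codon of `aa_from` differs in exactly
#' one nucleotide from some codon of `aa_to` under the standard genetic
#' code. Used to decide whether a mass-matched substitution could be
#' genomic rather than post-translational.
#'
#' @param aa_from,aa_to One-letter codes of standard amino acids.
#' @return List with `reachable` (logical) and `witness` (character vector
#'   of one from/to codon pair, or `character(0)`). `aa_from == aa_to` is
#'   defined as not reachable.
#' @export
#' @examples
#' snp_reachable("V", "I")$witness  # "GTT" "ATT"
snp_reachable <- function(aa_from, aa_to) {
  for (aa in c(aa_from, aa_to)) {
    if (length(aa) != 1L || !(aa %in% .AMINO_ACIDS)) {
      stop("not a standard amino acid: ", deparse(aa), call. = FALSE)
    }
  }
  if (aa_from == aa_to) {
    return(list(reachable = FALSE, witness = character(0)))
  }
  for (c1 in .codons_for(aa_from)) {
    for (c2 in .codons_for(aa_to)) {
      if (.hamming1(c1, c2)) {
        return(list(reachable = TRUE, witness = c(c1, c2)))
      }
    }
  }
  list(reachable = FALSE, witness = character(0))
}

#' Full 20 x 20 codon-reachability matrix
#'
#' @return Logical matrix; `[a, b]` is `TRUE` iff the substitution a -> b is
#'   reachable by a single-nucleotide change. The diagonal is `FALSE`.
#' @export
snp_reachability_matrix <- function() {
  aas <- .AMINO_ACIDS
  m <- matrix(FALSE, 20, 20, dimnames = list(aas, aas))
  for (a in aas) for (b in aas) {
    if (a != b) m[a, b] <- snp_reachable(a, b)$reachable
  }
  m
}
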