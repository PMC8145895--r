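# Mass constants, the substitution and chemistry catalog, and codon
# reachability.

test_that("residue masses equal the sum of their elemental formulas", {
  # independent recomputation from restated constants
  expect_lt(abs(residue_mass("G") -
                  (2 * 12 + 3 * oracle_element_masses[["H"]] +
                   oracle_element_masses[["N"]] +
                   oracle_element_masses[["O"]])), 1e-4)
  expect_lt(abs(residue_mass("A") -
                  (3 * 12 + 5 * oracle_element_masses[["H"]] +
                   oracle_element_masses[["N"]] +
                   oracle_element_masses[["O"]])), 1e-4)
  expect_equal(round(residue_mass("G"), 5), 57.02146)
  expect_equal(round(residue_mass("A"), 5), 71.03711)
  expect_identical(residue_mass("I"), residue_mass("L"))
  expect_length(residue_masses(), 20L)
  expect_error(residue_mass("B"), "B")
  expect_true(all(element_masses() > 0))
  expect_identical(element_masses()[["C"]], 12)
})

test_that("substitution catalog holds all 380 antisymmetric ordered pairs", {
  s <- substitution_deltas()
  expect_identical(nrow(s), 380L)
  expect_true(all(s$class == "substitution"))
  # antisymmetry: delta(a->b) = -delta(b->a) exactly
  from <- sub(">.*", "", s$name)
  to <- sub(".*>", "", s$name)
  rev_idx <- match(paste0(to, ">", from), s$name)
  expect_true(all(s$delta_mass == -s$delta_mass[rev_idx]))
  expect_lt(abs(s$delta_mass[s$name == "G>A"] - 14.0156), 1e-4)
  # substitutions carry exactly one source residue as target
  expect_true(all(nchar(s$targets) == 1L & s$targets == from))
})

test_that("every formula-bearing catalog record reproduces its mass", {
  cat <- builtin_catalog()
  has_f <- !is.na(cat$formula) & nzchar(cat$formula)
  expect_gt(sum(has_f), 380L)  # all substitutions plus curated chemistries
  expect_true(all(abs(formula_mass(cat$formula[has_f]) -
                        cat$delta_mass[has_f]) < 1e-6))
  # spot values against independent constants
  expect_lt(abs(cat$delta_mass[cat$name == "C>deHA (H2S loss)"] +
                  2 * oracle_element_masses[["H"]] +
                  oracle_element_masses[["S"]]), 1e-4)
  expect_lt(abs(cat$delta_mass[cat$name == "Glutathione disulfide"] -
                  305.0682), 1e-4)
  expect_lt(abs(cat$delta_mass[cat$name == "Methylation"] - 14.0156), 1e-4)
})

test_that("catalog TSV round-trips and merges, rejecting inconsistency", {
  cat <- builtin_catalog(substitutions = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  back <- read_catalog(path)
  expect_equal(back$delta_mass, cat$delta_mass, tolerance = 1e-9)
  expect_identical(back$name, cat$name)

  user <- data.frame(name = "Custom", class = "PTM", delta_mass = 100.5,
                     formula = NA, targets = "any", source = "user")
  merged <- merge_catalogs(cat, user)
  expect_identical(nrow(merged), nrow(cat) + 1L)

  bad <- user
  bad$formula <- "C1H2"  # mass says otherwise
  expect_error(merge_catalogs(cat, bad), "inconsistent")
})

test_that("codon reachability matches exhaustive codon-pair enumeration", {
  v_i <- snp_reachable("V", "I")
  expect_true(v_i$reachable)
  expect_identical(v_i$witness, c("GTT", "ATT"))

  expect_false(snp_reachable("A", "A")$reachable)
  expect_error(snp_reachable("V", "*"), "standard amino acid")
  expect_error(snp_reachable("X", "V"), "standard amino acid")

  m <- snp_reachability_matrix()
  o <- oracle_reachability_matrix()
  expect_identical(m[rownames(o), colnames(o)], o)
  # every witness pair really is a single-nucleotide change coding the
  # right residues
  code <- oracle_genetic_code()
  for (a in c("V", "F", "C", "G")) for (b in c("I", "L", "A", "D")) {
    if (a == b) next
    r <- snp_reachable(a, b)
    if (r$reachable) {
      expect_identical(unname(code[r$witness]), c(a, b))
      expect_identical(sum(strsplit(r$witness[1], "")[[1]] !=
                             strsplit(r$witness[2], "")[[1]]), 1L)
    }
  }
})
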