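# PSM table ingestion, filtering boundary semantics, occurrence tallies
# and the site notation.

test_that("PSM tables read back with validation and malformed-row counts", {
  fx <- make_psm_fixture(5)
  path <- write_fixture(fx)
  psms <- read_psm_table(path)
  expect_identical(nrow(psms), 5L)
  expect_identical(attr(psms, "n_malformed"), 0L)

  # invariant violation: position 0 is rejected and counted, not dropped
  # silently
  bad <- fx
  bad$site_position[2] <- 0
  expect_message(psms2 <- read_psm_table(write_fixture(bad)), "rejected 1")
  expect_identical(nrow(psms2), 4L)
  expect_identical(attr(psms2, "n_malformed"), 1L)

  # unmapped extra columns are ignored
  extra <- cbind(fx, RetentionTime = runif(5))
  expect_identical(nrow(read_psm_table(write_fixture(extra))), 5L)

  # missing mandatory column is named in the error
  broken <- fx[setdiff(names(fx), "delta_mass")]
  expect_error(read_psm_table(write_fixture(broken)), "delta_mass")

  empty <- fx[0, ]
  expect_error(read_psm_table(write_fixture(empty)), "empty")
})

test_that("byonic-style CSV dialect maps to canonical columns", {
  fx <- make_psm_fixture(3)
  names(fx) <- unname(psm_dialect("byonic"))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(fx, path, row.names = FALSE)
  psms <- read_psm_table(path, dialect = "byonic")
  expect_identical(names(psms)[1:3],
                   c("spectrum_id", "sample_id", "condition"))
  expect_identical(nrow(psms), 3L)
})

test_that("filtering applies the documented boundary semantics", {
  # boundary record: score and FDR exactly at threshold are kept,
  # |delta| exactly at 0.01 is not
  at_boundary <- make_psm_fixture(1, delta = 0.02, score = 300, dms = 10,
                                  fdr = 0.01)
  expect_identical(nrow(filter_psms(at_boundary)), 1L)
  at_delta <- make_psm_fixture(1, delta = 0.01)
  expect_identical(nrow(filter_psms(at_delta)), 0L)

  # engineered six-record fixture: hand-applying the thresholds keeps
  # rows 1 and 4 only
  six <- make_psm_fixture(6)
  six$score <- c(400, 299, 400, 300, 400, 400)
  six$delta_mods_score <- c(20, 20, 9, 10, 20, 20)
  six$fdr2d <- c(0.005, 0.005, 0.005, 0.01, 0.02, 0.005)
  six$delta_mass <- c(14.0172, 14.0172, 14.0172, 14.0172, 14.0172, 0.005)
  kept <- filter_psms(six)
  expect_identical(kept$spectrum_id, six$spectrum_id[c(1, 4)])

  # idempotence
  expect_identical(filter_psms(kept), kept)
})

test_that("frequency tally separates distinct sites from redundancies", {
  # two sites sharing a rounded delta: 415 + 3 observations
  obs <- delta_observations(rbind(
    make_psm_fixture(415, delta = 14.0172, position = rep(431, 415),
                     residue = "V"),
    make_psm_fixture(3, delta = 14.0172, position = rep(424, 3),
                     residue = "E")
  ))
  tab <- tally_frequencies(obs)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$freq, 2L)
  expect_identical(tab$counts, 418L)

  single <- tally_frequencies(delta_observations(make_psm_fixture(1)))
  expect_identical(single$freq, 1L)
  expect_identical(single$counts, 1L)

  empty <- tally_frequencies(delta_observations(make_psm_fixture(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("counts conservation holds over random observation sets", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    fx <- make_psm_fixture(n, delta = 0, position = sample(1:30, n, TRUE))
    fx$delta_mass <- sample(c(14.0172, -33.9858, 42.0117), n, TRUE) +
      sample(c(0, 1e-5), n, TRUE)
    obs <- delta_observations(fx)
    tab <- tally_frequencies(obs)
    expect_identical(sum(tab$counts), n)
    # freq never exceeds counts
    expect_true(all(tab$freq <= tab$counts))
  }
})

test_that("site notation parses published forms and round-trips", {
  p <- parse_site_notation("P02770@431V+14.0172")
  expect_identical(p$protein_acc, "P02770")
  expect_identical(p$site_position, 431L)
  expect_identical(p$site_residue, "V")
  expect_equal(p$delta, 14.0172)

  # typographic minus (U+2212) accepted on parse
  p2 <- parse_site_notation("Q64122@109C−33.9858")
  expect_equal(p2$delta, -33.9858)
  expect_identical(p2$site_residue, "C")

  expect_true(is.na(parse_site_notation("P02770@431V")$delta))
  expect_error(parse_site_notation("P02770-431V"), "malformed")
  expect_error(parse_site_notation("@12V"), "malformed")

  set.seed(7)
  for (i in 1:100) {
    x <- format_site_notation(
      paste0("P", sample(10000:99999, 1)),
      sample(1:2000, 1),
      sample(c("A", "C", "V", "K", "E"), 1),
      delta = round(runif(1, -200, 1000), 4)
    )
    p <- parse_site_notation(x)
    expect_identical(
      format_site_notation(p$protein_acc, p$site_position,
                           p$site_residue, p$delta), x)
  }
})
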