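# Signed ratios, the spectral-count t-test against a permutation oracle,
# the significance gate and protein aggregation.

test_that("signed ratio follows the pseudocount fold-change convention", {
  expect_identical(signed_ratio(4, 4), 1)
  expect_equal(signed_ratio(8, 2, pseudocount = 0.5), 3.4)
  expect_equal(signed_ratio(2, 8, pseudocount = 0.5), -3.4)

  set.seed(21)
  a <- runif(200, 0, 50)
  b <- runif(200, 0, 50)
  r_ab <- signed_ratio(a, b)
  r_ba <- signed_ratio(b, a)
  uneq <- abs(a - b) > 1e-9
  expect_equal(r_ab[uneq], -r_ba[uneq])
  expect_true(all(abs(r_ab) >= 1))
})

test_that("site test matches a closed-form view and handles degeneracy", {
  expect_identical(as.numeric(site_test(c(3, 3, 3), c(3, 3, 3))), 1)
  expect_lt(site_test(c(10, 11, 9), c(1, 2, 1)), 0.01)

  p0 <- site_test(c(5, 5, 5), c(2, 2, 2))
  expect_identical(as.numeric(p0), 0)
  expect_true(attr(p0, "degenerate"))

  # normalizers rescale to the count scale
  p <- site_test(c(10, 11, 9), c(1, 2, 1),
                 normalizers = list(case = c(100, 100, 100),
                                    control = c(100, 100, 100)))
  expect_equal(as.numeric(p), site_test(c(10, 11, 9), c(1, 2, 1)))
})

test_that("t-test p-values track the exact permutation oracle", {
  # the exact 3-vs-3 permutation distribution has 20 arrangements, so its
  # p-values move in steps of 0.05 (coarser still under count ties);
  # pointwise agreement with the continuous t p-value cannot beat that
  # granularity, but the two must order fixtures the same way and agree
  # on average
  set.seed(31)
  ps <- t(replicate(50, {
    repeat {
      x <- rpois(3, sample(3:15, 1)) + runif(3, 0, 0.01)
      y <- rpois(3, sample(3:15, 1)) + runif(3, 0, 0.01)
      if (var(x) > 0 || var(y) > 0) break
    }
    c(as.numeric(site_test(x, y)), perm_test_p(x, y))
  }))
  expect_gt(cor(ps[, 1], ps[, 2], method = "spearman"), 0.8)
  expect_lt(mean(abs(ps[, 1] - ps[, 2])), 0.1)
})

test_that("planted regulated sites are called and nulls are not", {
  # ten 4-fold-up sites and ten null sites, 3 vs 3, low noise
  mods <- data.frame(
    name = c("up_mod", "null_mod"),
    delta_mass = c(14.01565, 42.010565),
    residue = c("V", "S"),
    n_sites = 10L, mean_count = 5, fold_change = c(4, 1),
    stringsAsFactors = FALSE
  )
  cfg <- synthetic_config(seed = 8, planted_mods = mods, count_noise = 0.1,
                          background_rate = 0.01, fail_rate = 0)
  gen <- generate_psm_data(cfg)
  obs <- delta_observations(filter_psms(validate_psms(gen$psms)))
  cl <- cluster_deltas(obs, seed = 8)
  sites <- call_significance(obs, cl)
  rec <- score_recovery(cl, gen, sites)
  expect_gte(rec$sensitivity, 0.8)
  expect_lte(rec$false_call_rate, 0.1)
})

test_that("swapping condition labels maps up to down and keeps p-values", {
  gen <- generate_psm_data(synthetic_config(seed = 12))
  obs <- delta_observations(filter_psms(validate_psms(gen$psms)))
  cl <- cluster_deltas(obs, seed = 12)
  fwd <- call_significance(obs, cl)
  rev <- call_significance(obs, cl,
                           condition_map = c(case = "control",
                                             control = "ischemia"))
  key <- function(d) paste(d$site, d$cluster_id)
  idx <- match(key(fwd), key(rev))
  expect_false(anyNA(idx))
  expect_equal(fwd$p_value, rev$p_value[idx])
  expect_identical(fwd$direction == "up", rev$direction[idx] == "down")
  expect_identical(fwd$direction == "down", rev$direction[idx] == "up")
  uneq <- abs(fwd$mean_case - fwd$mean_control) > 1e-12
  expect_equal(fwd$ratio[uneq], -rev$ratio[idx][uneq], tolerance = 1e-9)
})

test_that("sites aggregate to per-direction protein lists", {
  sites <- data.frame(
    protein_acc = c("P1", "P1", "P2"),
    site = c("P1@5K", "P1@9E", "P2@3C"),
    direction = c("up", "up", "down"),
    stringsAsFactors = FALSE
  )
  pl <- aggregate_proteins(sites)
  expect_identical(pl$up$protein_acc, "P1")
  expect_identical(pl$up$n_sites, 2L)
  expect_identical(pl$down$protein_acc, "P2")

  # a protein with sites in both directions appears in both lists
  both <- rbind(sites, data.frame(protein_acc = "P1", site = "P1@2C",
                                  direction = "down"))
  pl2 <- aggregate_proteins(both)
  expect_true("P1" %in% pl2$up$protein_acc)
  expect_true("P1" %in% pl2$down$protein_acc)

  none <- aggregate_proteins(sites[0, ])
  expect_identical(nrow(none$up), 0L)
  expect_identical(nrow(none$down), 0L)
})
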