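# Windowing, per-window mixture fitting, Gaussian regression and the
# clustering pipeline.

test_that("window assignment is the half-open 1-Da partition", {
  expect_identical(assign_window(14.0172), 14L)
  expect_identical(assign_window(-0.49), 0L)
  expect_identical(assign_window(14.5), 15L)  # upper edge belongs upward
  expect_identical(assign_window(-0.5), 0L)
  expect_identical(assign_window(c(-201, 1000.7)),
                   c(NA_integer_, NA_integer_))
  # partition property: every in-range delta falls in exactly the window
  # whose bounds contain it
  set.seed(11)
  d <- runif(500, -200.5, 1000.5 - 1e-9)
  w <- assign_window(d)
  expect_true(all(d >= w - 0.5 & d < w + 0.5))
})

test_that("a single planted Gaussian is recovered as one cluster", {
  set.seed(101)
  x <- rnorm(500, 0.9840, 0.003)
  comps <- fit_window(x)
  expect_length(comps, 1L)
  expect_lt(abs(comps[[1]]$mu - 0.9840), 3 * 0.003 / sqrt(500))
  expect_identical(sort(comps[[1]]$members), seq_along(x))
})

test_that("two well-separated planted components are both found", {
  set.seed(102)
  x <- c(rnorm(300, 0.9840, 0.003), rnorm(300, 0.0, 0.003))
  comps <- fit_window(x)
  expect_length(comps, 2L)
  mus <- sort(vapply(comps, `[[`, numeric(1), "mu"))
  expect_lt(abs(mus[1] - 0.0), 0.002)
  expect_lt(abs(mus[2] - 0.9840), 0.002)
  # separation exceeds two peak widths
  width <- 2 * sqrt(2 * log(2)) * max(vapply(comps, `[[`, numeric(1),
                                             "sigma"))
  expect_gt(diff(mus), 2 * width)
})

test_that("windows below the minimum size yield no clusters", {
  set.seed(103)
  expect_length(fit_window(rnorm(10, 0.5, 0.003)), 0L)
})

test_that("planted-mean recovery holds across seeds", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    x <- rnorm(n, 0.2512, 0.0025)
    comps <- fit_window(x)
    expect_gte(length(comps), 1L)
    main <- comps[[which.max(vapply(comps, `[[`, integer(1), "size"))]]
    expect_lt(abs(main$mu - 0.2512), 4 * 0.0025 / sqrt(n))
  }
})

test_that("gaussian regression recovers planted peak, SD and fit quality", {
  set.seed(104)
  x <- rnorm(10000, 14.0172, 0.002)
  fit <- gaussian_regression(x)
  expect_identical(fit$flag, "ok")
  expect_lt(abs(fit$mu - 14.0172), 2e-4)
  expect_lt(abs(fit$sigma - 0.002), 5e-4)
  expect_gt(fit$r_squared, 0.9)
  expect_lte(fit$r_squared, 1)
})

test_that("gaussian regression flags non-Gaussian and degenerate input", {
  set.seed(105)
  flat <- runif(2000, 13.5, 14.5)
  fit <- gaussian_regression(flat)
  expect_lt(ifelse(is.na(fit$r_squared), 0, fit$r_squared), 0.5)

  same <- rep(42.0106, 30)
  fit2 <- gaussian_regression(same)
  expect_identical(fit2$flag, "degenerate")
  expect_identical(fit2$mu, 42.0106)
  expect_identical(fit2$sigma, 0)
  expect_true(is.na(fit2$r_squared))

  expect_identical(gaussian_regression(rnorm(4))$flag, "unfit")
})

test_that("the clustering pipeline partitions observations deterministically", {
  gen <- generate_psm_data(synthetic_config(seed = 5))
  obs <- delta_observations(filter_psms(validate_psms(gen$psms)))
  cl <- cluster_deltas(obs, seed = 5)

  # partition: each observation in at most one cluster and the books
  # balance
  expect_identical(length(cl$assignment), nrow(obs))
  sizes <- table(cl$assignment)
  expect_identical(as.integer(sizes[as.character(cl$clusters$cluster_id)]),
                   cl$clusters$size)
  expect_identical(sum(cl$clusters$size) + sum(is.na(cl$assignment)),
                   nrow(obs))
  expect_identical(cl$clusters$counts, cl$clusters$size)
  # sorted by descending size; residue fractions are proper fractions
  expect_true(all(diff(cl$clusters$size) <= 0))
  expect_true(all(vapply(cl$residue_fractions,
                         function(f) abs(sum(f) - 1) < 1e-9, logical(1))))
  expect_true(all(cl$clusters$r_squared >= 0 & cl$clusters$r_squared <= 1,
                  na.rm = TRUE))

  # order invariance: permuting the input rows gives identical clusters
  set.seed(99)
  perm <- sample.int(nrow(obs))
  cl2 <- cluster_deltas(obs[perm, ], seed = 5)
  expect_equal(cl2$clusters$delta_mass, cl$clusters$delta_mass,
               tolerance = 1e-12)
  expect_identical(cl2$clusters$size, cl$clusters$size)
  # membership matches through the permutation
  expect_identical(cl2$assignment, cl$assignment[perm])

  # empty input
  empty <- cluster_deltas(obs[0, ])
  expect_identical(nrow(empty$clusters), 0L)
  expect_length(empty$assignment, 0L)
})

test_that("planted chemistries are recovered with accurate peak masses", {
  gen <- generate_psm_data(synthetic_config(seed = 2))
  obs <- delta_observations(filter_psms(validate_psms(gen$psms)))
  cl <- cluster_deltas(obs, seed = 2)
  planted <- unique(gen$truth_sites$true_delta)
  for (m in planted) {
    expect_true(any(abs(cl$clusters$delta_mass - m) < 0.002))
  }
})

test_that("delta_clusters methods print and summarize without error", {
  gen <- generate_psm_data(synthetic_config(seed = 3))
  obs <- delta_observations(filter_psms(validate_psms(gen$psms)))
  cl <- cluster_deltas(obs, seed = 3)
  expect_output(print(cl), "cluster")
  expect_output(print(summary(cl)), "clusters over")
  w <- cl$clusters$window[1]
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(cl, obs, window = w))
})
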