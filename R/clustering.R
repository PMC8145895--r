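# Delta-mass clustering: 1-Da windowing, per-window Gaussian mixture
# modeling with BIC model selection under peak-shape constraints, and
# Gaussian regression of each cluster's histogram for peak, SD and R^2.

.WINDOW_MIN <- -200L
.WINDOW_MAX <- 1000L

#' Clustering constraints
#'
#' The three constraints applied to mixture components before they are
#' accepted as delta-mass clusters:
#' half-width of a peak (half width at half maximum, `sigma * sqrt(2 ln 2)`)
#' must exceed `min_half_width_ppm` parts per million of `reference_mass_da`;
#' adjacent peaks must be separated by more than
#' `min_peak_separation_widths` peak widths (full width at half maximum);
#' and a cluster must contain at least `min_cluster_size` observations.
#'
#' The referent of the ppm half-width bound is configurable because delta
#' masses near zero make "ppm of the shift" degenerate: the default is
#' 1 ppm of a nominal 1000 Da precursor, i.e. a floor of 0.001 Da.
#'
#' @param min_half_width_ppm Minimum peak half-width, ppm of the reference
#'   mass (default 1).
#' @param reference_mass_da Reference mass for the ppm bound (default
#'   1000 Da, a nominal precursor).
#' @param min_peak_separation_widths Minimum distance between adjacent
#'   peaks in units of the larger peak's FWHM (default 2).
#' @param min_cluster_size Minimum observations per cluster and per window
#'   (default 20).
#' @param max_components Largest number of mixture components tried per
#'   window (default 5).
#' @return Named list of constraints.
#' @export
clustering_constraints <- function(min_half_width_ppm = 1,
                                   reference_mass_da = 1000,
                                   min_peak_separation_widths = 2,
                                   min_cluster_size = 20,
                                   max_components = 5) {
  stopifnot(min_half_width_ppm > 0, reference_mass_da > 0,
            min_peak_separation_widths > 0, min_cluster_size > 0,
            max_components >= 1)
  list(min_half_width_ppm = min_half_width_ppm,
       reference_mass_da = reference_mass_da,
       min_peak_separation_widths = min_peak_separation_widths,
       min_cluster_size = as.integer(min_cluster_size),
       max_components = as.integer(max_components))
}

.half_width_floor <- function(constraints) {
  constraints$min_half_width_ppm * 1e-6 * constraints$reference_mass_da
}

#' Assign a delta mass to its 1-Da window
#'
#' Windows are indexed by integer n from -200 to 1000 and bounded by
#' n - 0.5 (inclusive) and n + 0.5 (exclusive); the half-open upper edge
#' makes the windows a partition. Deltas outside the covered range map to
#' `NA`.
#'
#' @param delta Numeric vector of delta masses (Da).
#' @return Integer vector of window indices (`NA` = out of range).
#' @export
#' @examples
#' assign_window(c(14.0172, -0.49, 14.5))  # 14 0 15
assign_window <- function(delta) {
  n <- as.integer(floor(delta + 0.5))
  n[delta < (.WINDOW_MIN - 0.5) | delta >= (.WINDOW_MAX + 0.5)] <- NA_integer_
  n
}

#' Gaussian mixture clustering of one window
#'
#' Fits univariate Gaussian mixtures with 1 to `max_components` components
#' to the delta masses of one window and selects the number of components
#' by BIC, using the convention BIC = 2 ln L - k ln n in which larger
#' values indicate the stronger model. Observations are assigned to
#' components by maximum responsibility. Components violating the
#' constraints are then discarded: too-narrow peaks are dropped, of two
#' peaks closer than the separation bound the smaller is dropped, and
#' undersized components are dropped. Windows with fewer than
#' `min_cluster_size` observations yield no clusters.
#'
#' @param deltas Numeric vector of delta masses in one window.
#' @param constraints See [clustering_constraints()].
#' @return List of components, each a list with `mu`, `sigma`, `members`
#'   (indices into `deltas`), `size`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_window <- function(deltas, constraints = clustering_constraints()) {
  n <- length(deltas)
  if (n < constraints$min_cluster_size) return(list())

  # sort for order invariance; map assignments back through the order
  ord <- order(deltas)
  x <- deltas[ord]

  if (stats::sd(x) < 1e-12) {
    comps <- list(list(mu = x[1], sigma = 0, members = seq_len(n),
                       size = n))
  } else {
    gmax <- min(constraints$max_components, max(1L, floor(n / 2L)))
    fit <- tryCatch(
      mclust::Mclust(x, G = seq_len(gmax), modelNames = c("V", "E"),
                     verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) {
      warning("mixture fit failed for a window (n = ", n, "); skipped")
      return(list())
    }
    mu <- fit$parameters$mean
    sigmasq <- fit$parameters$variance$sigmasq
    if (length(sigmasq) == 1L) sigmasq <- rep(sigmasq, fit$G)
    sigma <- sqrt(pmax(sigmasq, 0))
    cls <- fit$classification
    comps <- lapply(seq_len(fit$G), function(k) {
      idx <- which(cls == k)
      list(mu = unname(mu[k]), sigma = unname(sigma[k]),
           members = idx, size = length(idx))
    })
  }

  comps <- .apply_constraints(comps, constraints)
  # map member indices back to the caller's order
  lapply(comps, function(cp) {
    cp$members <- sort(ord[cp$members])
    cp
  })
}

# constraint enforcement on fitted components (members indexed in sorted x)
.apply_constraints <- function(comps, constraints) {
  comps <- Filter(function(cp) {
    is.finite(cp$mu) && is.finite(cp$sigma) && cp$size > 0L
  }, comps)
  if (!length(comps)) return(comps)
  hw_floor <- .half_width_floor(constraints)
  hw <- function(cp) cp$sigma * sqrt(2 * log(2))
  # (1) peak half-width bound; zero-sigma degenerate spikes are kept only
  # if every member is identical (handled upstream as a single component)
  comps <- Filter(function(cp) cp$sigma == 0 || hw(cp) > hw_floor, comps)
  # (2) peak separation: peaks closer than min_peak_separation_widths
  # FWHMs are not distinct clusters — merge the pair (pooled moments)
  # and repeat until stable, so no observations are lost to an
  # over-fitted split
  repeat {
    if (length(comps) < 2L) break
    comps <- comps[order(vapply(comps, `[[`, numeric(1), "mu"))]
    merged <- FALSE
    for (i in seq_len(length(comps) - 1L)) {
      a <- comps[[i]]; b <- comps[[i + 1L]]
      width <- 2 * sqrt(2 * log(2)) * max(a$sigma, b$sigma)
      if (isTRUE((b$mu - a$mu) <=
                   constraints$min_peak_separation_widths * width)) {
        n_ab <- a$size + b$size
        mu_ab <- (a$size * a$mu + b$size * b$mu) / n_ab
        var_ab <- (a$size * (a$sigma^2 + (a$mu - mu_ab)^2) +
                     b$size * (b$sigma^2 + (b$mu - mu_ab)^2)) / n_ab
        comps[[i]] <- list(mu = mu_ab, sigma = sqrt(var_ab),
                           members = c(a$members, b$members), size = n_ab)
        comps <- comps[-(i + 1L)]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # (3) cluster size
  Filter(function(cp) cp$size >= constraints$min_cluster_size, comps)
}

#' Gaussian regression of a cluster's delta-mass histogram
#'
#' Histograms the member delta masses and fits bin heights by least
#' squares to `A * exp(-(x - mu)^2 / (2 sigma^2))`, giving the peak value
#' (clustered delta mass), the SD, and the goodness of fit
#' `R^2 = 1 - SSres/SStot` over bin heights (clamped to `[0, 1]`).
#' Degenerate inputs are flagged rather than fitted: all-identical members
#' give `mu` = that value, `sigma = 0` and undefined `r_squared`
#' (`flag = "degenerate"`); fewer than 5 members, fewer than 3 non-empty
#' bins, or a non-converging fit give `flag = "unfit"`.
#'
#' @param deltas Member delta masses (Da).
#' @param bin_width Histogram bin width; default
#'   `max(0.0005, range/25)` Da.
#' @return List with `mu`, `sigma`, `r_squared`, `flag`
#'   (`"ok"`, `"degenerate"` or `"unfit"`).
#' @export
gaussian_regression <- function(deltas, bin_width = NULL) {
  n <- length(deltas)
  if (n >= 1L && diff(range(deltas)) < 1e-12) {
    return(list(mu = deltas[1], sigma = 0, r_squared = NA_real_,
                flag = "degenerate"))
  }
  if (n < 5L) {
    return(list(mu = mean(deltas), sigma = stats::sd(deltas),
                r_squared = NA_real_, flag = "unfit"))
  }
  rng <- range(deltas)
  if (is.null(bin_width)) bin_width <- max(0.0005, diff(rng) / 25)
  breaks <- seq(rng[1] - bin_width / 2, rng[2] + bin_width, by = bin_width)
  h <- graphics::hist(deltas, breaks = breaks, plot = FALSE)
  y <- h$counts
  x <- h$mids
  if (sum(y > 0) < 3L) {
    return(list(mu = mean(deltas), sigma = stats::sd(deltas),
                r_squared = NA_real_, flag = "unfit"))
  }
  start <- list(A = max(y), mu = sum(x * y) / sum(y),
                sigma = max(stats::sd(deltas), bin_width / 2))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
                      start = start,
                      lower = c(A = 0, mu = rng[1] - bin_width,
                                sigma = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(mu = mean(deltas), sigma = stats::sd(deltas),
                r_squared = NA_real_, flag = "unfit"))
  }
  cf <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else NA_real_
  list(mu = unname(cf[["mu"]]), sigma = abs(unname(cf[["sigma"]])),
       r_squared = r2, flag = "ok")
}

#' Cluster delta-mass observations across all windows
#'
#' The full clustering stage: observations are partitioned into 1-Da
#' windows, each window is mixture-modeled under the constraints
#' ([fit_window()]), and each surviving component is refit by Gaussian
#' regression ([gaussian_regression()]) for its peak value, SD and R^2.
#' Per-cluster bookkeeping records the total observation count
#' (`counts`, the cluster size), the number of distinct modified sites
#' (`freq`), and the residue composition of the members.
#'
#' The result is deterministic for a given input set and invariant to the
#' input row order; `seed` is recorded in the object for provenance.
#'
#' @param observations Observation data frame, see [delta_observations()].
#' @param constraints See [clustering_constraints()].
#' @param seed Integer recorded in the result metadata.
#' @return An object of class `delta_clusters`: list with
#'   `clusters` (data frame: `cluster_id`, `window`, `delta_mass`, `sd`,
#'   `r_squared`, `fit_flag`, `size`, `freq`, `counts`,
#'   `dominant_residue`, `dominant_residue_fraction`), `assignment`
#'   (integer vector, cluster id per observation, `NA` = unclustered),
#'   `residue_fractions` (list of named vectors), `constraints`, `seed`.
#' @export
cluster_deltas <- function(observations, constraints = clustering_constraints(),
                           seed = NULL) {
  n_obs <- nrow(observations)
  windows <- assign_window(observations$delta_mass)
  n_oor <- sum(is.na(windows) & !is.na(observations$delta_mass))
  if (n_oor > 0L) {
    message("excluded ", n_oor, " observation(s) outside the window range")
  }
  assignment <- rep(NA_integer_, n_obs)
  rows <- list()
  res_fracs <- list()
  cid <- 0L

  for (w in sort(unique(windows[!is.na(windows)]))) {
    idx <- which(!is.na(windows) & windows == w)
    comps <- fit_window(observations$delta_mass[idx], constraints)
    for (cp in comps) {
      cid <- cid + 1L
      members <- idx[cp$members]
      d <- observations$delta_mass[members]
      fit <- gaussian_regression(d)
      mu <- if (fit$flag == "ok" || fit$flag == "degenerate") fit$mu else cp$mu
      sdv <- if (fit$flag == "ok" || fit$flag == "degenerate") fit$sigma else cp$sigma
      keys <- format_site_notation(observations$protein_acc[members],
                                   observations$site_position[members],
                                   observations$site_residue[members])
      rf_tab <- sort(table(observations$site_residue[members]),
                     decreasing = TRUE)
      rf <- stats::setNames(as.numeric(rf_tab) / length(members),
                            names(rf_tab))
      assignment[members] <- cid
      res_fracs[[cid]] <- rf
      rows[[cid]] <- data.frame(
        cluster_id = cid, window = w, delta_mass = mu, sd = sdv,
        r_squared = fit$r_squared, fit_flag = fit$flag,
        size = length(members), freq = length(unique(keys)),
        counts = length(members),
        dominant_residue = names(rf)[1],
        dominant_residue_fraction = unname(rf[1]),
        stringsAsFactors = FALSE
      )
    }
  }

  clusters <- if (length(rows)) do.call(rbind, rows) else data.frame(
    cluster_id = integer(0), window = integer(0), delta_mass = numeric(0),
    sd = numeric(0), r_squared = numeric(0), fit_flag = character(0),
    size = integer(0), freq = integer(0), counts = integer(0),
    dominant_residue = character(0), dominant_residue_fraction = numeric(0),
    stringsAsFactors = FALSE
  )

  # sort by descending size and renumber, remapping the assignments
  if (nrow(clusters)) {
    ord <- order(-clusters$size, clusters$delta_mass)
    clusters <- clusters[ord, , drop = FALSE]
    remap <- stats::setNames(seq_len(nrow(clusters)), clusters$cluster_id)
    assignment <- unname(remap[as.character(assignment)])
    res_fracs <- res_fracs[ord]
    clusters$cluster_id <- seq_len(nrow(clusters))
    rownames(clusters) <- NULL
  }

  structure(
    list(clusters = clusters, assignment = assignment,
         residue_fractions = res_fracs, constraints = constraints,
         seed = seed, n_obs = n_obs),
    class = "delta_clusters"
  )
}

#' @export
print.delta_clusters <- function(x, ...) {
  cat("Delta-mass clustering of", x$n_obs, "observations\n")
  cat(nrow(x$clusters), "cluster(s);",
      sum(!is.na(x$assignment)), "clustered,",
      sum(is.na(x$assignment)), "unclustered\n")
  if (nrow(x$clusters)) {
    show <- utils::head(x$clusters[c("cluster_id", "window", "delta_mass",
                                     "sd", "r_squared", "freq", "counts")], 10)
    show$delta_mass <- round(show$delta_mass, 4)
    show$sd <- signif(show$sd, 3)
    show$r_squared <- round(show$r_squared, 3)
    print(show, row.names = FALSE)
    if (nrow(x$clusters) > 10) cat("... and", nrow(x$clusters) - 10, "more\n")
  }
  invisible(x)
}

#' @export
summary.delta_clusters <- function(object, ...) {
  cl <- object$clusters
  structure(list(
    n_obs = object$n_obs,
    n_clusters = nrow(cl),
    n_clustered = sum(!is.na(object$assignment)),
    n_windows = length(unique(cl$window)),
    median_r_squared = stats::median(cl$r_squared, na.rm = TRUE),
    constraints = object$constraints
  ), class = "summary.delta_clusters")
}

#' @export
print.summary.delta_clusters <- function(x, ...) {
  cat("delta_clusters:", x$n_clusters, "clusters over", x$n_windows,
      "windows;", x$n_clustered, "/", x$n_obs, "observations clustered\n")
  cat("median cluster R-squared:", round(x$median_r_squared, 3), "\n")
  invisible(x)
}

#' Plot the delta-mass histogram of one window with fitted peaks
#'
#' @param x A `delta_clusters` object.
#' @param observations The observation data frame the object was fit to.
#' @param window Window index to plot.
#' @param bin_width Histogram bin width (default 0.0005 Da).
#' @param ... Passed to [graphics::hist()].
#' @export
plot.delta_clusters <- function(x, observations, window, bin_width = 5e-4,
                                ...) {
  widx <- assign_window(observations$delta_mass)
  d <- observations$delta_mass[!is.na(widx) & widx == window]
  if (!length(d)) stop("no observations in window ", window, call. = FALSE)
  h <- graphics::hist(d, breaks = seq(min(d) - bin_width, max(d) + bin_width,
                                      by = bin_width),
                      main = paste("window", window), xlab = "delta mass (Da)",
                      ...)
  cl <- x$clusters[x$clusters$window == window, , drop = FALSE]
  for (i in seq_len(nrow(cl))) {
    if (is.na(cl$sd[i]) || cl$sd[i] <= 0) next
    xs <- seq(cl$delta_mass[i] - 4 * cl$sd[i], cl$delta_mass[i] + 4 * cl$sd[i],
              length.out = 200)
    scale <- cl$size[i] * bin_width / (cl$sd[i] * sqrt(2 * pi))
    graphics::lines(xs, scale * exp(-(xs - cl$delta_mass[i])^2 /
                                      (2 * cl$sd[i]^2)), col = 2, lwd = 2)
  }
  invisible(h)
}
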