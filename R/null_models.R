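#' Monte-Carlo null models for the cell-to-vessel proximity distribution
#'
#' Three computational controls dissect a proximity-distribution shift
#' between two samples:
#'
#' * `null_reposition_observed()` — redistribute the observed cells
#'   uniformly at random over the extravascular ROI pixels of their own
#'   vessel map (tests cell-vessel attraction);
#' * `null_matched_number()` — place a caller-chosen, common number of
#'   random cells on each map (tests whether cell number explains a shift);
#' * `null_all_pixels()` — the exact distance distribution of every
#'   extravascular ROI pixel, i.e. the n -> infinity limit of uniform
#'   random placement (tests whether vessel morphology alone explains a
#'   shift).
#'
#' Random placements are uniform over extravascular pixel centres (not
#' continuous positions), which makes `null_all_pixels()` the exact
#' population law of the other two. Intravascular pixels are excluded by
#' default (cells are extravascular by biology); set
#' `allow_intravascular = TRUE` to sample all ROI pixels.
#'
#' @name null_models
NULL

null_ensemble <- function(model, replicates, n_cells, seed) {
  pooled <- unlist(replicates, use.names = FALSE)
  structure(list(model = model, replicates = replicates,
                 n_cells = n_cells, seed = seed,
                 pooled = pooled,
                 pooled_ecdf = if (length(pooled)) stats::ecdf(pooled) else NULL),
            class = "null_ensemble")
}

# distance values at candidate (extravascular, in-ROI) pixel centres
candidate_distances <- function(mask, roi, allow_intravascular = FALSE) {
  field <- compute_distance_field(mask, roi)
  keep <- field$roi & !is.na(field$values)
  if (!allow_intravascular) keep <- keep & !mask$grid
  d <- field$values[keep]
  if (length(d) == 0) stop("ROI contains no extravascular pixels")
  d
}

#' Reposition the observed cells at random within their own vessel map
#'
#' Each replicate places `length(cells)` points uniformly at random (with
#' replacement) over extravascular ROI pixel centres and records their
#' nearest-vessel distances. Placement at pixel centres means a placed
#' point's distance is exactly the distance-field value at that pixel.
#'
#' @param cells the observed [cell_set()] (supplies the count)
#' @param mask a [vessel_mask()]
#' @param roi an [roi()] (or `NULL` for the whole grid)
#' @param n_reps number of Monte-Carlo replicates (default 1000)
#' @param seed master seed; replicate r uses `derive_seed(seed, r)`
#' @param allow_intravascular also sample vessel pixels
#' @return a `null_ensemble`
#' @export
null_reposition_observed <- function(cells, mask, roi = NULL, n_reps = 1000,
                                     seed = 1, allow_intravascular = FALSE) {
  stopifnot(inherits(cells, "cell_set"))
  null_matched_number(mask, roi, n_cells = length(cells), n_reps = n_reps,
                      seed = seed, allow_intravascular = allow_intravascular,
                      .model = "reposition_observed")
}

#' Place a chosen number of random cells on a vessel map
#'
#' Identical construction to [null_reposition_observed()] but with a
#' caller-chosen cell count, applied with the same count to both maps of a
#' genotype contrast.
#'
#' @inheritParams null_reposition_observed
#' @param n_cells cells per replicate
#' @param .model internal model tag
#' @return a `null_ensemble`
#' @export
null_matched_number <- function(mask, roi = NULL, n_cells, n_reps = 1000,
                                seed = 1, allow_intravascular = FALSE,
                                .model = "matched_number") {
  stopifnot(n_reps >= 1, n_cells >= 0)
  cand <- candidate_distances(mask, roi, allow_intravascular)
  if (n_cells == 0)
    vp_log("n_cells = 0: replicates are empty", level = "WARN")
  reps <- lapply(seq_len(n_reps), function(r) {
    withr::with_seed(derive_seed(seed, r), {
      if (n_cells == 0) numeric(0)
      else cand[sample.int(length(cand), n_cells, replace = TRUE)]
    })
  })
  null_ensemble(.model, reps, n_cells, seed)
}

#' Exact all-extravascular-pixel proximity distribution
#'
#' The single deterministic "replicate" holds the distance value at every
#' extravascular pixel centre inside the ROI: the exact distribution of a
#' uniformly random extravascular position on this map.
#'
#' @param field a `distance_field` from [compute_distance_field()]
#' @param mask the [vessel_mask()] the field came from (to exclude vessel
#'   pixels)
#' @return a `null_ensemble` with one replicate
#' @export
null_all_pixels <- function(field, mask) {
  stopifnot(inherits(field, "distance_field"), inherits(mask, "vessel_mask"))
  keep <- field$roi & !is.na(field$values) & !mask$grid
  d <- field$values[keep]
  if (length(d) == 0) stop("ROI contains no extravascular pixels")
  null_ensemble("all_pixels", list(d), length(d), NA_integer_)
}

#' Compare an observed distance sample with a null ensemble
#'
#' The statistic is the exact two-sample Kolmogorov-Smirnov distance
#' between the observed sample and the ensemble's pooled distances. The
#' Monte-Carlo p-value draws `n_mc` resamples of `length(obs)` points from
#' the pooled null and applies the add-one rule
#' `p = (1 + #\{D_r >= D_obs\}) / (n_mc + 1)`, so the smallest attainable p
#' is `1/(n_mc + 1)`. The mean difference `mean(obs) - mean(null)` is
#' reported alongside (positive = observed cells farther from vessels than
#' the null).
#'
#' @param obs numeric vector of observed distances (um), non-empty
#' @param null a `null_ensemble`
#' @param n_mc Monte-Carlo resamples (>= 19 for p resolution; default 999)
#' @param seed master seed for the resampling
#' @return a `distribution_comparison`: list(ks_statistic, mc_p_value,
#'   mean_diff, n_obs, n_mc)
#' @export
compare_distributions <- function(obs, null, n_mc = 999, seed = 1) {
  stopifnot(length(obs) >= 1, inherits(null, "null_ensemble"))
  if (n_mc < 19) stop("n_mc < 19 gives no useful p-value resolution")
  pooled <- null$pooled
  if (length(unique(pooled)) < 2 && length(unique(obs)) < 2 &&
      !identical(unique(pooled), unique(obs)))
    vp_log("degenerate null ensemble", level = "WARN")
  spooled <- sort(pooled)
  d_obs <- ks_sorted(obs, spooled)
  n <- length(obs)
  exceed <- withr::with_seed(derive_seed(seed, 0), {
    vapply(seq_len(n_mc), function(r) {
      sim <- spooled[sample.int(length(spooled), n, replace = TRUE)]
      ks_sorted(sim, spooled) >= d_obs
    }, logical(1))
  })
  structure(list(ks_statistic = d_obs,
                 mc_p_value = (1 + sum(exceed)) / (n_mc + 1),
                 mean_diff = mean(obs) - mean(pooled),
                 n_obs = n, n_mc = n_mc),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf("KS = %.4f, MC p = %.4g, mean diff = %.2f um (n = %d)\n",
              x$ks_statistic, x$mc_p_value, x$mean_diff, x$n_obs))
  invisible(x)
}

#' Attribute a proximity-distribution shift to attraction, number, or
#' vessel morphology
#'
#' Runs the three computational controls on both maps of a two-sample
#' contrast and reports, in one table:
#'
#' 1. *attraction test* — observed cells vs the repositioning null within
#'    each map (a rejection means the cells sit closer to, or farther
#'    from, vessels than random extravascular positions on their own map);
#' 2. *number test* — the between-map shift of the observed samples
#'    themselves, plus matched-number nulls with a common n on both maps
#'    (pure cell-number differences produce no distribution shift);
#' 3. *morphology test* — the exact all-pixel distance distributions of
#'    the two maps compared against the matched-number sampling null (a
#'    rejection means the vessel architectures alone produce different
#'    proximity laws).
#'
#' The verdict column names the factor(s) whose test rejects at
#' `alpha_level` (default 0.01, deliberately conservative since three
#' tests are read jointly). This decision logic is this package's
#' codification; the choice of statistic and threshold is recorded in the
#' output.
#'
#' @param obs_A,obs_B observed distance samples (um) for maps A and B
#' @param mask_A,mask_B the two [vessel_mask()]s
#' @param roi_A,roi_B the two ROIs (or `NULL`)
#' @param n_reps replicates for the repositioning nulls
#' @param n_mc Monte-Carlo resamples per comparison
#' @param seed master seed
#' @param alpha_level verdict significance level
#' @return a data.frame with one row per test (test, ks, p, mean_diff,
#'   rejected) plus attributes `verdict` (character) and `alpha_level`
#' @export
attribute_shift <- function(obs_A, obs_B, mask_A, mask_B,
                            roi_A = NULL, roi_B = NULL,
                            n_reps = 1000, n_mc = 999, seed = 1,
                            alpha_level = 0.01) {
  field_A <- compute_distance_field(mask_A, roi_A)
  field_B <- compute_distance_field(mask_B, roi_B)
  pix_A <- null_all_pixels(field_A, mask_A)
  pix_B <- null_all_pixels(field_B, mask_B)

  # (i) attraction: obs vs repositioning null, per map. The repositioning
  # null's population is exactly the pixel distribution, so compare
  # against it directly (n_reps controls only the dump of replicates).
  att_A <- compare_distributions(obs_A, pix_A, n_mc, derive_seed(seed, 101))
  att_B <- compare_distributions(obs_B, pix_B, n_mc, derive_seed(seed, 102))

  # (ii) number: is there a between-map shift at all? Two-sample KS of the
  # observed samples with a pooled permutation null.
  shift <- two_sample_mc_test(obs_A, obs_B, n_mc, derive_seed(seed, 103))

  # (iii) morphology: exact pixel populations of the two maps, judged
  # against the sampling noise of a matched-number draw (common n = the
  # smaller observed count), so the morphology verdict is on the same
  # footing as a matched-number experiment.
  n_common <- max(2L, min(length(obs_A), length(obs_B)))
  morph <- population_mc_test(pix_A$pooled, pix_B$pooled, n_common, n_mc,
                              derive_seed(seed, 104))

  tab <- data.frame(
    test = c("attraction_A", "attraction_B", "between_map_shift",
             "morphology"),
    ks = c(att_A$ks_statistic, att_B$ks_statistic, shift$ks, morph$ks),
    p = c(att_A$mc_p_value, att_B$mc_p_value, shift$p, morph$p),
    mean_diff = c(att_A$mean_diff, att_B$mean_diff,
                  mean(obs_A) - mean(obs_B),
                  mean(pix_A$pooled) - mean(pix_B$pooled)),
    stringsAsFactors = FALSE
  )
  tab$rejected <- tab$p < alpha_level

  attraction <- tab$rejected[1] || tab$rejected[2]
  morphology <- tab$rejected[4]
  shifted <- tab$rejected[3]
  verdict <- if (!shifted && !attraction && !morphology) {
    if (length(obs_A) != length(obs_B))
      "no distribution shift; samples differ only in cell number"
    else "no difference detected"
  } else {
    factors <- c(if (attraction) "cell-vessel attraction",
                 if (morphology) "vascular morphology")
    if (length(factors) == 0)
      "distribution shift detected but not attributed"
    else paste(factors, collapse = " + ")
  }
  attr(tab, "verdict") <- verdict
  attr(tab, "alpha_level") <- alpha_level
  tab
}

# Two-sample MC KS test: null = both samples drawn from the pooled data.
two_sample_mc_test <- function(x, y, n_mc, seed) {
  d_obs <- ks_statistic(x, y)
  pool <- sort(c(x, y))
  nx <- length(x); ny <- length(y)
  exceed <- withr::with_seed(seed, {
    vapply(seq_len(n_mc), function(r) {
      sx <- pool[sample.int(length(pool), nx, replace = TRUE)]
      sy <- pool[sample.int(length(pool), ny, replace = TRUE)]
      ks_statistic(sx, sy) >= d_obs
    }, logical(1))
  })
  list(ks = d_obs, p = (1 + sum(exceed)) / (n_mc + 1))
}

# Compare two exact pixel populations: the statistic is the population KS
# distance; the reference null is the KS between two n-sized draws from
# the pooled population (sampling noise at experimental cell counts).
population_mc_test <- function(pop_x, pop_y, n, n_mc, seed) {
  d_obs <- ks_statistic(pop_x, pop_y)
  pool <- sort(c(pop_x, pop_y))
  exceed <- withr::with_seed(seed, {
    vapply(seq_len(n_mc), function(r) {
      sx <- pool[sample.int(length(pool), n, replace = TRUE)]
      sy <- pool[sample.int(length(pool), n, replace = TRUE)]
      ks_statistic(sx, sy) >= d_obs
    }, logical(1))
  })
  list(ks = d_obs, p = (1 + sum(exceed)) / (n_mc + 1))
}

#' Maximum-likelihood fit of a distance-dependent attraction mixture
#'
#' Models observed nearest-vessel distances as draws from the density
#' `p(d) = g(d) * ((1 - alpha) + alpha * exp(-d / lambda) / Z(lambda))`
#' where `g` is the map's all-extravascular-pixel distance law (supplied
#' as a `null_all_pixels()` ensemble from the same map the cells were
#' observed on) and `Z(lambda) = E_g[exp(-d / lambda)]` normalizes the
#' attraction component. Because `g` enters the likelihood only as a
#' constant factor, the fit reduces to maximizing
#' `sum(log((1 - alpha) + alpha * exp(-d_i / lambda) / Z(lambda)))` —
#' no density binning is required. `alpha = 0` recovers uniform random
#' placement; `lambda` is the attraction length scale in um.
#'
#' Optimization: L-BFGS-B on `(alpha, log lambda)` with bounds
#' `alpha in [0, 1]`, `lambda in [0.5, 500] um`, from three starts
#' (`alpha 0.25/0.5/0.75`, `lambda` = median pixel distance). A degenerate
#' pixel law (single-valued `g`) makes `(alpha, lambda)` unidentifiable:
#' the fit is returned unconverged with a warning.
#'
#' The reported `alpha` is the normalized-mixture weight. Because the
#' per-pixel sampling kernel `(1 - a) + a * exp(-d / lambda)` used by
#' [place_cells()] weights the attraction component before normalization,
#' its `a` relates to the mixture weight by
#' `alpha = a Z / (1 - a + a Z)`; the back-converted kernel-scale weight
#' is returned as `alpha_kernel`.
#'
#' @param distances observed distance sample (um)
#' @param pixel_null a `null_ensemble` from [null_all_pixels()] on the same
#'   map
#' @return an `attraction_fit`: list(alpha, lambda, alpha_kernel, loglik,
#'   converged)
#' @export
fit_attraction <- function(distances, pixel_null) {
  stopifnot(length(distances) >= 1, inherits(pixel_null, "null_ensemble"))
  g <- pixel_null$pooled
  if (length(unique(g)) < 2) {
    vp_log("pixel distance law is degenerate; attraction unidentifiable",
           level = "WARN")
    return(structure(list(alpha = NA_real_, lambda = NA_real_,
                          loglik = NA_real_, converged = FALSE),
                     class = "attraction_fit"))
  }
  negll <- function(par) {
    a <- par[1]; lam <- exp(par[2])
    z <- mean(exp(-g / lam))
    w <- (1 - a) + a * exp(-distances / lam) / z
    -sum(log(pmax(w, 1e-300)))
  }
  lam0 <- max(stats::median(g), 1)
  starts <- lapply(c(0.25, 0.5, 0.75), function(a0) c(a0, log(lam0)))
  fits <- lapply(starts, function(p0) {
    tryCatch(stats::optim(p0, negll, method = "L-BFGS-B",
                          lower = c(0, log(0.5)), upper = c(1, log(500))),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    return(structure(list(alpha = NA_real_, lambda = NA_real_,
                          loglik = NA_real_, converged = FALSE),
                     class = "attraction_fit"))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  a_mix <- best$par[1]
  lam_hat <- exp(best$par[2])
  # convert the normalized-mixture weight back to the sampling-kernel
  # weight a_k of p(d) proportional to g(d) * ((1 - a_k) + a_k exp(-d/lam)):
  # a_mix = a_k Z / (1 - a_k + a_k Z)  =>  a_k = a_mix / (Z (1 - a_mix) + a_mix)
  z_hat <- mean(exp(-g / lam_hat))
  structure(list(alpha = a_mix, lambda = lam_hat,
                 alpha_kernel = a_mix / (z_hat * (1 - a_mix) + a_mix),
                 loglik = -best$value, converged = best$convergence == 0),
            class = "attraction_fit")
}

#' @export
print.attraction_fit <- function(x, ...) {
  cat(sprintf("attraction fit: alpha = %.3f, lambda = %.1f um, loglik = %.2f%s\n",
              x$alpha, x$lambda, x$loglik,
              if (isTRUE(x$converged)) "" else " (NOT converged)"))
  invisible(x)
}
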