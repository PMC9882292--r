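#' Run the full genotype-contrast analysis from a configuration
#'
#' Orchestrates, per sample: proximity summary, the three null models,
#' vessel morphometry and (when a junction is given) looping-vessel
#' counts; then per-genotype aggregation (per-sample summaries first, then
#' genotype mean +/- SD across samples) and, for each genotype pair with
#' one sample per genotype, the three-way shift attribution. Writes
#' result tables (CSV), advisory figures (per-cell distance histogram and
#' ECDF overlay with the all-pixel null), and a reproducibility manifest
#' (JSON) whose content is checksum-stable across reruns with the same
#' seed.
#'
#' @param config a list, or the path to a YAML file, with entries:
#'   * `samples`: list of sample entries, each with `genotype`, plus either
#'     in-memory objects (`mask`, `cells`, `roi`, `junction`) or file
#'     paths (`mask_path`, `cells_path`, `roi_path`, `junction_path`);
#'   * `pixel_size` (um/px, used when reading masks from disk; default 1);
#'   * `n_reps`, `n_mc` (Monte-Carlo sizes; defaults 1000, 999);
#'   * `bin_width` (histogram bin, default 5), `band_width` (looping band,
#'     default 50), `core_fraction` (default 0.5);
#'   * `seed` (mandatory), `out_dir` (mandatory).
#' @param make_plots write figures (default TRUE)
#' @return a result bundle: list(per_sample, genotype_summary,
#'   attribution, manifest), invisibly also written under `out_dir`
#' @export
run_pipeline <- function(config, make_plots = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), length(config$samples) >= 1)
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$out_dir)) stop("config must set out_dir")
  seed <- config$seed
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  px <- config$pixel_size %||% 1
  n_reps <- config$n_reps %||% 1000
  n_mc <- config$n_mc %||% 999
  bin_width <- config$bin_width %||% 5
  band_width <- config$band_width %||% 50
  core_fraction <- config$core_fraction %||% 0.5

  stage <- function(name, sample_id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for sample '%s': %s",
                   name, sample_id, conditionMessage(e)), call. = FALSE))
  }

  per_sample <- list()
  loaded <- list()
  for (k in seq_along(config$samples)) {
    sm <- config$samples[[k]]
    sid <- sm[["id"]] %||% paste0("sample", k)
    mask <- stage("load_mask", sid, {
      if (!is.null(sm[["mask"]])) sm[["mask"]]
      else read_mask(sm[["mask_path"]], calibration(px),
                     threshold = sm[["threshold"]] %||% 0)
    })
    cells <- stage("load_cells", sid, {
      if (!is.null(sm[["cells"]])) sm[["cells"]] else read_cells(sm[["cells_path"]])
    })
    sroi <- stage("load_roi", sid, {
      if (!is.null(sm[["roi"]])) sm[["roi"]]
      else if (!is.null(sm[["roi_path"]])) read_roi(sm[["roi_path"]]) else NULL
    })
    junction <- stage("load_junction", sid, {
      if (!is.null(sm[["junction"]])) sm[["junction"]]
      else if (!is.null(sm[["junction_path"]])) read_junction(sm[["junction_path"]])
      else NULL
    })

    field <- stage("distance_field", sid, compute_distance_field(mask, sroi))
    dists <- stage("cell_distances", sid, cell_distances(cells, field, mask))
    summ <- stage("proximity_summary", sid,
                  summarize_distances(dists, bin_width))
    pix <- stage("null_all_pixels", sid, null_all_pixels(field, mask))
    att <- stage("attraction_test", sid,
                 compare_distributions(dists, pix, n_mc,
                                       derive_seed(seed, 10 * k + 1)))
    morpho <- stage("morphometry", sid, vessel_morphometry(mask, sroi))
    looping <- if (!is.null(junction))
      stage("looping", sid,
            looping_vessel_counts(mask, junction, sroi, band_width,
                                  core_fraction))
    else NULL

    loaded[[sid]] <- list(mask = mask, cells = cells, roi = sroi,
                          genotype = sm[["genotype"]] %||% "unknown",
                          distances = dists, pixel_null = pix)
    per_sample[[sid]] <- data.frame(
      sample = sid, genotype = sm[["genotype"]] %||% "unknown",
      n_cells = summ$n, mean_distance_um = summ$mean,
      sd_distance_um = summ$sd,
      attraction_ks = att$ks_statistic, attraction_p = att$mc_p_value,
      area_fraction = morpho$area_fraction,
      perimeter_area_ratio = morpho$perimeter_area_ratio,
      n_components = morpho$n_components,
      looping_core = if (is.null(looping)) NA else looping$core_count,
      looping_annulus = if (is.null(looping)) NA else looping$annulus_count,
      stringsAsFactors = FALSE)
  }
  per_sample_tab <- do.call(rbind, per_sample)
  utils::write.csv(per_sample_tab, file.path(out_dir, "per_sample.csv"),
                   row.names = FALSE)

  agg <- stats::aggregate(
    cbind(mean_distance_um, area_fraction, perimeter_area_ratio) ~ genotype,
    data = per_sample_tab,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  genotype_summary <- data.frame(
    genotype = agg$genotype,
    mean_distance_um = agg$mean_distance_um[, "mean"],
    sd_across_samples = agg$mean_distance_um[, "sd"],
    area_fraction = agg$area_fraction[, "mean"],
    perimeter_area_ratio = agg$perimeter_area_ratio[, "mean"])
  utils::write.csv(genotype_summary,
                   file.path(out_dir, "genotype_summary.csv"),
                   row.names = FALSE)

  genos <- unique(per_sample_tab$genotype)
  attribution <- NULL
  if (length(genos) == 2) {
    by_geno <- split(names(loaded),
                     vapply(loaded, `[[`, character(1), "genotype"))
    if (all(lengths(by_geno) == 1)) {
      a <- loaded[[by_geno[[1]]]]; b <- loaded[[by_geno[[2]]]]
      attribution <- attribute_shift(a$distances, b$distances,
                                     a$mask, b$mask, a$roi, b$roi,
                                     n_reps, n_mc,
                                     derive_seed(seed, 999))
      out_attr <- attribution
      out_attr$verdict <- attr(attribution, "verdict")
      utils::write.csv(out_attr, file.path(out_dir, "attribution.csv"),
                       row.names = FALSE)
    } else {
      vp_log("attribution needs exactly one sample per genotype; skipped",
             level = "WARN")
    }
  }

  if (make_plots) plot_proximity(loaded, out_dir, bin_width)

  input_paths <- unlist(lapply(config$samples, function(sm)
    Filter(is.character,
           sm[intersect(names(sm),
                        c("mask_path", "cells_path", "roi_path",
                          "junction_path"))])), use.names = TRUE)
  manifest <- run_manifest(
    inputs = as.list(input_paths),
    parameters = list(pixel_size = px, n_reps = n_reps, n_mc = n_mc,
                      bin_width = bin_width, band_width = band_width,
                      core_fraction = core_fraction),
    seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(per_sample = per_sample_tab,
                 genotype_summary = genotype_summary,
                 attribution = attribution,
                 manifest = manifest))
}

# Advisory figures: per-cell distance histogram and ECDF overlay with the
# all-extravascular-pixel null of each sample.
plot_proximity <- function(loaded, out_dir, bin_width) {
  dir.create(file.path(out_dir, "plots"), showWarnings = FALSE)
  obs <- do.call(rbind, lapply(names(loaded), function(sid)
    data.frame(sample = sid, genotype = loaded[[sid]]$genotype,
               distance = loaded[[sid]]$distances)))
  p_hist <- ggplot2::ggplot(obs, ggplot2::aes(x = distance, fill = genotype)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "nearest-vessel distance (um)", y = "cells") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "plots", "histogram.png"), p_hist,
                  width = 6, height = 4, dpi = 150)

  nulls <- do.call(rbind, lapply(names(loaded), function(sid)
    data.frame(sample = paste0(sid, " (pixel null)"),
               genotype = loaded[[sid]]$genotype,
               distance = loaded[[sid]]$pixel_null$pooled)))
  both <- rbind(cbind(obs, kind = "observed"),
                cbind(nulls, kind = "all-pixel null"))
  p_ecdf <- ggplot2::ggplot(both, ggplot2::aes(x = distance, colour = sample,
                                               linetype = kind)) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "nearest-vessel distance (um)",
                  y = "cumulative fraction") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out_dir, "plots", "ecdf.png"), p_ecdf,
                  width = 6, height = 4, dpi = 150)
  invisible(NULL)
}
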