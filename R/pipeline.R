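#' Assemble a full study run configuration
#'
#' Collects every stage parameter of the end-to-end pipeline with the
#' acquisition defaults: masking at 1608 cm^-1, Savitzky-Golay window 13 /
#' order 2, 3-sigma significance, +/-2 cm^-1 occurrence tolerance, 100
#' occurrence spectra per ROI, 2000 sampled pixels per ROI, 8 ROIs per
#' class and top-40 feature ranking.
#'
#' @param generator `mirsi_config` for the synthetic study (or `NULL` when
#'   supplying cubes directly to [run_study()]).
#' @param rois_per_class,n_pixels,n_per_roi Study sizes.
#' @param mask_band Masking wavenumber (cm^-1).
#' @param params [derivative_params()].
#' @param tolerance Occurrence matching tolerance (cm^-1).
#' @param n_sigma Peak significance multiple.
#' @param min_fraction Band-consistency threshold for
#'   [count_consistent_bands()].
#' @param bands Reference band table.
#' @param integration_mode `"absorbance"` or `"second_derivative"`.
#' @param pca_components,n_neighbors,min_dist,top_k Discrimination stage
#'   parameters.
#' @param n_embed_per_class Spectra per class used for embedding /
#'   importance.
#' @param run_discriminate Run the classification branch (default TRUE).
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for CSV/JSON artifacts (`NULL` = keep
#'   in memory only).
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = default_config(), rois_per_class = 8,
                       n_pixels = 2000, n_per_roi = 100, mask_band = 1608,
                       params = derivative_params(), tolerance = 2,
                       n_sigma = 3, min_fraction = 0.5,
                       bands = default_band_table(),
                       integration_mode = c("absorbance", "second_derivative"),
                       pca_components = 20, n_neighbors = 15, min_dist = 0.1,
                       top_k = 40, n_embed_per_class = 1000,
                       run_discriminate = TRUE, seed = 0L, out_dir = NULL) {
  structure(list(generator = generator, rois_per_class = rois_per_class,
                 n_pixels = n_pixels, n_per_roi = n_per_roi,
                 mask_band = mask_band, params = params,
                 tolerance = tolerance, n_sigma = n_sigma,
                 min_fraction = min_fraction, bands = bands,
                 integration_mode = match.arg(integration_mode),
                 pca_components = pca_components, n_neighbors = n_neighbors,
                 min_dist = min_dist, top_k = top_k,
                 n_embed_per_class = n_embed_per_class,
                 run_discriminate = run_discriminate,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Validate a run configuration without executing it
#'
#' Collects every invariant violation and suspicious setting as findings
#' (character vector); an empty return means the configuration is clean.
#' Never throws.
#'
#' @param config A `run_config`.
#' @return Character vector of findings (possibly empty).
#' @export
validate_config <- function(config) {
  findings <- character(0)
  note <- function(...) findings <<- c(findings, paste0(...))
  p <- config$params
  if (p$window_length %% 2 != 1) {
    note("SG window length ", p$window_length, " must be odd")
  }
  if (p$window_length < p$poly_order + 2) {
    note("SG window length must be >= poly_order + 2")
  }
  gen <- config$generator
  grid <- if (!is.null(gen)) gen$grid else default_grid()
  if (config$tolerance < grid$step) {
    note("occurrence tolerance ", config$tolerance,
         " cm-1 is below the grid step ", grid$step, " cm-1")
  }
  if (config$mask_band < grid$start || config$mask_band > grid$stop) {
    note("mask band ", config$mask_band, " cm-1 lies outside the grid [",
         grid$start, ", ", grid$stop, "]")
  }
  bad <- config$bands$center < grid$start | config$bands$center > grid$stop
  if (any(bad)) {
    note("band center(s) outside the grid: ",
         paste(config$bands$center[bad], collapse = ", "))
  }
  tg_len <- length(grid$values) - p$trim_low - p$trim_high
  if (tg_len < p$window_length) {
    note("trimming leaves only ", tg_len, " points")
  }
  if (config$n_per_roi > config$n_pixels) {
    note("n_per_roi (", config$n_per_roi, ") exceeds n_pixels (",
         config$n_pixels, ")")
  }
  if (!is.null(gen)) {
    ok <- tryCatch({ validate_generator_config(gen); TRUE },
                   error = function(e) { note(conditionMessage(e)); FALSE })
    if (ok && config$n_pixels >
        0.95 * gen$tissue_fraction * gen$height * gen$width) {
      note("n_pixels (", config$n_pixels,
           ") is close to or above the expected tissue pixel count")
    }
    if (config$n_sigma <= 0) note("n_sigma must be positive")
  }
  findings
}

# Preprocess + sub-band analysis of the cubes of one class: masks, noise
# calibration, pixel sampling, occurrence, ROI-mean integrals.
process_class <- function(cubes, config, seed) {
  stats_list <- list()
  raw_sets <- list()
  roi_means <- list()
  bg_means <- NULL
  for (i in seq_along(cubes)) {
    cube <- cubes[[i]]
    tm <- tissue_mask(cube, config$mask_band)
    bs <- background_stats(cube, tm$mask, config$params,
                           mask_band = tm$mask_band)
    raw <- sample_pixels(cube, tm$mask, config$n_pixels,
                         seed = derive_seed(seed, 7, i), correct = FALSE)
    stats_list[[i]] <- bs
    raw_sets[[i]] <- raw
    roi_means[[i]] <- rubberband_correct(roi_mean_spectrum(raw))$corrected
    bg_means <- rbind(bg_means, bs$background_spectrum$absorbance)
  }
  grid <- cubes[[1]]$grid
  occ <- peak_occurrence(raw_sets, config$bands,
                         sigma = vapply(stats_list, `[[`, 0, "sigma_pixel"),
                         params = config$params, tolerance = config$tolerance,
                         n_per_roi = config$n_per_roi,
                         seed = derive_seed(seed, 11), n_sigma = config$n_sigma,
                         correct = TRUE)
  integrals <- roi_band_integrals(roi_means, config$bands,
                                  mode = config$integration_mode,
                                  params = config$params)
  colnames(integrals) <- vapply(raw_sets, function(s) as.character(s$roi_id), "")
  mean_mat <- t(vapply(roi_means, function(s) s$absorbance,
                       numeric(length(grid$values))))
  arm_mean <- new_spectrum(grid, colMeans(mean_mat))
  # noise scale of the class-arm mean spectrum: derivative of the pooled
  # background mean (same averaging order of magnitude)
  d_bg <- sg_second_derivative(matrix(colMeans(bg_means), nrow = 1),
                               grid$step, config$params)
  list(stats = stats_list, raw_sets = raw_sets, roi_means = roi_means,
       occurrence = occ, integrals = integrals, arm_mean = arm_mean,
       sigma_arm = stats::sd(as.vector(d_bg)))
}

subsample_corrected <- function(set, n, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- sort(sample(nrow(set$matrix), n, replace = FALSE))
  mat <- rubberband_correct_matrix(set$matrix[rows, , drop = FALSE],
                                   set$grid$values)
  spectrum_set(set$grid, mat, set$pixel_ids[rows, ], set$roi_id,
               set$tissue, set$prep)
}

#' Run the full synthetic study pipeline
#'
#' Synthesize (or accept) hyperspectral cubes, preprocess every ROI
#' (tissue mask, background noise calibration, pixel sampling), run the
#' second-derivative sub-band analysis (occurrence tables, consistent band
#' counts, band integrals, FF/FFPE percent reductions), and optionally the
#' classification branch (ROI correlation, PCA/UMAP embedding, per-tissue
#' feature rankings). Fully deterministic for a fixed config seed; when
#' `config$out_dir` is set, all stage tables are written as CSV plus a JSON
#' run report.
#'
#' @param config A [run_config()].
#' @param cubes Optional pre-built list of `mir_cube`s (e.g. read from
#'   ENVI files); by default the generator in the config is run.
#' @return A list of class `run_report`; see details in the package
#'   vignette.
#' @export
run_study <- function(config, cubes = NULL) {
  stopifnot(inherits(config, "run_config"))
  findings <- validate_config(config)
  if (length(findings) > 0) {
    stop("invalid configuration:\n- ", paste(findings, collapse = "\n- "))
  }
  seed <- config$seed
  if (is.null(cubes)) {
    cubes <- simulate_study(config$generator, config$rois_per_class,
                            seed = derive_seed(seed, 1))
  }
  classes <- study_classes()
  keys <- apply(classes, 1, function(r) class_key(r[["tissue"]], r[["prep"]]))
  by_class <- lapply(keys, function(k) {
    sel <- vapply(cubes, function(cb) class_key(cb$tissue, cb$prep) == k, TRUE)
    cubes[sel]
  })
  names(by_class) <- keys
  if (any(vapply(by_class, length, 0L) == 0)) {
    stop("missing cubes for class(es): ",
         paste(keys[vapply(by_class, length, 0L) == 0], collapse = ", "))
  }

  arms <- list()
  for (k in keys) {
    arms[[k]] <- process_class(by_class[[k]], config,
                               seed = derive_seed(seed, 2, match(k, keys)))
  }
  band_counts <- vapply(arms, function(a) {
    count_consistent_bands(a$occurrence, config$min_fraction)
  }, 0L)

  # per-band FF vs FFPE comparison within each tissue
  comparison <- NULL
  for (tissue in TISSUES) {
    iff <- rowMeans(arms[[class_key(tissue, "FF")]]$integrals)
    ipe <- rowMeans(arms[[class_key(tissue, "FFPE")]]$integrals)
    ok <- iff > 0
    comparison <- rbind(comparison, data.frame(
      tissue = tissue, center = config$bands$center,
      assignment = config$bands$assignment,
      integral_ff = iff, integral_ffpe = ipe,
      percent_reduction = ifelse(ok, 100 * (iff - ipe) / iff, NA_real_),
      row.names = NULL))
  }

  discriminate <- NULL
  if (isTRUE(config$run_discriminate)) {
    n_roi_embed <- max(1L, ceiling(config$n_embed_per_class /
                                     config$rois_per_class))
    embed_sets <- list()
    for (k in keys) {
      for (i in seq_along(arms[[k]]$raw_sets)) {
        s <- arms[[k]]$raw_sets[[i]]
        embed_sets[[length(embed_sets) + 1]] <-
          zscore_spectra(subsample_corrected(
            s, min(n_roi_embed, nrow(s$matrix)),
            seed = derive_seed(seed, 5, match(k, keys), i)))
      }
    }
    correlation <- roi_correlation(embed_sets)
    embedding <- embed_spectra(embed_sets, config$pca_components,
                               config$n_neighbors, config$min_dist,
                               seed = derive_seed(seed, 6))
    rankings <- list()
    for (tissue in TISSUES) {
      sel <- vapply(embed_sets, function(s) s$tissue == tissue, TRUE)
      rankings[[tissue]] <- feature_importance(embed_sets[sel],
                                               response = "prep",
                                               top_k = config$top_k)
    }
    rankings$pooled <- feature_importance(embed_sets, response = "prep",
                                          top_k = config$top_k)
    discriminate <- list(correlation = correlation, embedding = embedding,
                         rankings = rankings)
  }

  report <- structure(list(
    band_counts = band_counts,
    occurrence = lapply(arms, `[[`, "occurrence"),
    quantification = lapply(arms, function(a) band_quantification(a$integrals)),
    comparison = comparison,
    arm_means = lapply(arms, `[[`, "arm_mean"),
    sigma_arm = vapply(arms, `[[`, 0, "sigma_arm"),
    n_spectra_per_class = vapply(arms, function(a) {
      sum(vapply(a$raw_sets, function(s) nrow(s$matrix), 0L))
    }, 0L),
    discriminate = discriminate,
    config = config, seed = seed,
    version = as.character(utils::packageVersion("mirspec"))
  ), class = "run_report")
  if (!is.null(config$out_dir)) write_run_outputs(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> consistent bands per class:\n")
  print(x$band_counts)
  amide <- x$comparison[x$comparison$assignment == "Amide I", ]
  cat("Amide I percent reduction (FFPE vs FF):\n")
  print(stats::setNames(round(amide$percent_reduction, 1), amide$tissue))
  invisible(x)
}

write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (k in names(report$occurrence)) {
    utils::write.csv(as.data.frame(unclass(report$occurrence[[k]])),
                     file.path(out_dir, paste0("occurrence_", k, ".csv")))
    utils::write.csv(report$quantification[[k]],
                     file.path(out_dir, paste0("integrals_", k, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(class = names(report$band_counts),
                              consistent_bands = report$band_counts),
                   file.path(out_dir, "band_counts.csv"), row.names = FALSE)
  if (!is.null(report$discriminate)) {
    utils::write.csv(as.data.frame(report$discriminate$correlation),
                     file.path(out_dir, "correlation.csv"))
    emb <- cbind(as.data.frame(report$discriminate$embedding$coordinates),
                 report$discriminate$embedding$labels)
    utils::write.csv(emb, file.path(out_dir, "embedding.csv"),
                     row.names = FALSE)
    for (nm in names(report$discriminate$rankings)) {
      utils::write.csv(report$discriminate$rankings[[nm]],
                       file.path(out_dir, paste0("importance_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  meta <- list(version = report$version, seed = report$seed,
               band_counts = as.list(report$band_counts),
               n_spectra_per_class = as.list(report$n_spectra_per_class))
  jsonlite::write_json(meta, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
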