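#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis in one serializable
#' list. Defaults echo the protocol constants: 2.971 um^2/pixel, fixed
#' threshold 50, 5x5 median, histogram bin widths 60 / 0.1 / 0.02 / 0.02,
#' AE threshold factor 5 with 2 ms dead time.
#'
#' @param pixel_area_um2 image calibration.
#' @param threshold,blur_sigma_px,polarity,connectivity,median_size
#'   segmentation settings, see [segmentation_config()].
#' @param ae_threshold_factor,ae_dead_time_s AE hit detection settings.
#' @param seed integer seed for any stochastic stage.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_area_um2 = 2.971, threshold = 50L,
                            blur_sigma_px = 50, polarity = "dark_objects",
                            connectivity = 8L, median_size = 5L,
                            ae_threshold_factor = 5, ae_dead_time_s = 0.002,
                            seed = 1L) {
  structure(list(pixel_area_um2 = pixel_area_um2, threshold = threshold,
                 blur_sigma_px = blur_sigma_px, polarity = polarity,
                 connectivity = connectivity, median_size = median_size,
                 hist_widths = histogram_spec()$widths,
                 ae_threshold_factor = ae_threshold_factor,
                 ae_dead_time_s = ae_dead_time_s,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the image-analysis pipeline over a batch of slices
#'
#' For every input image: read, segment ([segment_pores()]), measure
#' ([measure_slice()]). Then summarize groups, and when both factors are
#' crossed with every cell occupied, run the object-level two-way ANOVA
#' with Tukey post hoc for each descriptor and the slice-level ANOVA for
#' the total pore fraction. Per-file failures are logged in the manifest
#' and skipped; the pipeline fails only if every input fails.
#'
#' @param inputs data.frame with columns `path` (image file),
#'   `histology`, `treatment` and optionally `sample_id`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if missing. All tables are
#'   written as CSV and a `manifest.json` records configuration, input
#'   checksums, output checksums, per-stage timings and warnings.
#' @return Invisibly, a list with `slices`, `objects`, `group_summary`,
#'   `anova`, `tukey`, `manifest`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir) {
  stopifnot(is.data.frame(inputs),
            all(c("path", "histology", "treatment") %in% names(inputs)),
            nrow(inputs) > 0)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seg_cfg <- segmentation_config(median_size = config$median_size,
                                 blur_sigma_px = config$blur_sigma_px,
                                 threshold = config$threshold,
                                 polarity = config$polarity,
                                 connectivity = config$connectivity)
  warnings_log <- character(0)
  failures <- character(0)
  slices <- list()
  t0 <- proc.time()[["elapsed"]]

  for (i in seq_len(nrow(inputs))) {
    res <- tryCatch({
      img <- read_calibrated_image(inputs$path[i], config$pixel_area_um2)
      mask <- segment_pores(img, seg_cfg)
      list(morphometry = measure_slice(mask),
           histology = as.character(inputs$histology[i]),
           treatment = as.character(inputs$treatment[i]),
           path = inputs$path[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0(inputs$path[i], ": ",
                                     conditionMessage(res)))
    } else {
      slices[[length(slices) + 1L]] <- res
    }
  }
  if (length(slices) == 0L) {
    stop("all inputs failed: ", paste(failures, collapse = "; "))
  }
  t_images <- proc.time()[["elapsed"]] - t0

  objects <- do.call(rbind, lapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    obj <- s$morphometry$objects
    if (nrow(obj) == 0L) return(NULL)
    cbind(slice = i, path = s$path, histology = s$histology,
          treatment = s$treatment, obj)
  }))
  slice_table <- do.call(rbind, lapply(seq_along(slices), function(i) {
    s <- slices[[i]]
    data.frame(slice = i, path = s$path, histology = s$histology,
               treatment = s$treatment,
               n_objects = s$morphometry$n_objects,
               border_excluded = s$morphometry$border_excluded_count,
               total_pore_fraction = s$morphometry$total_pore_fraction,
               stringsAsFactors = FALSE)
  }))
  group_summary <- withCallingHandlers(
    summarize_groups(slices),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  # statistics: object-level for descriptors, slice-level for porosity
  anova_tables <- list(); tukey_tables <- list()
  crossed <- length(unique(slice_table$histology)) == 2 &&
    length(unique(slice_table$treatment)) == 2 &&
    all(table(slice_table$histology, slice_table$treatment) >= 2)
  if (crossed && !is.null(objects)) {
    for (resp in c("area_um2", "elongation", "circularity",
                   "shape_roughness")) {
      d <- data.frame(value = objects[[resp]], histology = objects$histology,
                      treatment = objects$treatment)
      anova_tables[[resp]] <- two_way_anova(d)
      tukey_tables[[resp]] <- tukey_posthoc(d)
    }
    d <- data.frame(value = slice_table$total_pore_fraction,
                    histology = slice_table$histology,
                    treatment = slice_table$treatment)
    anova_tables[["total_pore_fraction"]] <- two_way_anova(d)
    tukey_tables[["total_pore_fraction"]] <- tukey_posthoc(d)
  } else {
    warnings_log <- c(warnings_log,
                      "factors not fully crossed (>=2 slices per cell); ANOVA skipped")
  }

  out_files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    out_files <<- c(out_files, p)
  }
  if (!is.null(objects)) wr(objects, "objects.csv")
  wr(slice_table, "slices.csv")
  wr(group_summary, "group_summary.csv")
  for (nm in names(anova_tables)) {
    wr(as.data.frame(anova_tables[[nm]]), paste0("anova_", nm, ".csv"))
    wr(as.data.frame(tukey_tables[[nm]]), paste0("tukey_", nm, ".csv"))
  }

  manifest <- list(
    package_version = as.character(packageVersion("poromech")),
    config = unclass(config),
    inputs = data.frame(path = inputs$path,
                        md5 = unname(tools::md5sum(inputs$path)),
                        histology = inputs$histology,
                        treatment = inputs$treatment,
                        stringsAsFactors = FALSE),
    outputs = data.frame(path = out_files,
                         md5 = unname(tools::md5sum(out_files)),
                         stringsAsFactors = FALSE),
    timings_s = list(images = t_images),
    n_slices = length(slices),
    failures = failures,
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(slices = slice_table, objects = objects,
                 group_summary = group_summary, anova = anova_tables,
                 tukey = tukey_tables, manifest = manifest))
}

#' End-to-end demonstration on generated data
#'
#' Generates a 2 x 2 batch of synthetic slices (histology AM/PL by
#' treatment F/C, `n_slices_per_group` each) with group-dependent pore
#' populations -- Haversian-like (PL) fields carry larger pores, fatigued
#' (F) fields more and rougher ones -- writes them as TIFF, and runs
#' [run_pipeline()] on the batch. Deterministic under a fixed seed.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param image_px image side length in pixels (default 256; the full
#'   acquisition size is 2048).
#' @param n_slices_per_group slices per group (default 2).
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_demo <- function(out_dir, seed = 1L, image_px = 256L,
                     n_slices_per_group = 2L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  img_dir <- file.path(out_dir, "images")
  if (!dir.exists(img_dir)) dir.create(img_dir)
  groups <- expand.grid(histology = c("AM", "PL"), treatment = c("F", "C"),
                        stringsAsFactors = FALSE)
  scale <- image_px / 512
  inputs <- NULL
  k <- 0L
  for (g in seq_len(nrow(groups))) {
    hist_lab <- groups$histology[g]; trt_lab <- groups$treatment[g]
    for (s in seq_len(n_slices_per_group)) {
      k <- k + 1L
      base_axis <- if (hist_lab == "PL") c(10, 22) else c(7, 16)
      n_obj <- round((if (trt_lab == "F") 14 else 10) *
                       (if (hist_lab == "PL") 1.2 else 1) * scale^2 * 4)
      spec <- image_spec(
        width_px = image_px, height_px = image_px,
        n_objects = max(3L, n_obj),
        axis_length_range_px = base_axis * (if (trt_lab == "F") 1.15 else 1),
        axis_ratio_range = if (hist_lab == "AM") c(1.5, 4) else c(1, 2.5),
        roughness_amplitude = if (trt_lab == "F") 0.22 else 0.12,
        noise_fraction = 0.02, illumination_gradient_amplitude = 0.2,
        seed = seed * 1000L + k)
      syn <- generate_pore_image(spec)
      p <- file.path(img_dir, sprintf("%s_%s_slice%02d.tif", hist_lab,
                                      trt_lab, s))
      write_calibrated_image(syn$image, p)
      inputs <- rbind(inputs, data.frame(path = p, histology = hist_lab,
                                         treatment = trt_lab,
                                         stringsAsFactors = FALSE))
    }
  }
  run_pipeline(inputs, pipeline_config(seed = seed), out_dir)
}
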