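# End-to-end orchestration of the three analysis pathways over one or more
# images: (a) binarize + shape statistics, (b) Voronoi regularity,
# (c) orientation/coherency + ROI angle series; plus cross-sample
# statistics and report writing.

#' Configuration of a pipeline run
#'
#' Collects every tunable of the three pathways. The resolved configuration
#' is serialized (JSON) next to the outputs of every run, so each choice is
#' recorded.
#'
#' @param niblack_radius Niblack window half-size, px (required for
#'   pathway a; image-dependent).
#' @param niblack_k Niblack weight.
#' @param polarity foreground polarity for thresholding.
#' @param channel RGB channel policy for [select_channel()].
#' @param connectivity component connectivity (4 or 8).
#' @param scale_px_per_mm optional pixel scale for areas in mm^2.
#' @param include_unbounded,cell_center Voronoi options, see [vri()].
#' @param operator,window_sigma orientation analysis parameters.
#' @param n_rois,roi_size,peaks_per_roi ROI collection parameters
#'   (20 x 250 px x 3 reproduces the customary N = 60 series).
#' @param chi2_mode chi-square construction, see [pairwise_stats()].
#' @param rng_seed seed recorded with the run.
#' @return object of class \code{"run_config"} (a named list).
#' @export
run_config <- function(niblack_radius = 128, niblack_k = -0.2,
                       polarity = "dark_foreground", channel = "auto",
                       connectivity = 8, scale_px_per_mm = NULL,
                       include_unbounded = FALSE, cell_center = "centroid",
                       operator = "riesz", window_sigma = 8,
                       n_rois = 20, roi_size = 250, peaks_per_roi = 3,
                       chi2_mode = "paired", rng_seed = 1) {
  cfg <- list(niblack_radius = niblack_radius, niblack_k = niblack_k,
              polarity = polarity, channel = channel,
              connectivity = connectivity, scale_px_per_mm = scale_px_per_mm,
              include_unbounded = include_unbounded, cell_center = cell_center,
              operator = operator, window_sigma = window_sigma,
              n_rois = n_rois, roi_size = roi_size,
              peaks_per_roi = peaks_per_roi, chi2_mode = chi2_mode,
              rng_seed = rng_seed)
  class(cfg) <- "run_config"
  cfg
}

resolve_gray <- function(image, config) {
  if (is.matrix(image)) image
  else select_channel(image, config$channel)$image
}

#' Pathway (a): binarization and shape statistics
#'
#' Channel selection, Niblack threshold field, mask, connected components,
#' shape summary. When \code{outdir} is given, writes the mask PNG, the
#' per-object CSV and the summary JSON.
#'
#' @param image grayscale matrix or RGB array.
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @param name sample name used in file names.
#' @return list with \code{mask}, \code{objects}, \code{summary}.
#' @export
run_pathway_a <- function(image, config = run_config(), outdir = NULL,
                          name = "sample") {
  gray <- resolve_gray(image, config)
  mask <- niblack_binarize(gray, config$niblack_radius, config$niblack_k,
                           config$polarity)
  objects <- label_objects(mask, config$connectivity)
  summ <- suppressMessages(
    summarize_shapes(objects, config$scale_px_per_mm))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_gray_png(mask$pixels, file.path(outdir, paste0(name, "_mask.png")))
    utils::write.csv(as.data.frame(objects),
                     file.path(outdir, paste0(name, "_objects.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(count = summ$count, total_area_px2 = summ$total_area_px2,
           total_area_mm2 = summ$total_area_mm2, coverage = mask$coverage),
      file.path(outdir, paste0(name, "_shapes.json")),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(mask = mask, objects = objects, summary = summ)
}

#' Pathway (b): Voronoi regularity of object centroids
#'
#' Reuses (or computes) the pathway-a segmentation, tessellates the object
#' centroids and computes the regularity index.
#'
#' @inheritParams run_pathway_a
#' @param pathway_a optional precomputed result of [run_pathway_a()].
#' @return list with \code{diagram} and \code{vri}.
#' @export
run_pathway_b <- function(image, config = run_config(), pathway_a = NULL,
                          outdir = NULL, name = "sample") {
  if (is.null(pathway_a)) pathway_a <- run_pathway_a(image, config)
  objects <- pathway_a$objects
  if (nrow(objects) < 3)
    stop("pathway b needs >= 3 segmented objects; lower the threshold radius or check the image",
         call. = FALSE)
  seeds <- seeds_from_objects(objects)
  gray_dim <- dim(pathway_a$mask$pixels)
  diagram <- tessellate(seeds, window = c(1, 1, gray_dim[2], gray_dim[1]))
  include_unbounded <- config$include_unbounded
  if (!include_unbounded && sum(diagram$bounded) < 2L) {
    warning("fewer than 2 interior Voronoi cells; including border cells ",
            "(their clipped distances are distorted)")
    include_unbounded <- TRUE
  }
  res <- vri(diagram, include_unbounded = include_unbounded,
             cell_center = config$cell_center)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(data.frame(x = seeds[, 1], y = seeds[, 2]),
                     file.path(outdir, paste0(name, "_seeds.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(vri = if (is.finite(res$vri)) res$vri else "Inf",
           D_mean = res$D_mean, D_sd = res$D_sd,
           n_cells_used = res$n_cells_used,
           regular_pattern = res$regular_pattern),
      file.path(outdir, paste0(name, "_vri.json")),
      auto_unbox = TRUE, digits = NA)
  }
  list(diagram = diagram, vri = res)
}

#' Pathway (c): orientation analysis and angle series
#'
#' Gradient, structure tensor, orientation/coherency field, HSB and
#' coherency renderings, ROI summaries and the angle series.
#'
#' @inheritParams run_pathway_a
#' @return list with \code{orientation}, \code{tensor}, \code{rois},
#'   \code{roi_summaries}, \code{angle_series}.
#' @export
run_pathway_c <- function(image, config = run_config(), outdir = NULL,
                          name = "sample") {
  gray <- resolve_gray(image, config)
  tensor <- structure_tensor(gradient(gray, config$operator),
                             config$window_sigma)
  orient <- orientation_and_coherency(tensor)
  rois <- tile_rois(dim(gray), config$n_rois, config$roi_size)
  roi_summaries <- lapply(seq_len(nrow(rois)), function(i)
    summarize_roi(orient, tensor, rois[i, ], max_peaks = config$peaks_per_roi))
  series <- collect_angle_series(orient, rois = rois,
                                 peaks_per_roi = config$peaks_per_roi,
                                 sample_id = name, tensor = tensor)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_orientation_tiff(orient, file.path(outdir, name))
    write_rgb_png(render_hsb(orient, gray),
                  file.path(outdir, paste0(name, "_hsb.png")))
    write_gray_png(render_coherency(orient),
                   file.path(outdir, paste0(name, "_coherency.png")))
    utils::write.csv(
      cbind(sample_id = name, as.data.frame(series)),
      file.path(outdir, paste0(name, "_angles.csv")), row.names = FALSE)
  }
  list(orientation = orient, tensor = tensor, rois = rois,
       roi_summaries = roi_summaries, angle_series = series)
}

#' Run the full study over a set of images
#'
#' Executes pathways (a), (b) and (c) per sample, assembles a summary table
#' (count, total area, relative coverage with respect to the reference
#' sample, VRI), and, when at least two samples are present, the
#' cross-sample statistics: pairwise Pearson/Spearman/chi-square matrix,
#' standardized PCA of the angle series, and the separation report.
#'
#' @param images named list of grayscale matrices (or RGB arrays); names
#'   are the sample ids.
#' @param config a [run_config()].
#' @param outdir optional output directory; per-sample artifacts, the
#'   summary CSV, the stats JSON and the resolved config are written there.
#' @param reference reference sample name for relative coverage (default:
#'   the first image).
#' @return object of class \code{"study_report"}: \code{samples} (per-sample
#'   results), \code{table} (summary data frame), \code{pairwise} (list of
#'   \code{pairwise_stats}), \code{pca}, \code{separation}, \code{config}.
#' @export
run_study <- function(images, config = run_config(), outdir = NULL,
                      reference = NULL) {
  if (length(images) < 1) stop("need at least one image", call. = FALSE)
  if (is.null(names(images)) || any(names(images) == ""))
    names(images) <- paste0("sample", seq_along(images))
  if (is.null(reference)) reference <- names(images)[1]
  if (!reference %in% names(images)) stop("unknown reference sample", call. = FALSE)

  samples <- lapply(names(images), function(nm) {
    a <- run_pathway_a(images[[nm]], config, outdir, nm)
    b <- tryCatch(run_pathway_b(images[[nm]], config, pathway_a = a,
                                outdir = outdir, name = nm),
                  error = function(e) NULL)
    cc <- run_pathway_c(images[[nm]], config, outdir, nm)
    list(name = nm, a = a, b = b, c = cc)
  })
  names(samples) <- names(images)

  area_of <- function(s)
    if (is.na(s$a$summary$total_area_mm2)) s$a$summary$total_area_px2
    else s$a$summary$total_area_mm2
  ref_area <- area_of(samples[[reference]])
  tab <- do.call(rbind, lapply(samples, function(s) data.frame(
    sample = s$name,
    count = s$a$summary$count,
    area = area_of(s),
    relative_cvg = relative_coverage(area_of(s), ref_area),
    vri = if (is.null(s$b)) NA_real_ else s$b$vri$vri,
    coverage = s$a$mask$coverage)))
  rownames(tab) <- NULL

  pairwise <- NULL; pca <- NULL; separation <- NULL
  if (length(samples) >= 2) {
    series <- lapply(samples, function(s) s$c$angle_series)
    ns <- vapply(series, nrow, integer(1))
    if (length(unique(ns)) != 1)
      stop("angle series lengths differ across samples (",
           paste(ns, collapse = ", "),
           "); use a shared ROI configuration", call. = FALSE)
    nm <- names(series)
    pairwise <- list()
    for (i in seq_along(series)) for (j in seq_along(series)) if (i < j)
      pairwise[[paste(nm[i], nm[j], sep = " vs ")]] <-
        pairwise_stats(series[[i]], series[[j]], config$chi2_mode)
    pca <- pca_angles(angle_series_matrix(series))
    separation <- tryCatch(separation_report(series), error = function(e) NULL)
  }

  report <- structure(list(samples = samples, table = tab,
                           pairwise = pairwise, pca = pca,
                           separation = separation, config = config,
                           reference = reference), class = "study_report")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(outdir, "summary_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(config_manifest(report, outdir),
                         file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  report
}

# Manifest: resolved config, package version, per-file md5 of the CSV
# outputs written so far.
config_manifest <- function(report, outdir) {
  csvs <- list.files(outdir, pattern = "\\.csv$", full.names = TRUE)
  list(config = unclass(report$config),
       reference = report$reference,
       package_version = as.character(utils::packageVersion("orientfilm")),
       files = as.list(tools::md5sum(csvs)))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study report: %d sample(s), reference %s\n",
              length(x$samples), x$reference))
  print(x$table, row.names = FALSE)
  if (!is.null(x$pca)) {
    evr <- x$pca$explained_variance_ratio
    cat(sprintf("PCA: first two components explain %.1f%% of the variance\n",
                100 * sum(evr[1:min(2, length(evr))])))
  }
  if (!is.null(x$separation))
    cat(sprintf("separation ratio %.2f (silhouette %.3f)\n",
                x$separation$separation_ratio, x$separation$silhouette))
  invisible(x)
}
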