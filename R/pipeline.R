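# Configuration, image I/O and the end-to-end driver from multi-channel
# images to the correlation report.

#' Pipeline configuration
#'
#' Collects every tunable of the quantification chain. Defaults follow the
#' standard punctate-factor recipe: 0.5 um rim cutoff, 4 px bandpass
#' cutoffs, moment-preserving thresholding.
#'
#' @param pixel_size_um Pixel size (um/px).
#' @param channels Named list mapping roles `dna`, `rim`, `foci` to plane
#'   indices in the TIFF.
#' @param cutoff_um Rim classification cutoff (um).
#' @param rim_band_width_um Rim band width (um).
#' @param occupancy_radius_um Rim occupancy capture radius (um).
#' @param filter_large_px,filter_small_px Bandpass cutoffs (px).
#' @param min_area_px Minimum particle area (px).
#' @param min_nucleus_area_um2 Minimum nucleus area (um^2).
#' @param reference_condition Condition supplying the reference shape means
#'   (`NULL`: first condition in the manifest).
#' @param seed Random seed recorded in the provenance log.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 0.04,
                            channels = list(dna = 1L, rim = 2L, foci = 3L),
                            cutoff_um = 0.5,
                            rim_band_width_um = 0.5,
                            occupancy_radius_um = 0.25,
                            filter_large_px = 4,
                            filter_small_px = 4,
                            min_area_px = 2,
                            min_nucleus_area_um2 = 10,
                            reference_condition = NULL,
                            seed = 1L) {
  cfg <- list(pixel_size_um = pixel_size_um, channels = channels,
              cutoff_um = cutoff_um, rim_band_width_um = rim_band_width_um,
              occupancy_radius_um = occupancy_radius_um,
              filter_large_px = filter_large_px,
              filter_small_px = filter_small_px,
              min_area_px = min_area_px,
              min_nucleus_area_um2 = min_nucleus_area_um2,
              reference_condition = reference_condition,
              seed = as.integer(seed))
  for (f in c("pixel_size_um", "cutoff_um", "rim_band_width_um",
              "occupancy_radius_um", "filter_large_px", "filter_small_px")) {
    check_number(cfg[[f]], f, 0, strict_min = TRUE)
  }
  roles <- names(cfg$channels)
  if (!all(c("dna", "rim", "foci") %in% roles)) {
    abort("channels must map the roles dna, rim and foci.")
  }
  if (anyDuplicated(unlist(cfg$channels))) {
    abort("channel roles must map to distinct plane indices.")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read and write pipeline configurations (YAML)
#'
#' The configuration round-trips losslessly through YAML.
#'
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$channels <- lapply(raw$channels, as.integer)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Read a multi-channel nucleus image
#'
#' Reads a TIFF and maps its planes to the configured roles. When the file
#' holds a z-stack (plane count a multiple of the number of roles), each
#' channel block is collapsed by maximum-intensity projection with a
#' notice.
#'
#' @param path TIFF path.
#' @param config A [pipeline_config()].
#' @return Named list of 2-D matrices keyed by role (`dna`, `rim`, `foci`).
#' @export
read_nucleus_image <- function(path, config) {
  if (!file.exists(path)) abort(sprintf("cannot read image '%s'.", path))
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse any sample dimension
    p
  })
  roles <- config$channels
  n_roles <- length(roles)
  np <- length(planes)
  if (np == max(unlist(roles)) || np == n_roles) {
    out <- lapply(roles, function(i) planes[[i]])
  } else if (np %% n_roles == 0L && np > n_roles) {
    nz <- np %/% n_roles
    inform(sprintf("'%s': %d planes collapsed to %d channels by maximum-intensity projection.",
                   basename(path), np, n_roles))
    out <- lapply(roles, function(i) {
      block <- planes[((i - 1) * nz + 1):(i * nz)]
      Reduce(pmax, block)
    })
  } else {
    abort(sprintf(
      "'%s' has %d planes but the configuration expects roles %s on %d channels.",
      basename(path), np, paste(names(roles), collapse = "/"), n_roles))
  }
  out
}

# quantify one image file: all per-nucleus measures
quantify_image <- function(channels, config) {
  px <- config$pixel_size_um
  nuclei <- segment_nuclei(channels$dna, px,
                           min_area_um2 = config$min_nucleus_area_um2)
  if (nrow(nuclei) == 0L) {
    abort("no nuclei segmented.")
  }
  foci <- detect_foci(channels$foci, nuclei,
                      min_area_px = config$min_area_px,
                      filter_large_px = config$filter_large_px,
                      filter_small_px = config$filter_small_px)
  filtered <- bandpass_filter(channels$foci, config$filter_large_px,
                              config$filter_small_px)

  per_nucleus <- purrr::pmap(nuclei[, c("nucleus", "mask")],
                             function(nucleus, mask) {
    rim <- rim_geometry(mask, px, config$rim_band_width_um, nucleus = nucleus)
    morph <- shape_descriptors(mask, px)
    morph$bleb_count <- count_blebs(mask, px)
    morph$nucleus <- nucleus
    nfoci <- dplyr::filter(foci, .data$nucleus == !!nucleus)
    nfoci <- classify_foci(nfoci, rim, cutoff_um = config$cutoff_um,
                           rim_channel = channels$rim)
    thr <- tryCatch(moments_threshold(filtered, mask), error = function(e) Inf)
    foci_mask <- matrix(as.numeric(filtered > thr & mask != 0),
                        nrow(mask), ncol(mask))
    occupancy <- percent_positive_rim(foci_mask, rim,
                                      config$occupancy_radius_um)
    coloc <- tryCatch(
      dplyr::bind_rows(
        pearson_coloc(channels$foci, channels$rim, mask,
                      channels = c("foci", "rim")),
        compartment_coloc(channels$foci, channels$rim, rim, mask,
                          channels = c("foci", "rim"))
      ),
      error = function(e) NULL
    )
    if (!is.null(coloc)) coloc$nucleus <- nucleus
    rimtab <- if (nrow(nfoci)) rim_counts(nfoci) else
      tibble(nucleus = nucleus, n_rim = 0L, n_nucleoplasm = 0L, n_total = 0L,
             pct_rim = NA_real_, pct_nucleoplasm = NA_real_)
    rimtab$pct_positive_rim <- occupancy
    list(morph = morph, foci = nfoci, rim = rimtab, coloc = coloc)
  })

  list(
    morpho = dplyr::bind_rows(purrr::map(per_nucleus, "morph")),
    foci = dplyr::bind_rows(purrr::map(per_nucleus, "foci")),
    rim = dplyr::bind_rows(purrr::map(per_nucleus, "rim")),
    coloc = dplyr::bind_rows(purrr::compact(purrr::map(per_nucleus, "coloc")))
  )
}

#' Run the full quantification pipeline over an image manifest
#'
#' Executes segmentation, morphometry, foci detection, rim classification
#' and colocalization for every image, aggregates per condition, fits the
#' correlation layer when expression levels are supplied, and writes the
#' CSV bundle, a markdown report and a provenance log. Unreadable or
#' unquantifiable files are collected as failures and the run continues.
#'
#' @param manifest Tibble with columns `condition` and `path`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param expression Optional tibble (`condition`, `protein`, `level`) for
#'   the correlation layer.
#' @return Invisibly, a list of class `rim_bundle`: tibbles `nuclei`,
#'   `foci`, `rim`, `coloc`, `summary`, optional `correlation`, a
#'   `failures` tibble and the written `paths`. `partial` is `TRUE` when
#'   any file failed.
#' @export
run_pipeline <- function(manifest, config, out_dir, expression = NULL) {
  if (!all(c("condition", "path") %in% names(manifest))) {
    abort("manifest must have columns condition and path.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    cond <- manifest$condition[i]; path <- manifest$path[i]
    res <- tryCatch({
      channels <- read_nucleus_image(path, config)
      q <- quantify_image(channels, config)
      lapply(q, function(df) {
        if (nrow(df)) dplyr::mutate(df, condition = cond,
                                    image = basename(path), .before = 1)
        else df
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble(condition = cond, path = path, error = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (length(results) == 0L) abort("every image failed; nothing to report.")

  nuclei <- dplyr::bind_rows(purrr::map(results, "morpho"))
  foci <- dplyr::bind_rows(purrr::map(results, "foci"))
  rim <- dplyr::bind_rows(purrr::map(results, "rim"))
  coloc <- dplyr::bind_rows(purrr::map(results, "coloc"))

  ref_cond <- config$reference_condition %||% manifest$condition[1]
  ref <- reference_means(nuclei, ref_cond)
  nuclei <- aberration(nuclei, ref)
  summary <- summarize_morphometry(nuclei)
  rim_cond <- dplyr::summarise(
    dplyr::group_by(rim, .data$condition),
    pct_positive_rim = mean(.data$pct_positive_rim),
    pct_rim_foci = mean(.data$pct_rim, na.rm = TRUE),
    foci_per_nucleus = mean(.data$n_total),
    .groups = "drop"
  )
  summary <- dplyr::left_join(summary, rim_cond, by = "condition")

  correlation <- NULL
  if (!is.null(expression)) {
    morpho_sum <- dplyr::select(summary, "condition",
                                aberration_index_mean = "aberration_index_mean")
    correlation <- build_correlation_table(
      dplyr::select(rim_cond, "condition", "pct_positive_rim"),
      morpho_sum, expression
    )
  }

  paths <- c(
    nuclei = file.path(out_dir, "nuclei.csv"),
    foci = file.path(out_dir, "foci.csv"),
    rim = file.path(out_dir, "rim.csv"),
    coloc = file.path(out_dir, "coloc.csv"),
    summary = file.path(out_dir, "summary.csv")
  )
  readr::write_csv(nuclei, paths["nuclei"])
  readr::write_csv(foci, paths["foci"])
  readr::write_csv(rim, paths["rim"])
  readr::write_csv(coloc, paths["coloc"])
  readr::write_csv(summary, paths["summary"])
  if (!is.null(correlation)) {
    paths["regressions"] <- file.path(out_dir, "regressions.csv")
    readr::write_csv(correlation$regressions, paths["regressions"])
  }

  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble(condition = character(), path = character(), error = character())

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  prov <- c(
    sprintf("nucrim %s", as.character(utils::packageVersion("nucrim"))),
    sprintf("R %s", as.character(getRversion())),
    sprintf("seed: %d", config$seed),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("images quantified: %d / %d", length(results), nrow(manifest))
  )
  writeLines(prov, file.path(out_dir, "provenance.txt"))
  write_report(summary, failures, file.path(out_dir, "report.md"), ref_cond,
               correlation)

  bundle <- structure(
    list(nuclei = nuclei, foci = foci, rim = rim, coloc = coloc,
         summary = summary, correlation = correlation, failures = failures,
         paths = paths, partial = nrow(failures) > 0L),
    class = "rim_bundle"
  )
  invisible(bundle)
}

write_report <- function(summary, failures, path, ref_cond, correlation) {
  lines <- c(
    "# Nuclear rim quantification report", "",
    sprintf("Reference condition for aberration: %s", ref_cond), "",
    "## Per-condition summary", "",
    paste(utils::capture.output(print(as.data.frame(summary))), collapse = "\n")
  )
  if (!is.null(correlation)) {
    lines <- c(lines, "", "## Correlation layer (no multiple-testing correction)", "",
               paste(utils::capture.output(
                 print(as.data.frame(correlation$regressions))), collapse = "\n"))
  }
  if (nrow(failures)) {
    lines <- c(lines, "", "## Failed inputs", "",
               sprintf("- %s (%s): %s", failures$path, failures$condition,
                       failures$error))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.rim_bundle <- function(x, ...) {
  cat(sprintf("rim_bundle: %d nuclei, %d foci, %d conditions%s\n",
              nrow(x$nuclei), nrow(x$foci),
              length(unique(x$nuclei$condition)),
              if (x$partial) sprintf(" (%d failures)", nrow(x$failures)) else ""))
  invisible(x)
}
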