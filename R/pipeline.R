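#' Run the full LD / Ne / structure pipeline
#'
#' Orchestrates the complete analysis over one or more population
#' panels: per-population QC, common-marker intersection (computed
#' after QC, in that order), within-chromosome pairwise LD, the binned
#' decay curve with threshold distance and fixed-distance reads,
#' adjacent-marker LD, historical Ne trajectories with per-chromosome
#' harmonic means, the contemporary LD Ne point estimate, relatedness
#' summaries, and PCA on the common markers. Every table is written as a
#' TSV with 6-significant-digit formatting so reruns are byte-identical,
#' plus a `manifest.json` with settings, seeds and per-stage counts.
#' Stage failure aborts with the stage named and leaves a `FAILED`
#' marker file next to the partial outputs.
#'
#' @param panels Named list of [genotype_panel()]s (one per population).
#' @param output_dir Directory for the report bundle (created if
#'   needed).
#' @param qc A [qc_config()].
#' @param ld_max_distance_bp,ld_bin_width_bp LD decay settings
#'   (defaults 10 Mb, 100 kb).
#' @param ld_estimator `"genotypic"` or `"em"`.
#' @param ne_hist An [ne_config()].
#' @param ne_pcrit,ne_mating Contemporary-Ne settings (defaults 0.05,
#'   `"monogamy"`).
#' @param pca_k Components to retain (default 10).
#' @param r2_threshold Decay threshold (default 0.2).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return Invisibly, a list with every in-memory result
#'   (`qc`, `panels_common`, `ld_pairs`, `decay`, `threshold_distance`,
#'   `r2_at_distance`, `adjacent_ld`, `ne_trajectory`, `chromosome_ne`,
#'   `ne_point`, `relatedness`, `pca`, `manifest`).
#' @export
run_pipeline <- function(panels, output_dir,
                         qc = qc_config(),
                         ld_max_distance_bp = 10e6,
                         ld_bin_width_bp = 100000,
                         ld_estimator = c("genotypic", "em"),
                         ne_hist = ne_config(),
                         ne_pcrit = 0.05,
                         ne_mating = c("monogamy", "random"),
                         pca_k = 10,
                         r2_threshold = 0.2,
                         seed = 1) {
  ld_estimator <- match.arg(ld_estimator)
  ne_mating <- match.arg(ne_mating)
  if (inherits(panels, "genotype_panel")) panels <- list(panels)
  if (is.null(names(panels)) || any(!nzchar(names(panels)))) {
    names(panels) <- vapply(panels, function(p) p$population, "")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(output_dir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 failed_marker)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  fmt_tsv <- function(df, file) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) {
      ifelse(is.na(x), "NA", format(signif(x, 6), trim = TRUE,
                                    scientific = FALSE))
    })
    utils::write.table(df, file.path(output_dir, file), quote = FALSE,
                       sep = "\t", row.names = FALSE)
  }

  res <- list()
  counts <- list()

  res$qc <- stage("qc", lapply(panels, apply_qc, config = qc))
  qc_panels <- lapply(res$qc, function(x) x$panel)
  qc_report <- dplyr::bind_rows(lapply(res$qc, function(x) x$report))
  fmt_tsv(qc_report, "qc_report.tsv")
  counts$qc <- stats::setNames(qc_report$n_snps_final, qc_report$population)

  res$maf_spectrum <- stage("maf_spectrum", {
    dplyr::bind_rows(lapply(names(qc_panels), function(nm) {
      dplyr::mutate(maf_spectrum(qc_panels[[nm]]), population = nm,
                    .before = 1L)
    }))
  })
  fmt_tsv(res$maf_spectrum, "maf_spectrum.tsv")

  if (length(qc_panels) >= 2L) {
    res$panels_common <- stage("intersect", intersect_markers(qc_panels))
    counts$common_markers <- attr(res$panels_common, "n_common")
  } else {
    res$panels_common <- qc_panels
    counts$common_markers <- n_markers(qc_panels[[1L]])
  }

  res$ld_pairs <- stage("ld", {
    lapply(res$panels_common, pairwise_ld,
           max_distance_bp = ld_max_distance_bp, estimator = ld_estimator)
  })
  counts$ld_pairs <- vapply(res$ld_pairs, nrow, 0L)

  res$decay <- stage("ld_decay", {
    lapply(res$ld_pairs, bin_ld, bin_width_bp = ld_bin_width_bp,
           max_bp = ld_max_distance_bp)
  })
  decay_tbl <- dplyr::bind_rows(lapply(names(res$decay), function(nm) {
    dplyr::mutate(res$decay[[nm]], population = nm, .before = 1L)
  }))
  fmt_tsv(decay_tbl, "ld_decay.tsv")

  res$threshold_distance <- vapply(res$decay, decay_threshold_distance,
                                   numeric(1), r2_threshold = r2_threshold)
  res$r2_at_distance <- dplyr::bind_rows(
    lapply(names(res$decay), function(nm) {
      dplyr::mutate(r2_at_distances(res$decay[[nm]]), population = nm,
                    .before = 1L)
    })
  )
  fmt_tsv(res$r2_at_distance, "r2_at_distance.tsv")

  res$adjacent_ld <- stage("adjacent_ld", {
    dplyr::bind_rows(lapply(names(res$ld_pairs), function(nm) {
      dplyr::mutate(
        adjacent_ld_summary(res$ld_pairs[[nm]],
                            res$panels_common[[nm]]$map),
        population = nm, .before = 1L
      )
    }))
  })
  fmt_tsv(res$adjacent_ld, "adjacent_ld.tsv")

  res$ne_trajectory <- stage("ne_historical", {
    lapply(res$ld_pairs, estimate_ne_trajectory, config = ne_hist)
  })
  traj_tbl <- dplyr::bind_rows(lapply(names(res$ne_trajectory),
    function(nm) {
      dplyr::mutate(res$ne_trajectory[[nm]], population = nm,
                    .before = 1L)
    }))
  fmt_tsv(traj_tbl, "ne_trajectory.tsv")

  res$chromosome_ne <- stage("chromosome_ne", {
    dplyr::bind_rows(lapply(names(res$ld_pairs), function(nm) {
      dplyr::mutate(chromosome_ne(res$ld_pairs[[nm]], ne_hist),
                    population = nm, .before = 1L)
    }))
  })
  fmt_tsv(res$chromosome_ne, "chromosome_ne.tsv")

  res$ne_point <- stage("ne_contemporary", {
    dplyr::bind_rows(lapply(res$panels_common, ld_ne_point_estimate,
                            pcrit = ne_pcrit, mating_model = ne_mating))
  })
  jsonlite::write_json(res$ne_point,
                       file.path(output_dir, "ne_point.json"),
                       digits = NA, pretty = TRUE)

  res$relatedness <- stage("relatedness", {
    dplyr::bind_rows(lapply(names(qc_panels), function(nm) {
      rel <- estimate_pairwise_relatedness(qc_panels[[nm]])
      tibble::tibble(population = nm,
                     mean_relatedness = attr(rel, "mean_relatedness"),
                     sd_relatedness = attr(rel, "sd_relatedness"),
                     n_pairs = nrow(rel))
    }))
  })
  fmt_tsv(res$relatedness, "relatedness.tsv")

  res$pca <- stage("pca", pca_genotypes(res$panels_common, k = pca_k))
  fmt_tsv(res$pca$coordinates, "pca.tsv")
  fmt_tsv(tibble::tibble(
    component = paste0("PC", seq_along(res$pca$eigenvalues)),
    eigenvalue = res$pca$eigenvalues,
    pct_variance = res$pca$pct_variance
  ), "pca_eigen.tsv")

  res$manifest <- list(
    populations = names(panels),
    n_samples_in = vapply(panels, n_samples, 0L),
    n_markers_in = vapply(panels, n_markers, 0L),
    qc = unclass(qc),
    snps_after_qc = counts$qc,
    common_markers = counts$common_markers,
    ld = list(estimator = ld_estimator,
              max_distance_bp = ld_max_distance_bp,
              bin_width_bp = ld_bin_width_bp,
              n_pairs = counts$ld_pairs),
    ne_historical = unclass(ne_hist),
    ne_contemporary = list(pcrit = ne_pcrit, mating_model = ne_mating),
    pca_k = res$pca$k,
    r2_threshold = r2_threshold,
    threshold_distance_bp = res$threshold_distance,
    seed = seed,
    package_version = as.character(utils::packageVersion("ldpopsize"))
  )
  jsonlite::write_json(res$manifest,
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
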