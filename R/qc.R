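#' QC thresholds for a genotype panel
#'
#' Defaults follow standard SNP-array practice for population-genetic
#' analyses: markers are dropped when their call rate falls below 95%,
#' when an exact Hardy-Weinberg test gives p < 1e-6, or when the minor
#' allele frequency is below 5%; individuals with more than 5% missing
#' genotypes are dropped first. All thresholds are strict inequalities
#' ("lower than 5%" keeps MAF = 0.05 exactly).
#'
#' @param min_snp_call_rate Minimum fraction of non-missing genotypes per
#'   SNP (default 0.95).
#' @param max_sample_missing Maximum fraction of missing genotypes per
#'   individual (default 0.05).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @param hwe_alpha Exact-test p-value below which a SNP is excluded
#'   (default 1e-6).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_snp_call_rate = 0.95, max_sample_missing = 0.05,
                      min_maf = 0.05, hwe_alpha = 1e-6) {
  vals <- c(min_snp_call_rate, max_sample_missing, min_maf, hwe_alpha)
  if (any(vals < 0 | vals > 1)) {
    stop("all QC thresholds must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(min_snp_call_rate = min_snp_call_rate,
         max_sample_missing = max_sample_missing,
         min_maf = min_maf, hwe_alpha = hwe_alpha),
    class = "qc_config"
  )
}

#' Minor allele frequency of a dosage vector
#'
#' @param dosage_column Numeric vector of 0/1/2/NA dosages.
#' @return MAF in `[0, 0.5]`: `min(p, 1 - p)` where `p` is the
#'   alternate-allele frequency `sum(dosages) / (2 * n_nonmissing)`.
#' @export
compute_maf <- function(dosage_column) {
  x <- dosage_column[!is.na(dosage_column)]
  if (length(x) == 0L) {
    stop("MAF undefined: all genotypes missing", call. = FALSE)
  }
  p <- sum(x) / (2 * length(x))
  min(p, 1 - p)
}

# Column-wise alt-allele frequency and MAF for a dosage matrix
# (NA where a column is all-missing).
col_alt_freq <- function(dosages) {
  n_obs <- colSums(!is.na(dosages))
  p <- colSums(dosages, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0L] <- NA_real_
  p
}

col_maf <- function(dosages) {
  p <- col_alt_freq(dosages)
  pmin(p, 1 - p)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the observed genotype counts: given the
#' allele counts, the probability of every heterozygote count consistent
#' with them is computed by recurrence, and the two-sided p-value is the
#' sum of probabilities no larger than that of the observed configuration
#' (the standard, not mid-p, tail used by the usual SNP implementations).
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1L) stop("need at least one genotyped individual", call. = FALSE)
  n_alt <- 2L * n_hom_alt + n_het
  rare <- min(n_alt, 2L * n - n_alt)
  if (rare == 0L) return(1)

  hets <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # start at the largest feasible het count and recurse downwards:
  # P(h-2)/P(h) = h (h-1) / (4 (hom_r + 1)(hom_c + 1)) at het = h
  k <- length(hets)
  probs[k] <- 1
  if (k >= 2L) for (i in k:2L) {
    h <- hets[i]
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    probs[i - 1L] <- probs[i] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  if (is.na(obs)) {
    stop("heterozygote count inconsistent with allele counts", call. = FALSE)
  }
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

#' Apply per-population quality control
#'
#' Filters in a fixed, reported order: (1) individuals with missing
#' fraction above `max_sample_missing`; then SNPs by (2) call rate,
#' (3) HWE exact-test p-value, (4) MAF. Each excluded SNP is attributed to
#' the first criterion that removed it, so the report's counts are
#' mutually exclusive and reconcile exactly:
#' `n_snps_in - call_rate - hwe - maf = n_snps_final`.
#'
#' @param panel A [genotype_panel()].
#' @param config A [qc_config()].
#' @return A list of class `qc_result` with elements `panel` (the filtered
#'   [genotype_panel()]) and `report` (a one-row tibble with columns
#'   `population`, `n_samples_in`, `n_samples_out`, `n_snps_in`,
#'   `excluded_by_call_rate`, `excluded_by_hwe`, `excluded_by_maf`,
#'   `n_snps_final`).
#' @export
apply_qc <- function(panel, config = qc_config()) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosages
  n_samples_in <- nrow(dos)
  n_snps_in <- ncol(dos)

  keep_ind <- rowMeans(is.na(dos)) <= config$max_sample_missing
  if (!any(keep_ind)) {
    stop("QC removed every individual", call. = FALSE)
  }
  dos <- dos[keep_ind, , drop = FALSE]

  call_rate <- colMeans(!is.na(dos))
  fail_cr <- call_rate < config$min_snp_call_rate

  hwe_p <- rep(NA_real_, ncol(dos))
  cand <- which(!fail_cr)
  for (j in cand) {
    g <- dos[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) next
    hwe_p[j] <- hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  fail_hwe <- !fail_cr & !is.na(hwe_p) & hwe_p < config$hwe_alpha

  maf <- col_maf(dos)
  fail_maf <- !fail_cr & !fail_hwe & (is.na(maf) | maf < config$min_maf)

  keep <- !(fail_cr | fail_hwe | fail_maf)
  if (!any(keep)) {
    stop("QC removed every SNP", call. = FALSE)
  }

  filtered <- subset_markers(
    genotype_panel(dos, panel$map, panel$population,
                   sample_ids = rownames(dos)),
    keep
  )
  report <- tibble::tibble(
    population = panel$population,
    n_samples_in = n_samples_in,
    n_samples_out = sum(keep_ind),
    n_snps_in = n_snps_in,
    excluded_by_call_rate = sum(fail_cr),
    excluded_by_hwe = sum(fail_hwe),
    excluded_by_maf = sum(fail_maf),
    n_snps_final = sum(keep)
  )
  structure(list(panel = filtered, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$report)
  invisible(x)
}

#' MAF spectrum of a panel
#'
#' Proportion of retained loci per MAF bin (default width 0.05, bins
#' `[0, 0.05), [0.05, 0.10), ...`), the usual post-QC allele-frequency
#' summary. Proportions sum to 1 over the loci with defined MAF.
#'
#' @param panel A post-QC [genotype_panel()].
#' @param bin_width Bin width on the MAF axis (default 0.05).
#' @return A tibble with `maf_lower`, `maf_upper`, `n_loci`, `proportion`.
#' @export
maf_spectrum <- function(panel, bin_width = 0.05) {
  maf <- col_maf(panel$dosages)
  maf <- maf[!is.na(maf)]
  if (length(maf) == 0L) stop("panel has no loci with defined MAF", call. = FALSE)
  edges <- round(seq(0, 0.5 + bin_width, by = bin_width), 10)
  idx <- findInterval(maf, edges, rightmost.closed = FALSE)
  n_bins <- length(edges) - 1L
  counts <- tabulate(idx, nbins = n_bins)
  tibble::tibble(
    maf_lower = edges[seq_len(n_bins)],
    maf_upper = edges[seq_len(n_bins) + 1L],
    n_loci = counts,
    proportion = counts / length(maf)
  ) |>
    dplyr::filter(.data$maf_lower < 0.5 + 1e-9)
}
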