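#' Genotypic (dosage-correlation) r-squared
#'
#' Squared Pearson correlation between two 0/1/2 dosage vectors over the
#' pairwise-complete individuals — the composite LD measure PLINK's
#' `--r2` reports by default. Undefined (NA) when either locus is
#' monomorphic among the complete pairs.
#'
#' @param dosages_i,dosages_j Numeric 0/1/2/NA dosage vectors of equal
#'   length.
#' @return r2 in `[0, 1]`, with attribute `n_used` (complete pairs), or
#'   NA when undefined.
#' @export
r2_genotypic <- function(dosages_i, dosages_j) {
  ok <- !is.na(dosages_i) & !is.na(dosages_j)
  n_used <- sum(ok)
  if (n_used < 2L) {
    return(structure(NA_real_, n_used = n_used))
  }
  x <- dosages_i[ok]
  y <- dosages_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(NA_real_, n_used = n_used))
  }
  r <- stats::cor(x, y)
  structure(min(1, r^2), n_used = n_used)
}

# EM estimate of the four haplotype frequencies from a 3x3 genotype count
# table (rows = dosage at locus i, cols = dosage at locus j, dosage order
# 0,1,2). Only the double-heterozygote cell is phase-ambiguous; its AB/ab
# vs Ab/aB split is re-estimated each iteration.
em_haplotype_freqs <- function(tab, tol = 1e-10, max_iter = 1000L) {
  n <- sum(tab)
  # fixed haplotype contributions (counts of alt_i/alt_j haplotypes)
  # from the eight unambiguous cells
  n_ab <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]          # ref_i/ref_j
  n_aB <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]          # ref_i/alt_j
  n_Ab <- 2 * tab[3, 1] + tab[2, 1] + tab[3, 2]          # alt_i/ref_j
  n_AB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]          # alt_i/alt_j
  n_dh <- tab[2, 2]

  p_i <- (n_AB + n_Ab + n_dh) / (2 * n)  # alt freq locus i
  p_j <- (n_AB + n_aB + n_dh) / (2 * n)
  # haplotype order: AB, Ab, aB, ab
  f <- c(p_i * p_j, p_i * (1 - p_j),
         (1 - p_i) * p_j, (1 - p_i) * (1 - p_j))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    denom <- f[1L] * f[4L] + f[2L] * f[3L]
    w <- if (denom > 0) f[1L] * f[4L] / denom else 0.5
    f_new <- c(
      (n_AB + w * n_dh) / (2 * n),
      (n_Ab + (1 - w) * n_dh) / (2 * n),
      (n_aB + (1 - w) * n_dh) / (2 * n),
      (n_ab + w * n_dh) / (2 * n)
    )
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  list(freqs = stats::setNames(f, c("AB", "Ab", "aB", "ab")),
       converged = converged)
}

#' EM (haplotype) r-squared
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' genotypes by EM (double heterozygotes resolved iteratively, tolerance
#' 1e-10, at most 1000 iterations) and returns the Hill-Robertson
#' haplotypic measure `r2 = D^2 / (pA pa pB pb)` with
#' `D = pAB - pA pB`. Equals the direct haplotype-count r2 whenever the
#' data contain no double heterozygotes.
#'
#' @inheritParams r2_genotypic
#' @return r2 in `[0, 1]` with attributes `n_used` and `converged`, or NA
#'   when a locus is monomorphic among complete pairs.
#' @export
r2_em <- function(dosages_i, dosages_j) {
  ok <- !is.na(dosages_i) & !is.na(dosages_j)
  n_used <- sum(ok)
  if (n_used < 2L) {
    return(structure(NA_real_, n_used = n_used, converged = NA))
  }
  x <- dosages_i[ok]
  y <- dosages_j[ok]
  tab <- matrix(0, 3, 3)
  for (k in seq_along(x)) {
    tab[x[k] + 1L, y[k] + 1L] <- tab[x[k] + 1L, y[k] + 1L] + 1
  }
  p_i <- (sum(x) / (2 * n_used))
  p_j <- (sum(y) / (2 * n_used))
  if (p_i %in% c(0, 1) || p_j %in% c(0, 1)) {
    return(structure(NA_real_, n_used = n_used, converged = NA))
  }
  em <- em_haplotype_freqs(tab)
  f <- em$freqs
  D <- f[["AB"]] - p_i * p_j
  r2 <- D^2 / (p_i * (1 - p_i) * p_j * (1 - p_j))
  structure(min(1, r2), n_used = n_used, converged = em$converged)
}

#' All within-chromosome LD pairs up to a maximum distance
#'
#' Computes r2 for every same-chromosome marker pair whose physical
#' distance is at most `max_distance_bp`, using either the genotypic
#' (dosage-correlation) estimator — the default, matching PLINK `--r2` —
#' or the EM haplotype estimator. Pairs whose r2 is undefined
#' (monomorphic among complete observations) are dropped; the count is
#' kept in attribute `n_skipped`.
#'
#' @param panel A post-QC [genotype_panel()].
#' @param max_distance_bp Maximum pair distance (default 10 Mb).
#' @param estimator `"genotypic"` or `"em"`.
#' @return A tibble of class `ld_pairs`, ordered by (chromosome, pos_i,
#'   pos_j), with columns `chromosome`, `marker_i`, `marker_j`, `pos_i`,
#'   `pos_j`, `distance_bp`, `r2`, `n_used`.
#' @export
pairwise_ld <- function(panel, max_distance_bp = 10e6,
                        estimator = c("genotypic", "em")) {
  estimator <- match.arg(estimator)
  map <- panel$map
  dos <- panel$dosages
  out <- vector("list", length(unique(map$chromosome)))
  n_skipped <- 0L
  chroms <- unique(map$chromosome)
  for (ci in seq_along(chroms)) {
    idx <- which(map$chromosome == chroms[ci])
    if (length(idx) < 2L) next
    pos <- map$position_bp[idx]
    m <- length(idx)
    ii <- rep(seq_len(m - 1L), times = (m - 1L):1L)
    jj <- sequence((m - 1L):1L, from = 2L:m)
    d <- pos[jj] - pos[ii]
    keep <- d <= max_distance_bp
    ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
    if (length(ii) == 0L) next
    sub <- dos[, idx, drop = FALSE]
    if (estimator == "genotypic") {
      cc <- suppressWarnings(
        stats::cor(sub, use = "pairwise.complete.obs")
      )
      nu <- crossprod(!is.na(sub))
      r2 <- pmin(1, cc[cbind(ii, jj)]^2)
      n_used <- nu[cbind(ii, jj)]
    } else {
      r2 <- numeric(length(ii))
      n_used <- integer(length(ii))
      for (k in seq_along(ii)) {
        v <- r2_em(sub[, ii[k]], sub[, jj[k]])
        r2[k] <- as.numeric(v)
        n_used[k] <- attr(v, "n_used")
      }
    }
    ok <- !is.na(r2)
    n_skipped <- n_skipped + sum(!ok)
    out[[ci]] <- tibble::tibble(
      chromosome = chroms[ci],
      marker_i = map$marker_id[idx][ii[ok]],
      marker_j = map$marker_id[idx][jj[ok]],
      pos_i = pos[ii[ok]],
      pos_j = pos[jj[ok]],
      distance_bp = d[ok],
      r2 = r2[ok],
      n_used = as.integer(n_used[ok])
    )
  }
  pairs <- dplyr::bind_rows(out)
  pairs <- dplyr::arrange(pairs, .data$chromosome, .data$pos_i, .data$pos_j)
  attr(pairs, "n_skipped") <- n_skipped
  attr(pairs, "estimator") <- estimator
  class(pairs) <- c("ld_pairs", class(pairs))
  pairs
}

#' Mean r-squared between physically adjacent markers
#'
#' Per-chromosome (and genome-wide) mean and standard deviation of r2 for
#' consecutive markers in map order — the usual "adjacent-SNP LD" summary
#' table. Chromosomes with fewer than two mapped pairs are omitted with a
#' warning.
#'
#' @param pairs An `ld_pairs` tibble from [pairwise_ld()].
#' @param map The panel's [marker_map()].
#' @return A tibble with `chromosome` (including a `"genome"` row),
#'   `n_pairs`, `mean_r2`, `sd_r2`.
#' @export
adjacent_ld_summary <- function(pairs, map) {
  adj <- map |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::reframe(
      marker_i = .data$marker_id[-dplyr::n()],
      marker_j = .data$marker_id[-1L]
    )
  adj_pairs <- dplyr::inner_join(
    pairs, adj, by = c("chromosome", "marker_i", "marker_j")
  )
  missing_chr <- setdiff(unique(map$chromosome), unique(adj_pairs$chromosome))
  if (length(missing_chr)) {
    warning("no adjacent pairs on chromosome(s): ",
            paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  per_chr <- adj_pairs |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mean_r2 = mean(.data$r2),
      sd_r2 = stats::sd(.data$r2),
      .groups = "drop"
    )
  genome <- tibble::tibble(
    chromosome = "genome",
    n_pairs = nrow(adj_pairs),
    mean_r2 = mean(adj_pairs$r2),
    sd_r2 = stats::sd(adj_pairs$r2)
  )
  dplyr::bind_rows(per_chr, genome)
}

#' Bin LD pairs into a decay curve
#'
#' Groups pairs into contiguous distance bins (default 100 kb wide from 0
#' to 10 Mb) and records each bin's pair count, mean distance and mean
#' r2 — the standard LD-decay curve. Empty bins are kept with count 0 and
#' NA means so the curve's bin structure is explicit.
#'
#' @param pairs An `ld_pairs` tibble.
#' @param bin_width_bp Bin width (default 100 kb).
#' @param max_bp Upper end of the binned range (default 10 Mb).
#' @return A tibble of class `ld_decay` with `bin_start`, `bin_end`,
#'   `n_pairs`, `mean_distance_bp`, `mean_r2`.
#' @export
bin_ld <- function(pairs, bin_width_bp = 100000, max_bp = 10e6) {
  if (nrow(pairs) == 0L) stop("no LD pairs to bin", call. = FALSE)
  edges <- seq(0, max_bp, by = bin_width_bp)
  if (edges[length(edges)] < max_bp) edges <- c(edges, max_bp)
  n_bins <- length(edges) - 1L
  keep <- pairs$distance_bp <= max_bp & pairs$distance_bp > 0
  d <- pairs$distance_bp[keep]
  r2 <- pairs$r2[keep]
  idx <- pmin(findInterval(d, edges, left.open = TRUE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  sum_d <- vapply(seq_len(n_bins), function(b) sum(d[idx == b]), 0)
  sum_r <- vapply(seq_len(n_bins), function(b) sum(r2[idx == b]), 0)
  curve <- tibble::tibble(
    bin_start = edges[seq_len(n_bins)],
    bin_end = edges[seq_len(n_bins) + 1L],
    n_pairs = counts,
    mean_distance_bp = ifelse(counts > 0, sum_d / counts, NA_real_),
    mean_r2 = ifelse(counts > 0, sum_r / counts, NA_real_)
  )
  class(curve) <- c("ld_decay", class(curve))
  curve
}

#' Distance at which a decay curve crosses an r-squared threshold
#'
#' Finds the first downward crossing of `r2_threshold` along the binned
#' decay curve and linearly interpolates between the mean distances of
#' the two bracketing bins. Returns NA (an explicit no-crossing result,
#' not an error) when the curve starts below the threshold or never
#' crosses it.
#'
#' @param curve An `ld_decay` tibble from [bin_ld()].
#' @param r2_threshold Threshold on mean r2 (default 0.2, the usual
#'   usefulness bound for association studies).
#' @return Interpolated distance in bp, or NA.
#' @export
decay_threshold_distance <- function(curve, r2_threshold = 0.2) {
  cc <- curve[curve$n_pairs > 0, ]
  if (nrow(cc) < 2L) stop("need >= 2 non-empty bins", call. = FALSE)
  r2 <- cc$mean_r2
  d <- cc$mean_distance_bp
  if (r2[1L] < r2_threshold) return(NA_real_)
  below <- which(r2 < r2_threshold)
  if (length(below) == 0L) return(NA_real_)
  j <- below[1L]
  i <- j - 1L
  d[i] + (r2[i] - r2_threshold) / (r2[i] - r2[j]) * (d[j] - d[i])
}

#' Mean r-squared at reference distances
#'
#' Reads the decay curve at fixed distances (defaults 0.1, 0.5, 1, 5 and
#' 10 Mb): for each distance, the mean r2 of the bin containing it,
#' reported with that bin's mean distance.
#'
#' @param curve An `ld_decay` tibble.
#' @param distances_bp Distances to read off (bp).
#' @return A tibble with `target_bp`, `bin_mean_distance_bp`, `mean_r2`,
#'   `n_pairs`.
#' @export
r2_at_distances <- function(curve,
                            distances_bp = c(0.1, 0.5, 1, 5, 10) * 1e6) {
  idx <- vapply(distances_bp, function(d) {
    hit <- which(curve$bin_start < d & d <= curve$bin_end)
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
  tibble::tibble(
    target_bp = distances_bp,
    bin_mean_distance_bp = curve$mean_distance_bp[idx],
    mean_r2 = curve$mean_r2[idx],
    n_pairs = curve$n_pairs[idx]
  )
}

#' Plot an LD decay curve
#'
#' @param object An `ld_decay` tibble from [bin_ld()].
#' @param ... Unused.
#' @return A ggplot object: mean r2 against bin mean distance.
#' @export
autoplot.ld_decay <- function(object, ...) {
  df <- object[object$n_pairs > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_distance_bp / 1e6, y = .data$mean_r2
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Distance (Mb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
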