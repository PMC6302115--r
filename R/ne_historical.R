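#' Configuration for historical Ne estimation from binned LD
#'
#' Historical effective population size is recovered from the expected
#' LD at recombination distance `c` via
#' `N_t = (1 / (4 f(c))) * (1 / E[r2_adj | c] - alpha)`,
#' where `t = 1/(2c)` generations ago, `f()` is an optional mapping
#' function, `r2_adj` is LD adjusted for sample size, and `alpha` is 2
#' when mutation is assumed to occur (1 otherwise). Defaults follow the
#' common SNP-array workflow: pairs collected to 5 Mb, 30 contiguous
#' 50-kb bins starting at 0 (pairs beyond the binned range are ignored
#' with their count logged), physical distance mapped to Morgans at
#' 1 cM/Mb with the identity map, and the `1/n` sample-size adjustment
#' appropriate for dosage-correlation r2.
#'
#' @param alpha Mutation adjustment, 1 or 2 (default 2).
#' @param min_distance_bp,max_distance_bp Distance range for pair
#'   collection (defaults 0 and 5 Mb).
#' @param bin_width_bp Bin width (default 50 kb).
#' @param n_bins Number of bins (default 30).
#' @param recomb_rate_cM_per_Mb Linear map rate (default 1).
#' @param mapping_function `"identity"`, `"haldane"` or `"sved_feldman"`.
#' @param sample_size_adjustment `"one_over_n"`, `"one_over_2n"` or
#'   `"none"`.
#' @return A list of class `ne_config`.
#' @export
ne_config <- function(alpha = 2, min_distance_bp = 0,
                      max_distance_bp = 5e6, bin_width_bp = 50000,
                      n_bins = 30,
                      recomb_rate_cM_per_Mb = 1.0,
                      mapping_function = c("identity", "haldane",
                                           "sved_feldman"),
                      sample_size_adjustment = c("one_over_n",
                                                 "one_over_2n", "none")) {
  if (!alpha %in% c(1, 2)) {
    stop("alpha must be 1 (no mutation) or 2 (mutation occurs)",
         call. = FALSE)
  }
  if (min_distance_bp < 0 || max_distance_bp <= min_distance_bp) {
    stop("invalid distance range", call. = FALSE)
  }
  structure(
    list(alpha = alpha, min_distance_bp = min_distance_bp,
         max_distance_bp = max_distance_bp, bin_width_bp = bin_width_bp,
         n_bins = n_bins, recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
         mapping_function = match.arg(mapping_function),
         sample_size_adjustment = match.arg(sample_size_adjustment)),
    class = "ne_config"
  )
}

#' Physical distance to recombination rate
#'
#' Converts bp to Morgans through a linear cM/Mb rate
#' (`d_M = bp * rate * 1e-8`), then applies a mapping function:
#' `identity` (c = d, recombination proportional to distance),
#' `haldane` (`c = (1 - exp(-2 d)) / 2`, no interference) or
#' `sved_feldman` (`c = d / (1 + 2 d)`, hyperbolic map).
#'
#' @param distance_bp Non-negative distance(s) in bp.
#' @param recomb_rate_cM_per_Mb Linear rate (default 1).
#' @param mapping_function Mapping to apply.
#' @return Recombination rate(s) in Morgans.
#' @export
physical_to_c <- function(distance_bp, recomb_rate_cM_per_Mb = 1.0,
                          mapping_function = c("identity", "haldane",
                                               "sved_feldman")) {
  if (any(distance_bp < 0)) {
    stop("distance must be non-negative", call. = FALSE)
  }
  mapping_function <- match.arg(mapping_function)
  d <- distance_bp * recomb_rate_cM_per_Mb * 1e-8
  switch(mapping_function,
    identity = d,
    haldane = (1 - exp(-2 * d)) / 2,
    sved_feldman = d / (1 + 2 * d)
  )
}

#' Sample-size adjustment of r-squared
#'
#' Subtracts the expected sample-induced LD from an observed r2:
#' `r2 - 1/n` (`one_over_n`, the convention for dosage-correlation r2),
#' `r2 - 1/(2n)` (`one_over_2n`, for haplotype-based r2 from 2n gametes)
#' or no change. Values pushed below zero are floored at 0 and flagged.
#'
#' @param r2 Observed r2 value(s).
#' @param n_used Number of individuals used per value (>= 2).
#' @param scheme Adjustment scheme.
#' @return Adjusted r2 with logical attribute `floored`.
#' @export
adjust_r2 <- function(r2, n_used,
                      scheme = c("one_over_n", "one_over_2n", "none")) {
  scheme <- match.arg(scheme)
  if (any(n_used < 2)) stop("n_used must be >= 2", call. = FALSE)
  adj <- switch(scheme,
    one_over_n = r2 - 1 / n_used,
    one_over_2n = r2 - 1 / (2 * n_used),
    none = r2
  )
  floored <- adj < 0
  adj[floored] <- 0
  structure(adj, floored = floored)
}

#' Historical Ne trajectory from LD pairs
#'
#' Bins same-chromosome LD pairs by distance, and inverts each bin's mean
#' sample-size-adjusted r2 into an effective population size
#' `N_t = (1 / (4 f(c))) * (1 / E[r2_adj] - alpha)` at
#' `t = 1 / (2 f(c))` generations ago, where `c` comes from the bin's
#' mean physical distance. Bins where `1 / E[r2_adj] <= alpha` (LD too
#' strong for a positive Ne under the model) yield no estimate and are
#' flagged rather than dropped silently.
#'
#' @param pairs An `ld_pairs` tibble from [pairwise_ld()].
#' @param config An [ne_config()].
#' @return A tibble of class `ne_trajectory`: `bin_start`, `bin_end`,
#'   `n_pairs`, `mean_distance_bp`, `mean_r2_adj`, `c_used`,
#'   `generations_ago_t`, `ne`, `well_posed`; attribute
#'   `n_pairs_beyond_bins` counts collected pairs past the binned range.
#' @export
estimate_ne_trajectory <- function(pairs, config = ne_config()) {
  if (nrow(pairs) == 0L) stop("no LD pairs supplied", call. = FALSE)
  keep <- pairs$distance_bp >= config$min_distance_bp &
    pairs$distance_bp <= config$max_distance_bp
  pp <- pairs[keep, ]
  edges <- config$min_distance_bp +
    config$bin_width_bp * (0:config$n_bins)
  in_bins <- pp$distance_bp > edges[1L] &
    pp$distance_bp <= edges[length(edges)]
  n_beyond <- sum(!in_bins)
  pp <- pp[in_bins, ]
  if (nrow(pp) == 0L) stop("no pairs fall inside the binned range",
                           call. = FALSE)
  r2_adj <- as.numeric(adjust_r2(pp$r2, pp$n_used,
                                 config$sample_size_adjustment))
  idx <- pmin(findInterval(pp$distance_bp, edges, left.open = TRUE),
              config$n_bins)
  counts <- tabulate(idx, nbins = config$n_bins)
  mean_d <- vapply(seq_len(config$n_bins),
                   function(b) mean(pp$distance_bp[idx == b]), 0)
  mean_r <- vapply(seq_len(config$n_bins),
                   function(b) mean(r2_adj[idx == b]), 0)

  c_used <- rep(NA_real_, config$n_bins)
  c_used[counts > 0] <- physical_to_c(mean_d[counts > 0],
                                      config$recomb_rate_cM_per_Mb,
                                      config$mapping_function)
  well_posed <- counts > 0 & is.finite(mean_r) & mean_r > 0 &
    (1 / mean_r) > config$alpha
  ne <- ifelse(well_posed,
               (1 / (4 * c_used)) * (1 / mean_r - config$alpha),
               NA_real_)
  out <- tibble::tibble(
    bin_start = edges[seq_len(config$n_bins)],
    bin_end = edges[seq_len(config$n_bins) + 1L],
    n_pairs = counts,
    mean_distance_bp = ifelse(counts > 0, mean_d, NA_real_),
    mean_r2_adj = ifelse(counts > 0, mean_r, NA_real_),
    c_used = ifelse(counts > 0, c_used, NA_real_),
    generations_ago_t = ifelse(counts > 0, 1 / (2 * c_used), NA_real_),
    ne = ne,
    well_posed = well_posed
  )
  attr(out, "n_pairs_beyond_bins") <- n_beyond
  attr(out, "config") <- config
  class(out) <- c("ne_trajectory", class(out))
  out
}

#' Harmonic mean of Ne values
#'
#' `k / sum(1 / Ne_i)` — the summary appropriate for effective sizes,
#' which combine harmonically over time.
#'
#' @param values Positive Ne values.
#' @return The harmonic mean.
#' @export
harmonic_mean_ne <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L || any(values <= 0)) {
    stop("harmonic mean needs a non-empty set of positive values",
         call. = FALSE)
  }
  length(values) / sum(1 / values)
}

#' Per-chromosome harmonic-mean Ne
#'
#' Runs [estimate_ne_trajectory()] separately on each chromosome's pairs
#' and summarises every chromosome's valid bins with a harmonic mean,
#' reporting the realized range of generations the bins cover.
#'
#' @param pairs An `ld_pairs` tibble.
#' @param config An [ne_config()].
#' @return A tibble with `chromosome`, `n_bins_used`, `ne_harmonic`,
#'   `t_min`, `t_max`.
#' @export
chromosome_ne <- function(pairs, config = ne_config()) {
  pairs |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::group_map(function(df, key) {
      traj <- tryCatch(
        estimate_ne_trajectory(df, config),
        error = function(e) NULL
      )
      if (is.null(traj) || !any(traj$well_posed)) {
        return(tibble::tibble(
          chromosome = key$chromosome, n_bins_used = 0L,
          ne_harmonic = NA_real_, t_min = NA_real_, t_max = NA_real_
        ))
      }
      ok <- traj$well_posed
      tibble::tibble(
        chromosome = key$chromosome,
        n_bins_used = sum(ok),
        ne_harmonic = harmonic_mean_ne(traj$ne[ok]),
        t_min = min(traj$generations_ago_t[ok]),
        t_max = max(traj$generations_ago_t[ok])
      )
    }) |>
    dplyr::bind_rows()
}

#' Plot a historical Ne trajectory
#'
#' @param object An `ne_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object: Ne against generations ago (log-x).
#' @export
autoplot.ne_trajectory <- function(object, ...) {
  df <- object[object$well_posed, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$generations_ago_t, y = .data$ne
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Generations ago (t = 1/2c)", y = "Ne") +
    ggplot2::theme_minimal()
}
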