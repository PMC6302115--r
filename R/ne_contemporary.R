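#' Bias-correction and inversion constants for the LD Ne method
#'
#' The single-point (contemporary) LD method corrects the mean pairwise
#' r2 for the expected sample-induced component at harmonic-mean sample
#' size S, then inverts the drift expectation into Ne. The empirical
#' constants (Waples 2006; as used by NeEstimator v2) are centralised
#' here so any dialect difference from other implementations is
#' auditable in one place. Rows are keyed by mating model and sample-size
#' branch:
#'
#' * sample expectation, S >= 30: `E_sample = 1/S + 3.19/S^2`
#' * sample expectation, S < 30:  `E_sample = 0.0018 + 0.907/S + 4.44/S^2`
#' * drift expectation: `E_drift = b1/Ne + b2/Ne^2`, inverted as
#'   `Ne = (b1 + sqrt(b1^2 + 4 b2 r2')) / (2 r2')`
#'
#' with (b1, b2) = (1/3, 0.69) random mating S >= 30; (0.308, 0.52)
#' random S < 30; (2/3, 1.80) monogamy S >= 30; (0.618, 1.31) monogamy
#' S < 30.
#'
#' @format A data frame with columns `mating_model`, `branch`, `b1`, `b2`.
#' @export
ldne_constants <- data.frame(
  mating_model = c("random", "random", "monogamy", "monogamy"),
  branch = c("ge30", "lt30", "ge30", "lt30"),
  b1 = c(1 / 3, 0.308, 2 / 3, 0.618),
  b2 = c(0.69, 0.52, 1.80, 1.31)
)

# Expected sample-induced r2 at (harmonic mean) sample size S.
ldne_expected_sample_r2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

#' Invert a drift r-squared into contemporary Ne
#'
#' Solves `r2_drift = b1/Ne + b2/Ne^2` for Ne with the constants of the
#' chosen mating model and sample-size branch (see [ldne_constants]).
#' Non-positive `r2_drift` (all observed LD explained by sampling) gives
#' an infinite estimate.
#'
#' @param r2_drift Mean r2 after subtracting the sample expectation.
#' @param mating_model `"monogamy"` (non-random mating) or `"random"`.
#' @param S Harmonic-mean sample size, used to pick the branch.
#' @return The Ne estimate (possibly `Inf`).
#' @export
ldne_invert <- function(r2_drift, mating_model = c("monogamy", "random"),
                        S = 30) {
  mating_model <- match.arg(mating_model)
  if (r2_drift <= 0) return(Inf)
  branch <- if (S >= 30) "ge30" else "lt30"
  row <- ldne_constants[ldne_constants$mating_model == mating_model &
                          ldne_constants$branch == branch, ]
  (row$b1 + sqrt(row$b1^2 + 4 * row$b2 * r2_drift)) / (2 * r2_drift)
}

#' Contemporary Ne by the LD method
#'
#' Screens out markers whose within-sample minor allele frequency is
#' below `pcrit` (a per-analysis screen, not a QC mutation of the
#' panel), computes the mean dosage r2 over all remaining marker
#' pairs — including pairs on the same chromosome beyond
#' `min_pair_distance`, and all cross-chromosome pairs — in the
#' Burrows-composite dialect (Pearson correlation times `n/(n-1)`,
#' squared, matching the published LD-method implementation the Waples
#' bias correction was calibrated for), subtracts the expected sample
#' component at the harmonic-mean pairwise sample size (missing
#' genotypes handled by pairwise deletion), and inverts the drift
#' expectation under the chosen mating model. A corrected r2 at or
#' below zero yields an infinite estimate. Note the drift expectation
#' assumes effectively unlinked loci: physically close pairs inflate
#' the estimate downward, so panels on few long chromosomes should use
#' `min_pair_distance` (or rely on cross-chromosome pairs).
#'
#' @param panel A post-QC [genotype_panel()].
#' @param pcrit Allele-frequency screening threshold (default 0.05).
#' @param mating_model `"monogamy"` (default, non-random mating) or
#'   `"random"`.
#' @param min_pair_distance Minimum bp distance for same-chromosome pairs
#'   (default 0 = all pairs allowed).
#' @return A one-row tibble: `population`, `ne`, `mean_r2`,
#'   `expected_sample_r2`, `r2_drift`, `harmonic_mean_s`, `n_markers`,
#'   `n_pairs`, `mating_model`, `pcrit`.
#' @export
ld_ne_point_estimate <- function(panel, pcrit = 0.05,
                                 mating_model = c("monogamy", "random"),
                                 min_pair_distance = 0) {
  mating_model <- match.arg(mating_model)
  if (pcrit < 0 || pcrit >= 0.5) stop("pcrit must be in [0, 0.5)",
                                      call. = FALSE)
  maf <- col_maf(panel$dosages)
  keep <- !is.na(maf) & maf >= pcrit
  if (sum(keep) < 2L) stop("fewer than 2 markers pass the pcrit screen",
                           call. = FALSE)
  dos <- panel$dosages[, keep, drop = FALSE]
  map <- panel$map[keep, ]
  m <- ncol(dos)

  cc <- suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs"))
  nu <- crossprod(!is.na(dos))
  ut <- upper.tri(cc)
  same_chr <- outer(map$chromosome, map$chromosome, "==")
  dist_ok <- !same_chr |
    abs(outer(map$position_bp, map$position_bp, "-")) >= min_pair_distance
  sel <- ut & dist_ok & !is.na(cc) & nu >= 3
  n_used <- nu[sel]
  # Burrows-composite scaling: the reference implementation's r carries
  # an n/(n-1) factor relative to the plain Pearson correlation, and
  # the Waples sample-size expectation is calibrated for that dialect
  r2 <- (cc[sel] * n_used / (n_used - 1))^2
  if (length(r2) == 0L) stop("no marker pairs after screening",
                             call. = FALSE)

  S <- length(n_used) / sum(1 / n_used)
  mean_r2 <- mean(r2)
  e_sample <- ldne_expected_sample_r2(S)
  r2_drift <- mean_r2 - e_sample
  ne <- ldne_invert(r2_drift, mating_model, S)

  tibble::tibble(
    population = panel$population,
    ne = ne,
    mean_r2 = mean_r2,
    expected_sample_r2 = e_sample,
    r2_drift = r2_drift,
    harmonic_mean_s = S,
    n_markers = m,
    n_pairs = length(r2),
    mating_model = mating_model,
    pcrit = pcrit
  )
}

#' Method-of-moments pairwise relatedness (PI_HAT)
#'
#' Genome-wide IBD-sharing estimates in the PLINK convention:
#' per-pair observed identity-by-state (IBS) counts are combined with
#' their expectations under IBD states 0/1/2 to give method-of-moments
#' estimates of P(IBD = 0/1/2), clamped to the probability simplex;
#' the summary statistic is `PI_HAT = P(IBD = 2) + P(IBD = 1) / 2`.
#' The expectations use sample allele frequencies with the
#' finite-sample correction factors of the PLINK `--genome`
#' implementation (ratios of observed allele counts, `X/(X-1)` style),
#' without which P(IBD = 0) is systematically underestimated and
#' PI_HAT inflated at small sample sizes. Markers need at least two
#' copies of each allele to be informative; a warning is issued when
#' fewer than 100 such markers are available.
#'
#' @param panel A [genotype_panel()] with >= 2 individuals.
#' @return A tibble of pairs: `sample_i`, `sample_j`, `pi_hat`, `n_markers`;
#'   attributes `mean_relatedness` and `sd_relatedness` carry the
#'   population summary.
#' @export
estimate_pairwise_relatedness <- function(panel) {
  dos <- panel$dosages
  n <- nrow(dos)
  if (n < 2L) stop("need >= 2 individuals", call. = FALSE)
  n_obs <- colSums(!is.na(dos))
  x <- colSums(dos, na.rm = TRUE)        # alt-allele count
  y <- 2 * n_obs - x                     # ref-allele count
  informative <- x >= 2 & y >= 2 & (x + y) > 3
  if (sum(informative) < 100L) {
    warning("fewer than 100 informative markers; relatedness estimates ",
            "will be unstable", call. = FALSE)
  }
  dos <- dos[, informative, drop = FALSE]
  x <- x[informative]
  y <- y[informative]
  bigx <- x + y
  p <- x / bigx
  q <- 1 - p

  # finite-sample corrected P(IBS | IBD) per marker (PLINK --genome)
  c1 <- bigx / (bigx - 1)
  c2 <- bigx / (bigx - 2)
  c3 <- bigx / (bigx - 3)
  fx1 <- (x - 1) / x
  fx2 <- (x - 2) / x
  fy1 <- (y - 1) / y
  fy2 <- (y - 2) / y
  a00 <- 2 * p^2 * q^2 * fx1 * fy1 * c1 * c2 * c3
  a10 <- 4 * p^3 * q * fx1 * fx2 * fy1 * c1 * c2 * c3 +
    4 * p * q^3 * fy1 * fy2 * fx1 * c1 * c2 * c3
  a20 <- 1 - a00 - a10
  a11 <- 2 * p^2 * q * fx1 * c1 * c2 + 2 * p * q^2 * fy1 * c1 * c2
  a21 <- 1 - a11

  pairs_idx <- utils::combn(n, 2L)
  n_pairs <- ncol(pairs_idx)
  out <- tibble::tibble(
    sample_i = character(n_pairs), sample_j = character(n_pairs),
    pi_hat = numeric(n_pairs), n_markers = integer(n_pairs)
  )
  ids <- rownames(dos)
  for (k in seq_len(n_pairs)) {
    i <- pairs_idx[1L, k]
    j <- pairs_idx[2L, k]
    gi <- dos[i, ]
    gj <- dos[j, ]
    ok <- !is.na(gi) & !is.na(gj)
    d <- abs(gi[ok] - gj[ok])
    ibs0 <- sum(d == 2)
    ibs1 <- sum(d == 1)
    ibs2 <- sum(d == 0)
    s00 <- sum(a00[ok])
    s10 <- sum(a10[ok])
    s20 <- sum(a20[ok])
    s11 <- sum(a11[ok])
    s21 <- sum(a21[ok])
    n_ok <- sum(ok)

    p0 <- if (s00 > 0) ibs0 / s00 else 0
    p1 <- if (s11 > 0) (ibs1 - p0 * s10) / s11 else 0
    p2 <- (ibs2 - p0 * s20 - p1 * s21) / n_ok
    # clamp to the probability simplex
    pr <- pmin(pmax(c(p0, p1, p2), 0), 1)
    if (sum(pr) > 0) pr <- pr / sum(pr)
    out$sample_i[k] <- ids[i]
    out$sample_j[k] <- ids[j]
    out$pi_hat[k] <- pr[3L] + pr[2L] / 2
    out$n_markers[k] <- n_ok
  }
  attr(out, "mean_relatedness") <- mean(out$pi_hat)
  attr(out, "sd_relatedness") <- stats::sd(out$pi_hat)
  out
}
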