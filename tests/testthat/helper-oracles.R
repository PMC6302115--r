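# Independent oracles used across the suite. These deliberately take the
# slow, direct route (full enumeration, explicit arithmetic, power
# iteration) so they share no code path with the package.

# Exact HWE p-value by brute-force enumeration of every heterozygote
# count consistent with the observed allele counts, using the closed-form
# conditional probability written out with log-factorials.
hwe_enum_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  rare <- min(n_alt, 2 * n - n_alt)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lfactorial(n) - lfactorial(hom_r) - lfactorial(h) -
      lfactorial(hom_c) + h * log(2) +
      lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp)
  obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

# Pearson correlation written out longhand.
pearson_r2_by_hand <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  (num / den)^2
}

# Haplotype r2 straight from phased 0/1 haplotype columns.
haplotype_r2 <- function(hap_i, hap_j) {
  pA <- mean(hap_i)
  pB <- mean(hap_j)
  pAB <- mean(hap_i == 1 & hap_j == 1)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Top-k eigenvalues of a symmetric matrix by power iteration with
# deflation (independent of LAPACK's eigen()).
power_iteration_eigen <- function(mat, k, iters = 10000, tol = 1e-13) {
  vals <- numeric(k)
  m <- mat
  for (comp in seq_len(k)) {
    # generic start vector (an all-ones start can be orthogonal to the
    # leading eigenvector of a centered kernel)
    v <- sin(seq_len(nrow(m)) + comp)
    v <- v / sqrt(sum(v^2))
    lambda <- 0
    for (i in seq_len(iters)) {
      w <- m %*% v
      lambda_new <- sqrt(sum(w^2))
      if (lambda_new < 1e-14) { lambda <- 0; break }
      v_new <- as.vector(w) / lambda_new
      if (max(abs(abs(v_new) - abs(v))) < tol) {
        v <- v_new
        lambda <- lambda_new
        break
      }
      v <- v_new
      lambda <- lambda_new
    }
    vals[comp] <- sum(v * (m %*% v))
    m <- m - vals[comp] * tcrossprod(v)
  }
  vals
}

# Hudson-style Fst from two allele-frequency vectors and sample sizes
# (ratio-of-averages estimator).
fst_hudson <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Restrict a panel to marker indices (in map order) without reaching
# into package internals.
subset_markers_public <- function(panel, idx) {
  m <- panel$map[idx, ]
  map <- marker_map(m$marker_id, m$chromosome, m$position_bp,
                    m$allele_ref, m$allele_alt)
  genotype_panel(panel$dosages[, idx, drop = FALSE], map,
                 population = panel$population,
                 sample_ids = rownames(panel$dosages))
}

# A tiny deterministic panel for IO and QC tests.
make_test_panel <- function(n = 6, m = 10, seed = 42, population = "test",
                            missing_rate = 0) {
  withr::with_seed(seed, {
    p <- runif(m, 0.2, 0.8)
    dos <- sapply(p, function(pp) rbinom(n, 2, pp))
    if (missing_rate > 0) {
      dos[runif(length(dos)) < missing_rate] <- NA
    }
    chrom <- rep(c("1", "2"), each = ceiling(m / 2))[seq_len(m)]
    pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1e5
    map <- marker_map(
      paste0("snp", seq_len(m)),
      chromosome = chrom,
      position_bp = pos,
      allele_ref = "A", allele_alt = "C"
    )
    genotype_panel(dos, map, population = population)
  })
}
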