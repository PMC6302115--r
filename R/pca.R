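#' Variance-standardize a dosage matrix
#'
#' Column j is transformed as `(g - 2 p_j) / sqrt(2 p_j (1 - p_j))` with
#' `p_j` the sample alternate-allele frequency — the usual GRM scaling
#' for genotype PCA. Missing dosages are mean-imputed (0 after
#' centering); monomorphic columns carry no information and are dropped
#' with a warning.
#'
#' @param panel A post-QC [genotype_panel()].
#' @return A samples x markers numeric matrix; attribute `dropped` lists
#'   dropped monomorphic marker ids.
#' @export
standardize_genotypes <- function(panel) {
  dos <- panel$dosages
  p <- col_alt_freq(dos)
  poly <- !is.na(p) & p > 0 & p < 1
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic marker(s) dropped before PCA",
            call. = FALSE)
  }
  x <- dos[, poly, drop = FALSE]
  pp <- p[poly]
  x <- sweep(x, 2L, 2 * pp, "-")
  x <- sweep(x, 2L, sqrt(2 * pp * (1 - pp)), "/")
  x[is.na(x)] <- 0
  attr(x, "dropped") <- panel$map$marker_id[!poly]
  x
}

#' PCA of standardized genotypes
#'
#' Eigendecomposition of the samples x samples covariance of the
#' standardized dosage matrix (scaled by 1/#markers). Variance explained
#' is each eigenvalue over the sum of ALL eigenvalues, so the reported
#' percentages are well defined regardless of how many components are
#' retained. Component signs follow a deterministic convention: the
#' largest-magnitude coordinate of each component is positive.
#'
#' @param panel A post-QC [genotype_panel()], or a list of panels (e.g.
#'   the output of [intersect_markers()]) analysed jointly with their
#'   population labels retained.
#' @param k Number of components to retain (default 10; truncated with a
#'   warning if it exceeds the rank bound `min(samples - 1, markers)`).
#' @return An object of class `genotype_pca` with elements
#'   `coordinates` (tibble: `sample_id`, `population`, `PC1..PCk`),
#'   `eigenvalues` (all of them), `pct_variance` (percent per component,
#'   all components), `k`.
#' @export
pca_genotypes <- function(panel, k = 10) {
  if (inherits(panel, "genotype_panel")) {
    panels <- list(panel)
  } else {
    panels <- panel
  }
  labels <- unlist(lapply(panels, function(p) {
    rep(p$population, n_samples(p))
  }))
  ids <- unlist(lapply(panels, function(p) rownames(p$dosages)))
  if (length(panels) > 1L) {
    panels <- intersect_markers(panels)
    dos <- do.call(rbind, lapply(panels, function(p) p$dosages))
    map <- panels[[1L]]$map
    merged <- genotype_panel(dos, map, population = "combined",
                             sample_ids = make.unique(ids))
  } else {
    merged <- panels[[1L]]
  }
  x <- standardize_genotypes(merged)
  n <- nrow(x)
  m <- ncol(x)
  if (n < 2L || m < 2L) stop("PCA needs >= 2 samples and >= 2 polymorphic ",
                             "markers", call. = FALSE)
  cov_s <- tcrossprod(x) / m
  eig <- eigen(cov_s, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  rank_bound <- min(n - 1L, m)
  if (k > rank_bound) {
    warning("k reduced from ", k, " to rank bound ", rank_bound,
            call. = FALSE)
    k <- rank_bound
  }
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude coordinate positive
  for (j in seq_len(k)) {
    peak <- which.max(abs(vecs[, j]))
    if (vecs[peak, j] < 0) vecs[, j] <- -vecs[, j]
  }
  coords <- sweep(vecs, 2L, sqrt(vals[seq_len(k)]), "*")
  colnames(coords) <- paste0("PC", seq_len(k))
  pct <- 100 * vals / sum(vals)
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble::tibble(sample_id = ids, population = labels),
        tibble::as_tibble(coords)
      ),
      eigenvalues = vals,
      pct_variance = pct,
      k = k
    ),
    class = "genotype_pca"
  )
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat("<genotype_pca> ", nrow(x$coordinates), " samples, ", x$k,
      " components retained\n", sep = "")
  cat("  PC1..PC", min(3L, x$k), " variance: ",
      paste0(sprintf("%.1f%%", x$pct_variance[seq_len(min(3L, x$k))]),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tidy a genotype PCA
#'
#' @param x A `genotype_pca` object.
#' @param ... Unused.
#' @return Sample coordinates in long form: `sample_id`, `population`,
#'   `component`, `value`.
#' @export
tidy.genotype_pca <- function(x, ...) {
  tidyr::pivot_longer(x$coordinates,
                      cols = dplyr::starts_with("PC"),
                      names_to = "component", values_to = "value")
}

#' One-row summary of a genotype PCA
#'
#' @param x A `genotype_pca` object.
#' @param ... Unused.
#' @return A tibble with `n_samples`, `k`, `pct_pc1`, `pct_pc2`,
#'   `pct_pc1_pc2`, `total_variance`.
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    k = x$k,
    pct_pc1 = x$pct_variance[1L],
    pct_pc2 = if (length(x$pct_variance) > 1L) x$pct_variance[2L] else NA_real_,
    pct_pc1_pc2 = sum(x$pct_variance[seq_len(min(2L, length(x$pct_variance)))]),
    total_variance = sum(x$eigenvalues)
  )
}

#' Plot the first two principal components
#'
#' @param object A `genotype_pca` object.
#' @param ... Unused.
#' @return A ggplot object coloured by population.
#' @export
autoplot.genotype_pca <- function(object, ...) {
  ggplot2::ggplot(object$coordinates, ggplot2::aes(
    x = .data$PC1, y = .data$PC2, colour = .data$population
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$pct_variance[1L]),
      y = sprintf("PC2 (%.1f%%)", object$pct_variance[2L])
    ) +
    ggplot2::theme_minimal()
}
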