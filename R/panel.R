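#' Construct a marker map
#'
#' A marker map is the physical-distance backbone of every LD computation:
#' one row per biallelic SNP with its chromosome and 1-based bp position.
#' Rows are sorted by (chromosome, position) and positions must be strictly
#' increasing within a chromosome, so `|pos_i - pos_j|` is always a valid
#' pairwise distance.
#'
#' @param marker_id Character vector of unique marker names.
#' @param chromosome Character (or coercible) chromosome labels.
#' @param position_bp Integer-valued 1-based physical positions.
#' @param allele_ref,allele_alt Single-character alleles. The "reference"
#'   allele is only a dosage-counting convention; all downstream statistics
#'   are invariant to swapping the two labels.
#'
#' @return A tibble of class `marker_map` with columns `marker_id`,
#'   `chromosome`, `position_bp`, `allele_ref`, `allele_alt`, sorted by
#'   (chromosome, position_bp).
#' @export
marker_map <- function(marker_id, chromosome, position_bp,
                       allele_ref = "A", allele_alt = "B") {
  map <- tibble::tibble(
    marker_id = as.character(marker_id),
    chromosome = as.character(chromosome),
    position_bp = as.integer(round(position_bp)),
    allele_ref = rep_len(as.character(allele_ref), length(marker_id)),
    allele_alt = rep_len(as.character(allele_alt), length(marker_id))
  )
  if (anyDuplicated(map$marker_id)) {
    stop("marker_id values must be unique", call. = FALSE)
  }
  if (nrow(map) && any(map$position_bp < 1L)) {
    stop("position_bp must be >= 1 (1-based coordinates)", call. = FALSE)
  }
  map <- dplyr::arrange(map, .data$chromosome, .data$position_bp)
  dup <- duplicated(map[, c("chromosome", "position_bp")])
  if (any(dup)) {
    stop(
      "duplicate (chromosome, position) pairs: ",
      paste(map$marker_id[dup], collapse = ", "),
      call. = FALSE
    )
  }
  class(map) <- c("marker_map", class(map))
  map
}

#' Construct a genotype panel
#'
#' Bundles a dosage matrix (individuals x markers, values 0/1/2/NA counted
#' as number of non-reference alleles) with its marker map and a population
#' label. This is the unit every pipeline stage consumes: one panel per
#' population.
#'
#' @param dosages Numeric matrix, rows = individuals, columns = markers in
#'   map order. Values must be 0, 1, 2 or NA (missing genotype).
#' @param map A [marker_map()] with one row per column of `dosages`.
#' @param population Population label, e.g. `"NAM"`.
#' @param sample_ids Optional character vector of individual ids; defaults
#'   to rownames of `dosages` or `"<population>_1"`, ...
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `population`, `dosages` (with sample/marker dimnames) and `map`.
#' @export
genotype_panel <- function(dosages, map, population = "pop",
                           sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (!inherits(map, "marker_map")) {
    stop("`map` must be a marker_map", call. = FALSE)
  }
  if (ncol(dosages) != nrow(map)) {
    stop("dosage matrix has ", ncol(dosages), " columns but map has ",
         nrow(map), " markers", call. = FALSE)
  }
  if (nrow(dosages) < 1L) stop("panel must contain >= 1 individual", call. = FALSE)
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) {
      sample_ids <- paste0(population, "_", seq_len(nrow(dosages)))
    }
  }
  dimnames(dosages) <- list(as.character(sample_ids), map$marker_id)
  structure(
    list(population = population, dosages = dosages, map = map),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(
    "<genotype_panel> ", x$population, ": ",
    nrow(x$dosages), " individuals x ", ncol(x$dosages), " markers on ",
    length(unique(x$map$chromosome)), " chromosome(s), ",
    sprintf("%.2f%%", 100 * miss), " missing\n",
    sep = ""
  )
  invisible(x)
}

#' Number of individuals / markers in a panel
#' @param panel A [genotype_panel()].
#' @return Integer count.
#' @export
n_samples <- function(panel) nrow(panel$dosages)

#' @rdname n_samples
#' @export
n_markers <- function(panel) ncol(panel$dosages)

#' Dosage matrix as a tibble
#'
#' One row per individual, one column per marker, plus `sample_id` and
#' `population` columns; convenient for dplyr-style exploration.
#'
#' @param x A `genotype_panel`.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.genotype_panel <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      population = x$population,
      sample_id = rownames(x$dosages)
    ),
    tibble::as_tibble(x$dosages)
  )
}

# Restrict a panel to a subset of marker columns (logical or index vector),
# keeping map and dosages aligned.
subset_markers <- function(panel, keep) {
  map <- panel$map[keep, , drop = FALSE]
  class(map) <- unique(c("marker_map", class(map)))
  genotype_panel(
    panel$dosages[, keep, drop = FALSE], map,
    population = panel$population,
    sample_ids = rownames(panel$dosages)
  )
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards; keeps all package randomness seed-driven
# without clobbering user state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
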