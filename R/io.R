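#' Read a PLINK text PED/MAP file pair
#'
#' Parses whitespace-delimited PED/MAP files into a [genotype_panel()].
#' Genotypes are coded as the number of non-reference alleles (0/1/2);
#' the missing allele code `0 0` becomes a missing dosage. PED files carry
#' no reference-allele designation, so by default the first allele seen in
#' the file for each marker is taken as "reference". Every downstream
#' statistic (MAF, HWE, r2, PCA) is invariant to that choice; pass
#' `ref_alleles` when an exact dosage orientation matters (e.g. round
#' trips).
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param population Population label for the panel; defaults to the PED
#'   family id of the first individual.
#' @param ref_alleles Optional character vector of reference alleles, named
#'   by marker id, overriding the first-seen convention.
#'
#' @return A [genotype_panel()] (its `$map` is the [marker_map()]), with
#'   markers sorted by (chromosome, position).
#' @export
read_plink_text <- function(ped_path, map_path, population = NULL,
                            ref_alleles = NULL) {
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) < 4L) {
    stop("MAP file must have 4 columns (chrom, id, cM, bp)", call. = FALSE)
  }
  n_mark <- nrow(map_raw)
  ped_raw <- utils::read.table(ped_path, header = FALSE,
                               colClasses = "character")
  if (ncol(ped_raw) != 6L + 2L * n_mark) {
    stop("PED has ", ncol(ped_raw), " columns; expected ",
         6L + 2L * n_mark, " for ", n_mark, " MAP markers", call. = FALSE)
  }
  n_ind <- nrow(ped_raw)
  a1 <- as.matrix(ped_raw[, 6L + 2L * seq_len(n_mark) - 1L, drop = FALSE])
  a2 <- as.matrix(ped_raw[, 6L + 2L * seq_len(n_mark), drop = FALSE])

  marker_ids <- map_raw[[2L]]
  ref <- character(n_mark)
  alt <- character(n_mark)
  dos <- matrix(NA_real_, n_ind, n_mark)
  for (j in seq_len(n_mark)) {
    al1 <- a1[, j]
    al2 <- a2[, j]
    obs <- c(rbind(al1, al2))
    obs_nm <- obs[obs != "0"]
    alleles <- unique(obs_nm)
    if (length(alleles) > 2L) {
      stop("marker ", marker_ids[j], " has >2 alleles (",
           paste(alleles, collapse = "/"), ")", call. = FALSE)
    }
    rj <- if (!is.null(ref_alleles) && marker_ids[j] %in% names(ref_alleles)) {
      ref_alleles[[marker_ids[j]]]
    } else if (length(alleles)) alleles[1L] else "A"
    aj <- setdiff(alleles, rj)
    if (length(aj) == 0L) aj <- if (rj == "B") "A" else "B"  # monomorphic
    ref[j] <- rj
    alt[j] <- aj[1L]
    miss <- al1 == "0" | al2 == "0"
    dos[, j] <- (al1 != rj) + (al2 != rj)
    dos[miss, j] <- NA_real_
  }

  map <- marker_map(marker_ids, map_raw[[1L]],
                    as.numeric(map_raw[[4L]]), ref, alt)
  ord <- match(map$marker_id, marker_ids)
  if (is.null(population)) population <- ped_raw[1L, 1L]
  genotype_panel(dos[, ord, drop = FALSE], map,
                 population = population, sample_ids = ped_raw[[2L]])
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Uses `vcfR` to parse the file, keeps biallelic SNP records only
#' (multiallelic records are skipped with a warning reporting the count),
#' and codes the GT field as ALT-allele dosage; phasing is ignored and
#' `./.` becomes missing.
#'
#' @param vcf_path Path to a VCF 4.x file with a GT FORMAT field.
#' @param population Population label (default `"pop"`).
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(vcf_path, population = "pop") {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  alt_field <- vcfR::getALT(v)
  multi <- grepl(",", alt_field, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped", call. = FALSE)
    v <- v[!multi, ]
    alt_field <- alt_field[!multi]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  ref <- vcfR::getREF(v)
  ids <- vcfR::getID(v)
  fix_id <- is.na(ids) | ids == "."
  ids[fix_id] <- paste0(chrom[fix_id], "_", pos[fix_id])

  # GT strings like 0/1, 1|1, ./.; dosage = count of "1" alleles
  count_alt <- function(g) {
    alleles <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
    vapply(alleles, function(a) {
      if (any(a == "." | is.na(a))) NA_real_ else sum(a == "1")
    }, numeric(1))
  }
  dos <- t(apply(gt, 1L, count_alt))
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = length(ids))
  dos[is.na(gt)] <- NA_real_

  map <- marker_map(ids, chrom, pos, ref, alt_field)
  ord <- match(map$marker_id, ids)
  genotype_panel(t(dos[ord, , drop = FALSE]), map,
                 population = population, sample_ids = colnames(gt))
}

#' Write a panel as PLINK text PED/MAP
#'
#' Inverse of [read_plink_text()]: dosage 0/1/2 become `ref ref`,
#' `ref alt`, `alt alt`; missing dosages are written as the PED missing
#' code `0 0`. Re-reading with `ref_alleles = ` the panel's reference
#' alleles reproduces the dosage matrix exactly.
#'
#' @param panel A [genotype_panel()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_plink_text <- function(panel, ped_path, map_path) {
  map <- panel$map
  utils::write.table(
    data.frame(map$chromosome, map$marker_id, 0, map$position_bp),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE
  )
  dos <- panel$dosages
  n <- nrow(dos)
  m <- ncol(dos)
  geno <- matrix("0 0", n, m)
  for (j in seq_len(m)) {
    g <- dos[, j]
    geno[, j] <- dplyr::case_when(
      is.na(g) ~ "0 0",
      g == 0 ~ paste(map$allele_ref[j], map$allele_ref[j]),
      g == 1 ~ paste(map$allele_ref[j], map$allele_alt[j]),
      TRUE ~ paste(map$allele_alt[j], map$allele_alt[j])
    )
  }
  lines <- cbind(panel$population, rownames(dos), "0", "0", "0", "-9", geno)
  utils::write.table(lines, ped_path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(list(ped = ped_path, map = map_path))
}

#' Write / read a TSV dosage matrix
#'
#' Plain samples-by-markers table: first column `sample_id`, remaining
#' columns one per marker (header row of marker ids), values 0/1/2 or `NA`.
#' The marker map travels separately; [read_tsv_matrix()] needs it to
#' rebuild a panel.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_matrix <- function(panel, path) {
  df <- data.frame(sample_id = rownames(panel$dosages),
                   panel$dosages, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @param tsv_path Path written by [write_tsv_matrix()].
#' @param map The panel's [marker_map()].
#' @param population Population label.
#' @export
read_tsv_matrix <- function(tsv_path, map, population = "pop") {
  df <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  dos <- as.matrix(df[, -1L, drop = FALSE])
  dos <- dos[, match(map$marker_id, colnames(dos)), drop = FALSE]
  genotype_panel(dos, map, population = population,
                 sample_ids = df$sample_id)
}

#' Restrict panels to their common markers
#'
#' After per-population QC each panel keeps its own marker set; joint
#' analyses (PCA, cross-population LD comparisons) use the intersection.
#' Marker identity is (chromosome, position, unordered allele pair), so a
#' marker whose alleles differ between panels is not matched; strand flips
#' are deliberately not auto-resolved.
#'
#' @param panels A list of two or more [genotype_panel()]s.
#' @return The input list with every panel restricted to the common
#'   markers (map order preserved); attribute `n_common` carries the count.
#' @export
intersect_markers <- function(panels) {
  if (length(panels) < 2L) {
    stop("need >= 2 panels to intersect", call. = FALSE)
  }
  key <- function(map) {
    al <- ifelse(map$allele_ref < map$allele_alt,
                 paste(map$allele_ref, map$allele_alt),
                 paste(map$allele_alt, map$allele_ref))
    paste(map$chromosome, map$position_bp, al)
  }
  keys <- lapply(panels, function(p) key(p$map))
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) {
    stop("no common markers across the supplied panels", call. = FALSE)
  }
  out <- purrr::map2(panels, keys, function(p, k) {
    subset_markers(p, k %in% common)
  })
  attr(out, "n_common") <- length(common)
  out
}
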