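test_that("genotypic r2 matches hand-computed Pearson arithmetic", {
  expect_equal(as.numeric(r2_genotypic(c(0, 1, 2, 1), c(0, 1, 2, 1))), 1)
  expect_equal(as.numeric(r2_genotypic(c(0, 0, 2, 2), c(2, 2, 0, 0))), 1)
  x <- c(0, 1, 2, 1)
  y <- c(1, 0, 1, 2)
  expect_equal(as.numeric(r2_genotypic(x, y)), pearson_r2_by_hand(x, y))
  # pairwise-complete handling records n_used
  v <- r2_genotypic(c(0, NA, 2, 1, 1), c(1, 1, 2, NA, 0))
  expect_equal(attr(v, "n_used"), 3L)
  # monomorphic among complete pairs -> undefined
  expect_true(is.na(r2_genotypic(c(0, 0, 0, 2), c(1, 2, 0, NA))))
})

test_that("EM r2 reproduces the direct haplotype-count answer", {
  # 100 individuals built from known haplotype counts 40 AB / 10 Ab /
  # 10 aB / 40 ab, paired so no double heterozygotes arise: phase is
  # unambiguous and D = 0.4 - 0.25 = 0.15, r2 = 0.15^2 / 0.5^4 = 0.36
  haps <- rbind(
    matrix(rep(c(1, 1), 40), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), 10), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), 10), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), 40), ncol = 2, byrow = TRUE)
  )
  # pair identical haplotypes: genotypes are 2x the haplotype, no hets
  dos_i <- 2 * haps[, 1]
  dos_j <- 2 * haps[, 2]
  expect_equal(as.numeric(r2_em(dos_i, dos_j)), 0.36, tolerance = 1e-9)

  # complete LD: only AB and ab haplotypes
  di <- c(rep(2, 30), rep(0, 70))
  expect_equal(as.numeric(r2_em(di, di)), 1, tolerance = 1e-9)

  # independence: haplotype frequencies equal products of allele freqs
  hi <- rep(c(1, 1, 0, 0), each = 25)
  hj <- rep(c(1, 0, 1, 0), each = 25)
  expect_equal(as.numeric(r2_em(2 * hi, 2 * hj)), 0, tolerance = 1e-9)
})

test_that("EM r2 equals haplotype-count r2 when phase is unambiguous", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      h1 <- rbinom(80, 1, runif(1, 0.2, 0.8))
      h2 <- ifelse(runif(80) < 0.8, h1, rbinom(80, 1, 0.5))
      # duplicate each haplotype into a homozygous diploid: no double hets
      if (var(h1) == 0 || var(h2) == 0) next
      em <- r2_em(2 * h1, 2 * h2)
      expect_equal(as.numeric(em), haplotype_r2(h1, h2), tolerance = 1e-8)
    }
  })
})

test_that("EM r2 on scrambled-phase genotypes recovers haplotypic r2", {
  # simulate a population with phase retained, form unphased genotypes
  # by random pairing of haplotypes, and compare the EM estimate with
  # the truth computed from the phased data
  cfg <- sim_config(
    ne_trajectory = list(c(0, 200)), n_chromosomes = 1,
    chromosome_length_bp = 5e6, n_segregating_target = 60,
    n_initial_sites = 300, burn_in = 150, sample_size = 200,
    maf_ascertainment = 0.1, seed = 33
  )
  sim <- suppressMessages(simulate_wf(cfg))
  hap <- sim$truth$haplotypes
  m <- ncol(hap)
  pairs <- withr::with_seed(34, {
    cbind(sample(m, 400, replace = TRUE), sample(m, 400, replace = TRUE))
  })
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  err <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    truth <- haplotype_r2(hap[, i], hap[, j])
    est <- as.numeric(r2_em(sim$panel$dosages[, i], sim$panel$dosages[, j]))
    abs(est - truth)
  }, numeric(1))
  expect_lt(mean(err), 0.02)
})

test_that("pairwise_ld enumerates within-chromosome pairs like a double loop", {
  panel <- make_test_panel(n = 40, m = 14, seed = 9)
  pairs <- pairwise_ld(panel, max_distance_bp = 10e6)
  # brute force oracle
  map <- panel$map
  expected <- 0
  for (a in seq_len(nrow(map) - 1)) {
    for (b in (a + 1):nrow(map)) {
      if (map$chromosome[a] == map$chromosome[b] &&
          abs(map$position_bp[a] - map$position_bp[b]) <= 10e6) {
        v <- suppressWarnings(
          cor(panel$dosages[, a], panel$dosages[, b],
              use = "pairwise.complete.obs")
        )
        if (!is.na(v)) expected <- expected + 1
      }
    }
  }
  expect_equal(nrow(pairs), expected)
  expect_true(all(pairs$distance_bp > 0))
  expect_true(all(pairs$r2 >= 0 & pairs$r2 <= 1))
  # within-chromosome rule: no cross-chromosome pairs
  chr_i <- map$chromosome[match(pairs$marker_i, map$marker_id)]
  chr_j <- map$chromosome[match(pairs$marker_j, map$marker_id)]
  expect_true(all(chr_i == chr_j))
})

test_that("r2 estimators are invariant to allele relabeling and sample order", {
  panel <- make_test_panel(n = 30, m = 8, seed = 15)
  pairs <- pairwise_ld(panel)
  flipped <- panel
  flipped$dosages <- 2 - flipped$dosages
  expect_equal(pairwise_ld(flipped)$r2, pairs$r2)
  shuffled <- panel
  ord <- withr::with_seed(16, sample(n_samples(panel)))
  shuffled$dosages <- shuffled$dosages[ord, ]
  expect_equal(pairwise_ld(shuffled)$r2, pairs$r2)
  # EM estimator too
  expect_equal(pairwise_ld(flipped, estimator = "em")$r2,
               pairwise_ld(panel, estimator = "em")$r2, tolerance = 1e-9)
})

test_that("bin_ld groups pairs like a brute-force grouped average", {
  withr::with_seed(19, {
    pairs <- tibble::tibble(
      chromosome = "1", marker_i = "a", marker_j = "b",
      pos_i = 0, pos_j = 0,
      distance_bp = sample(1:2e6, 1000),
      r2 = runif(1000), n_used = 50L
    )
  })
  curve <- bin_ld(pairs, bin_width_bp = 1e5, max_bp = 2e6)
  expect_equal(sum(curve$n_pairs), 1000)
  idx <- ceiling(pairs$distance_bp / 1e5)
  for (b in unique(idx)) {
    expect_equal(curve$mean_r2[b], mean(pairs$r2[idx == b]))
    expect_equal(curve$mean_distance_bp[b], mean(pairs$distance_bp[idx == b]))
  }
})

test_that("bin boundaries follow the worked example", {
  pairs <- tibble::tibble(
    chromosome = "1", marker_i = c("a", "a"), marker_j = c("b", "c"),
    pos_i = 0, pos_j = 0,
    distance_bp = c(10000, 150000), r2 = c(0.5, 0.1), n_used = 10L
  )
  curve <- bin_ld(pairs)
  expect_equal(curve$mean_r2[1], 0.5)
  expect_equal(curve$mean_r2[2], 0.1)
})

test_that("decay_threshold_distance interpolates the first downward crossing", {
  curve <- tibble::tibble(
    bin_start = c(0, 1e5), bin_end = c(1e5, 2e5), n_pairs = c(10L, 10L),
    mean_distance_bp = c(50000, 150000), mean_r2 = c(0.25, 0.15)
  )
  class(curve) <- c("ld_decay", class(curve))
  expect_equal(decay_threshold_distance(curve, 0.2), 100000)
  # all below threshold -> explicit NA
  low <- curve
  low$mean_r2 <- c(0.15, 0.10)
  expect_true(is.na(decay_threshold_distance(low, 0.2)))
  # never crosses -> NA
  high <- curve
  high$mean_r2 <- c(0.6, 0.5)
  expect_true(is.na(decay_threshold_distance(high, 0.2)))
})

test_that("adjacent_ld_summary averages consecutive-marker pairs only", {
  dos <- withr::with_seed(23, {
    sapply(runif(6, 0.3, 0.7), function(p) rbinom(30, 2, p))
  })
  map <- marker_map(paste0("s", 1:6), "1", (1:6) * 5e4)
  panel <- genotype_panel(dos, map, "x")
  pairs <- pairwise_ld(panel)
  adj <- adjacent_ld_summary(pairs, map)
  manual <- vapply(1:5, function(i) {
    as.numeric(r2_genotypic(dos[, i], dos[, i + 1]))
  }, numeric(1))
  expect_equal(adj$mean_r2[adj$chromosome == "1"], mean(manual))
  expect_equal(adj$mean_r2[adj$chromosome == "genome"], mean(manual))
  expect_equal(adj$n_pairs[adj$chromosome == "1"], 5L)
})

test_that("r2_at_distances reads the bin containing each target", {
  pairs <- tibble::tibble(
    chromosome = "1", marker_i = "a", marker_j = "b", pos_i = 0, pos_j = 0,
    distance_bp = c(5e4, 5e5, 1e6, 5e6, 9.95e6),
    r2 = c(0.5, 0.4, 0.3, 0.2, 0.1), n_used = 10L
  )
  curve <- bin_ld(pairs)
  tab <- r2_at_distances(curve)
  expect_equal(tab$mean_r2, c(0.5, 0.4, 0.3, 0.2, 0.1))
})
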