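test_that("the drift-r2 inversion recovers a planted Ne analytically", {
  # r2_drift built to equal the random-mating drift expectation at
  # Ne = 333 must invert back to 333
  for (S in c(50, 20)) {
    b <- ldne_constants[ldne_constants$mating_model == "random" &
                          ldne_constants$branch ==
                            ifelse(S >= 30, "ge30", "lt30"), ]
    r2d <- b$b1 / 333 + b$b2 / 333^2
    expect_equal(ldne_invert(r2d, "random", S), 333, tolerance = 1e-6)
  }
  # monogamy branch likewise
  b <- ldne_constants[ldne_constants$mating_model == "monogamy" &
                        ldne_constants$branch == "ge30", ]
  r2d <- b$b1 / 150 + b$b2 / 150^2
  expect_equal(ldne_invert(r2d, "monogamy", 40), 150, tolerance = 1e-6)
  # non-positive drift r2 -> infinite estimate
  expect_identical(ldne_invert(0, "random", 50), Inf)
  expect_identical(ldne_invert(-0.01, "monogamy", 50), Inf)
})

test_that("larger drift r2 strictly decreases the Ne estimate", {
  r2 <- seq(0.001, 0.2, by = 0.001)
  for (model in c("random", "monogamy")) {
    ne <- vapply(r2, ldne_invert, numeric(1), mating_model = model, S = 50)
    expect_true(all(diff(ne) < 0))
  }
})

test_that("point estimate matches a by-hand reconstruction on a small panel", {
  panel <- make_test_panel(n = 40, m = 12, seed = 31)
  est <- ld_ne_point_estimate(panel, pcrit = 0.05, mating_model = "random")
  # by hand: screen, all pairs, mean squared correlation
  maf <- apply(panel$dosages, 2, compute_maf)
  dos <- panel$dosages[, maf >= 0.05]
  r2s <- c()
  for (i in seq_len(ncol(dos) - 1)) {
    for (j in (i + 1):ncol(dos)) {
      # Burrows-dialect r: Pearson correlation times n/(n-1)
      r2s <- c(r2s, (cor(dos[, i], dos[, j]) * 40 / 39)^2)
    }
  }
  expect_equal(est$mean_r2, mean(r2s))
  expect_equal(est$harmonic_mean_s, 40)
  expect_equal(est$n_pairs, length(r2s))
  expect_equal(est$ne,
               ldne_invert(mean(r2s) - (1 / 40 + 3.19 / 1600), "random", 40))
})

test_that("mean r2 below the sampling expectation gives an infinite Ne", {
  # independent loci, large-ish panel: drift r2 ~ 0 and can fall below
  # the sampling expectation; force it by planting orthogonal columns
  dos <- cbind(
    rep(c(0, 2), 20),
    rep(c(0, 0, 2, 2), 10),
    rep(c(0, 2, 2, 0), 10)
  )
  map <- marker_map(c("a", "b", "c"), c("1", "2", "3"), c(1e5, 1e5, 1e5))
  panel <- genotype_panel(dos, map, "orth")
  est <- ld_ne_point_estimate(panel, mating_model = "random")
  expect_lt(est$r2_drift, 0)
  expect_identical(est$ne, Inf)
})

test_that("monogamy and random estimates differ by the model inversion only", {
  panel <- make_test_panel(n = 35, m = 15, seed = 37)
  est_r <- ld_ne_point_estimate(panel, mating_model = "random")
  est_m <- ld_ne_point_estimate(panel, mating_model = "monogamy")
  expect_equal(est_m$mean_r2, est_r$mean_r2)
  expect_equal(est_m$ne,
               ldne_invert(est_r$r2_drift, "monogamy", est_r$harmonic_mean_s))
  expect_gt(est_m$ne, est_r$ne)  # monogamy drift expectation is larger
})

test_that("the point estimate is invariant to allele relabeling", {
  panel <- make_test_panel(n = 30, m = 10, seed = 41)
  base <- ld_ne_point_estimate(panel)$ne
  flipped <- panel
  flipped$dosages[, c(2, 5)] <- 2 - flipped$dosages[, c(2, 5)]
  expect_equal(ld_ne_point_estimate(flipped)$ne, base)
})

test_that("contemporary Ne recovery is within a factor of two on WF panels", {
  est <- c()
  for (s in 1:8) {
    cfg <- sim_config(
      ne_trajectory = list(c(0, 100)), n_chromosomes = 8,
      chromosome_length_bp = 2e6, n_segregating_target = 120,
      n_initial_sites = 2400, sample_size = 50, seed = 500 + s
    )
    sim <- suppressMessages(simulate_wf(cfg))
    # cross-chromosome pairs only: the drift expectation assumes
    # unlinked loci, and 2-Mb chromosomes make same-chromosome pairs
    # tightly linked
    est <- c(est, ld_ne_point_estimate(sim$panel,
                                       mating_model = "random",
                                       min_pair_distance = 5e6)$ne)
  }
  med <- median(est)
  expect_gt(med, 50)
  expect_lt(med, 200)
})

test_that("a duplicated individual has relatedness 1", {
  panel <- make_test_panel(n = 10, m = 300, seed = 51)
  panel$dosages[2, ] <- panel$dosages[1, ]
  rel <- suppressWarnings(estimate_pairwise_relatedness(panel))
  dup <- rel$pi_hat[rel$sample_i == rownames(panel$dosages)[1] &
                      rel$sample_j == rownames(panel$dosages)[2]]
  expect_equal(dup, 1, tolerance = 1e-9)
})

test_that("unrelated individuals from one gene pool have near-zero relatedness", {
  # a large population with a realistically long genetic map (many
  # Morgans in total): realized relatedness between non-relatives then
  # concentrates tightly around zero. A short total map would leave few
  # independent genealogies and genuinely heavy-tailed realized IBD.
  cfg <- sim_config(
    ne_trajectory = list(c(0, 400)), n_chromosomes = 12,
    chromosome_length_bp = 2e6, recomb_rate_cM_per_Mb = 100,
    n_segregating_target = 2200,
    n_initial_sites = 9000, burn_in = 800, sample_size = 40, seed = 61
  )
  sim <- suppressMessages(simulate_wf(cfg))
  rel <- estimate_pairwise_relatedness(sim$panel)
  expect_lt(attr(rel, "mean_relatedness"), 0.05)
})

test_that("full sibs under monogamous mating average relatedness near 0.5", {
  # monogamous couples in a large population: sampled sib pairs share
  # both parents while the population background stays near zero
  cfg <- sim_config(
    ne_trajectory = list(c(0, 400)), n_chromosomes = 8,
    chromosome_length_bp = 2e6, n_segregating_target = 800,
    n_initial_sites = 3200, burn_in = 600, sample_size = 120,
    mating = "monogamy", seed = 63
  )
  sim <- suppressMessages(simulate_wf(cfg))
  ped <- sim$truth$pedigree
  fam <- paste(ped$parents_final$father[ped$sampled],
               ped$parents_final$mother[ped$sampled])
  rel <- estimate_pairwise_relatedness(sim$panel)
  ids <- rownames(sim$panel$dosages)
  fam_i <- fam[match(rel$sample_i, ids)]
  fam_j <- fam[match(rel$sample_j, ids)]
  sib <- rel$pi_hat[fam_i == fam_j]
  expect_gt(length(sib), 10)
  expect_equal(mean(sib), 0.5, tolerance = 0.05)
})
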