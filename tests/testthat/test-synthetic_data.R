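test_that("identical seeds give bit-identical panels", {
  cfg <- sim_config(ne_trajectory = list(c(0, 50)), n_chromosomes = 2,
                    chromosome_length_bp = 2e6, n_segregating_target = 80,
                    n_initial_sites = 400, burn_in = 100,
                    sample_size = 30, missing_rate = 0.02, seed = 11)
  a <- suppressMessages(simulate_wf(cfg))
  b <- suppressMessages(simulate_wf(cfg))
  expect_identical(a$panel$dosages, b$panel$dosages)
  expect_identical(a$truth$true_freqs, b$truth$true_freqs)
  # a different seed gives a different panel
  cfg2 <- cfg
  cfg2$seed <- 12L
  c_ <- suppressMessages(simulate_wf(cfg2))
  expect_false(identical(a$panel$dosages, c_$panel$dosages))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(suppressMessages(simulate_wf(
    sim_config(ne_trajectory = list(c(0, 20)), n_chromosomes = 1,
               chromosome_length_bp = 1e6, n_segregating_target = 20,
               n_initial_sites = 40, burn_in = 10, sample_size = 10,
               seed = 5)
  )))
  expect_identical(runif(1), before)
})

test_that("heterozygosity decays at the drift rate (1 - 1/2Ne)^t", {
  # Ne = 50, t = 20, all sites started at p0 = 0.5, no mutation, no
  # ascertainment; compare mean final heterozygosity with the closed
  # form within 3 Monte-Carlo standard errors over 50 replicates
  ne <- 50
  t_gen <- 20
  h_t <- vapply(1:50, function(s) {
    cfg <- sim_config(
      ne_trajectory = list(c(0, ne)), n_generations = t_gen, burn_in = 0,
      n_chromosomes = 1, chromosome_length_bp = 1e7,
      n_segregating_target = 150, n_initial_sites = 150,
      sample_size = 10, maf_ascertainment = 0, mutation_theta = 0,
      initial_freqs = 0.5, seed = 700 + s
    )
    sim <- simulate_wf(cfg)
    p <- sim$truth$true_freqs
    mean(2 * p * (1 - p))
  }, numeric(1))
  # founding draw loses one factor of (1 - 1/2Ne), then t more
  expected <- 0.5 * (1 - 1 / (2 * ne))^(t_gen + 1)
  se <- sd(h_t) / sqrt(length(h_t))
  expect_lt(abs(mean(h_t) - expected), 3 * se)
})

test_that("neutral alleles fix at their initial frequency", {
  # diffusion prediction: P(fix at 1) = p0; small population run long
  # enough that almost every replicate fixes
  p0 <- 0.3
  outcomes <- vapply(1:400, function(s) {
    cfg <- sim_config(
      ne_trajectory = list(c(0, 16)), n_generations = 150, burn_in = 0,
      n_chromosomes = 1, chromosome_length_bp = 1e6,
      n_segregating_target = 1, n_initial_sites = 1,
      sample_size = 5, maf_ascertainment = 0, mutation_theta = 0,
      initial_freqs = p0, seed = 900 + s
    )
    simulate_wf(cfg)$truth$true_freqs
  }, numeric(1))
  fixed <- outcomes[outcomes %in% c(0, 1)]
  expect_gt(length(fixed), 300)
  p_hat <- mean(fixed)
  ci <- 2.576 * sqrt(p0 * (1 - p0) / length(fixed))
  expect_lt(abs(p_hat - p0), ci)
  # martingale property: mean frequency over all replicates stays at p0
  expect_lt(abs(mean(outcomes) - p0),
            2.576 * sd(outcomes) / sqrt(length(outcomes)))
})

test_that("a bottleneck produces lower recent than ancient Ne", {
  # Ne 1000 -> 50 at 30 generations ago: recent trajectory points
  # (small t, long distances) must sit below ancient points (large t)
  cfg <- sim_config(
    ne_trajectory = list(c(0, 50), c(30, 1000)), n_generations = 30,
    n_chromosomes = 4, chromosome_length_bp = 12e6,
    n_segregating_target = 1500, n_initial_sites = 3000, burn_in = 1000,
    sample_size = 50, seed = 801
  )
  sim <- suppressMessages(simulate_wf(cfg))
  pairs <- pairwise_ld(sim$panel, max_distance_bp = 10e6)
  traj <- estimate_ne_trajectory(
    pairs, ne_config(max_distance_bp = 10e6, bin_width_bp = 2e5,
                     n_bins = 50)
  )
  ok <- traj$well_posed
  recent <- traj$ne[ok & traj$generations_ago_t <= 25]
  ancient <- traj$ne[ok & traj$generations_ago_t >= 80]
  expect_gt(length(recent), 2)
  expect_gt(length(ancient), 2)
  expect_lt(harmonic_mean_ne(recent), harmonic_mean_ne(ancient))
})

test_that("split time zero leaves populations undifferentiated", {
  # several short chromosomes so markers are loosely correlated and the
  # Fst noise floor is small
  cfg <- sim_config(
    ne_trajectory = list(c(0, 80)), n_chromosomes = 6,
    chromosome_length_bp = 2e6, n_segregating_target = 400,
    n_initial_sites = 1800, burn_in = 320, sample_size = 40, seed = 803
  )
  sp <- simulate_split(cfg, split_times = 0, pop_ne = c(80, 80))
  p1 <- colMeans(sp$panels[[1]]$dosages, na.rm = TRUE) / 2
  p2 <- colMeans(sp$panels[[2]]$dosages, na.rm = TRUE) / 2
  fst <- fst_hudson(p1, p2, 80, 80)  # haploid sample sizes
  expect_lt(abs(fst), 0.02)
})

test_that("longer isolation at smaller Ne increases differentiation", {
  fst_at <- function(split_t, ne_d, seed) {
    cfg <- sim_config(
      ne_trajectory = list(c(0, 80)), n_chromosomes = 4,
      chromosome_length_bp = 3e6, n_segregating_target = 300,
      n_initial_sites = 1200, burn_in = 320, sample_size = 40,
      seed = seed
    )
    sp <- simulate_split(cfg, split_times = split_t,
                         pop_ne = c(ne_d, ne_d))
    p1 <- colMeans(sp$panels[[1]]$dosages, na.rm = TRUE) / 2
    p2 <- colMeans(sp$panels[[2]]$dosages, na.rm = TRUE) / 2
    fst_hudson(p1, p2, 80, 80)
  }
  f <- vapply(1:3, function(s) {
    c(fst_at(5, 80, 810 + s), fst_at(30, 80, 810 + s),
      fst_at(30, 40, 810 + s))
  }, numeric(3))
  expect_true(all(f[2, ] > f[1, ]))
  expect_true(all(f[3, ] > f[2, ]))
})

test_that("ascertainment in one daughter depresses the other's MAF", {
  deltas <- vapply(1:6, function(s) {
    cfg <- sim_config(
      ne_trajectory = list(c(0, 60)), n_chromosomes = 2,
      chromosome_length_bp = 4e6, n_segregating_target = 400,
      n_initial_sites = 1600, burn_in = 240, sample_size = 40,
      maf_ascertainment = 0, seed = 820 + s
    )
    sp <- simulate_split(cfg, split_times = 60, pop_ne = c(60, 60))
    a <- sp$panels[[1]]
    b <- sp$panels[[2]]
    asc_a <- ascertain_snps(a, 0.1)
    b_on_a <- ascertain_snps(b, 0.1, reference = a)
    maf_of <- function(p) {
      f <- colMeans(p$dosages, na.rm = TRUE) / 2
      mean(pmin(f, 1 - f))
    }
    maf_of(asc_a) - maf_of(b_on_a)
  }, numeric(1))
  expect_gt(mean(deltas > 0), 0.8)
})

test_that("ascertain_snps boundary behaviour", {
  panel <- make_test_panel(n = 20, m = 10, seed = 825)
  expect_equal(n_markers(ascertain_snps(panel, 0)), 10L)
  expect_warning(out <- ascertain_snps(panel, 0.5), "no markers")
  expect_equal(n_markers(out), 0L)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(ne_trajectory = list(c(5, 100))), "generation 0")
  expect_error(sim_config(ne_trajectory = list(c(0, 100), c(0, 50))),
               "strictly increase")
  expect_error(sim_config(ne_trajectory = list(c(0, 1))), ">= 2")
  expect_error(sim_config(sample_size = 500), "sample_size")
  cfg <- sim_config(ne_trajectory = list(c(0, 50)), sample_size = 10)
  expect_error(simulate_split(cfg, split_times = c(10, 20),
                              pop_ne = c(50, 50, 50)),
               "strictly decrease")
  expect_error(simulate_split(cfg, split_times = 10, pop_ne = c(50, 50, 50)),
               "split times")
})
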