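#' Configuration for the forward Wright-Fisher simulator
#'
#' Describes a single-population simulation: discrete non-overlapping
#' generations of `Ne(t)` diploids, recombination with crossover counts
#' Poisson in map length (no interference) and uniform crossover
#' positions, standing variation seeded at Beta-shaped neutral-proxy
#' frequencies and burned in (default `4 * ancestral Ne` generations) so
#' LD is at drift-recombination equilibrium when sampling, then a final
#' sample of diploids genotyped at markers ascertained by MAF.
#'
#' @param ne_trajectory List of `c(generation_ago, ne)` change points,
#'   most recent first (first must have generation 0). `Ne(t)` is the
#'   value of the latest change point at or before `t`; beyond the oldest
#'   change point the ancestral Ne applies (also used during burn-in).
#' @param n_generations Generations simulated under the trajectory after
#'   burn-in (extended automatically to cover the oldest change point).
#' @param burn_in Burn-in generations at the ancestral Ne; default
#'   `8 * ancestral Ne`. The founding standing variation carries
#'   complete-LD-like associations (it predates the genealogy), and in
#'   the mutation-limited regime roughly eight Ne generations are needed
#'   before segregating variation is mutation-derived and LD sits at
#'   drift-recombination-mutation equilibrium.
#' @param n_chromosomes,chromosome_length_bp Genome layout.
#' @param recomb_rate_cM_per_Mb Uniform recombination rate (default 1).
#' @param n_segregating_target Markers to retain after ascertainment
#'   (downsampled uniformly if more survive; all kept with a message if
#'   fewer do).
#' @param n_initial_sites Standing-variation sites seeded at generation
#'   zero; default `6 * n_segregating_target` to allow for loss to drift.
#' @param sample_size Diploids sampled from the final generation.
#' @param missing_rate Fraction of genotypes masked uniformly at random.
#' @param maf_ascertainment Minimum sample MAF for a marker to be kept
#'   (default 0.05, emulating array ascertainment; 0 keeps every site).
#' @param mutation_theta Per-site scaled symmetric mutation rate
#'   `4 * ancestral Ne * mu` (default 0.02). Recurrent mutation keeps
#'   the population at mutation-drift equilibrium — the regime the
#'   alpha = 2 LD relationship `E[r2] ~ 1/(4 Ne c + 2)` assumes — and
#'   the default is deliberately small: the relationship treats mutation
#'   as the source of polymorphism but neglects homoplasy, which only
#'   holds when theta per site is well below 1. Setting 0 gives a
#'   pure-drift simulation (the alpha = 1 world, with standing
#'   variation only).
#' @param mating `"random"` (parents drawn independently, default) or
#'   `"monogamy"` (parents paired into couples each generation; gives
#'   full-sib structure for relatedness tests).
#' @param initial_freqs Optional vector of initial allele frequencies
#'   (recycled across sites); the default draws from the stationary
#'   Beta(theta, theta) frequency distribution of the symmetric
#'   mutation model (Beta(0.5, 0.5) when `mutation_theta = 0`),
#'   truncated to segregating frequencies, so burn-in starts near
#'   equilibrium.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ne_trajectory = list(c(0, 100)),
                       n_generations = 0,
                       burn_in = NULL,
                       n_chromosomes = 2,
                       chromosome_length_bp = 50e6,
                       recomb_rate_cM_per_Mb = 1.0,
                       n_segregating_target = 2000,
                       n_initial_sites = NULL,
                       sample_size = 50,
                       missing_rate = 0,
                       maf_ascertainment = 0.05,
                       mutation_theta = 0.02,
                       mating = c("random", "monogamy"),
                       initial_freqs = NULL,
                       seed = 1) {
  traj <- do.call(rbind, lapply(ne_trajectory, function(x) {
    if (length(x) != 2L) stop("trajectory change points are c(generation, ne)",
                              call. = FALSE)
    x
  }))
  if (traj[1L, 1L] != 0) {
    stop("first trajectory change point must be at generation 0",
         call. = FALSE)
  }
  if (any(diff(traj[, 1L]) <= 0)) {
    stop("trajectory generations must strictly increase", call. = FALSE)
  }
  if (any(traj[, 2L] < 2)) stop("Ne values must be >= 2", call. = FALSE)
  if (sample_size > traj[1L, 2L]) {
    stop("sample_size exceeds the final-generation Ne", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1 || maf_ascertainment < 0 ||
      recomb_rate_cM_per_Mb < 0 || mutation_theta < 0) {
    stop("rates must be non-negative (missing_rate < 1)", call. = FALSE)
  }
  ancestral_ne <- traj[nrow(traj), 2L]
  if (is.null(burn_in)) burn_in <- 8L * ancestral_ne
  if (is.null(n_initial_sites)) {
    n_initial_sites <- 6L * n_segregating_target
  }
  structure(
    list(ne_trajectory = traj, n_generations = n_generations,
         burn_in = as.integer(burn_in),
         n_chromosomes = as.integer(n_chromosomes),
         chromosome_length_bp = as.integer(chromosome_length_bp),
         recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
         n_segregating_target = as.integer(n_segregating_target),
         n_initial_sites = as.integer(n_initial_sites),
         sample_size = as.integer(sample_size),
         missing_rate = missing_rate,
         maf_ascertainment = maf_ascertainment,
         mutation_theta = mutation_theta,
         mating = match.arg(mating),
         initial_freqs = initial_freqs,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Ne at t generations ago under a change-point trajectory.
ne_at <- function(traj, t) {
  traj[max(which(traj[, 1L] <= t)), 2L]
}

# Seed standing variation: per-chromosome positions and haplotypes
# (stored sites x haplotypes) at linkage equilibrium with the supplied
# initial frequencies.
init_population <- function(cfg, n_dip) {
  per_chr <- rep(cfg$n_initial_sites %/% cfg$n_chromosomes,
                 cfg$n_chromosomes)
  rem <- cfg$n_initial_sites - sum(per_chr)
  if (rem > 0L) per_chr[seq_len(rem)] <- per_chr[seq_len(rem)] + 1L
  haps <- vector("list", cfg$n_chromosomes)
  pos <- vector("list", cfg$n_chromosomes)
  freqs <- vector("list", cfg$n_chromosomes)
  for (ci in seq_len(cfg$n_chromosomes)) {
    l <- per_chr[ci]
    pos[[ci]] <- sort(sample.int(cfg$chromosome_length_bp, l))
    th <- if (cfg$mutation_theta > 0) cfg$mutation_theta else 0.5
    # stationary Beta(theta, theta) SFS truncated to segregating
    # frequencies (inverse-CDF draw, so no atoms at the bounds)
    lo <- 1 / (2 * n_dip)
    p0 <- if (is.null(cfg$initial_freqs)) {
      stats::qbeta(
        stats::runif(l, stats::pbeta(lo, th, th),
                     stats::pbeta(1 - lo, th, th)),
        th, th
      )
    } else {
      rep_len(cfg$initial_freqs, l)
    }
    freqs[[ci]] <- p0
    haps[[ci]] <- matrix(
      stats::rbinom(l * 2L * n_dip, 1L, p0),
      nrow = l, ncol = 2L * n_dip
    )
  }
  list(haps = haps, pos = pos, freqs = freqs)
}

# Run `schedule` (vector of per-generation offspring counts, forward in
# time) from `state` through the compiled engine; returns final state
# plus the last two generations' parent indices (1-based).
run_schedule <- function(state, schedule, pos_morgan, map_len, mating,
                         mu = 0) {
  if (length(schedule) == 0L) {
    return(list(haps = state, pedigree = list(NULL, NULL)))
  }
  if (mating == "monogamy" && ncol(state[[1L]]) < 4L) {
    stop("monogamy needs >= 2 parents", call. = FALSE)
  }
  out <- .wf_evolve_cpp(state, pos_morgan, map_len,
                        as.integer(schedule),
                        as.integer(mating == "monogamy"), mu)
  ped_last <- tibble::tibble(father = out$fathers + 1L,
                             mother = out$mothers + 1L)
  ped_prev <- if (length(out$fathers_prev)) {
    tibble::tibble(father = out$fathers_prev + 1L,
                   mother = out$mothers_prev + 1L)
  } else {
    NULL
  }
  list(haps = out$haps, pedigree = list(ped_prev, ped_last))
}

#' Simulate a Wright-Fisher population and genotype a sample
#'
#' Runs the forward simulator described in [sim_config()] and genotypes
#' `sample_size` diploids drawn from the final generation. All
#' randomness flows from `config$seed`; identical configs give
#' bit-identical output.
#'
#' @param config A [sim_config()].
#' @param population Population label for the output panel.
#' @return A list of class `wf_simulation`: `panel` (a
#'   [genotype_panel()]) and `truth`, a list with the realized
#'   `ne_schedule` (tibble of generation-ago / Ne actually simulated),
#'   `true_freqs` (population allele frequencies of the kept markers at
#'   sampling time), `initial_freqs` (realized founding frequencies of
#'   those markers), `haplotypes` (phased 0/1 matrix, two rows per
#'   sampled diploid, columns = kept markers), `pedigree` (parent
#'   indices of the final two generations plus the sampled individuals'
#'   indices), and `seed`.
#' @export
simulate_wf <- function(config, population = "sim") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_wf_impl(config, population))
}

simulate_wf_impl <- function(cfg, population) {
  traj <- cfg$ne_trajectory
  ancestral_ne <- traj[nrow(traj), 2L]
  span <- max(cfg$n_generations, max(traj[, 1L]) + 1L)
  # forward-time offspring counts: burn-in at ancestral Ne, then Ne(t)
  # for t = span-1 ... 0
  sched <- c(rep(ancestral_ne, cfg$burn_in),
             vapply(rev(seq_len(span) - 1L),
                    function(t) ne_at(traj, t), numeric(1)))
  sched <- as.integer(sched)

  init <- init_population(cfg, ancestral_ne)
  pos_morgan <- lapply(init$pos, function(p) {
    p * cfg$recomb_rate_cM_per_Mb * 1e-8
  })
  map_len <- rep(cfg$chromosome_length_bp * cfg$recomb_rate_cM_per_Mb * 1e-8,
                 cfg$n_chromosomes)

  mu <- cfg$mutation_theta / (4 * ancestral_ne)
  run <- run_schedule(init$haps, sched, pos_morgan, map_len, cfg$mating,
                      mu)
  finish_population(run, init, cfg, population)
}

# Sample, ascertain and package one population's final state.
finish_population <- function(run, init, cfg, population,
                              keep_cols = NULL) {
  haps <- run$haps
  n_final <- ncol(haps[[1L]]) %/% 2L
  samp <- sort(sample.int(n_final, cfg$sample_size))
  hap_cols <- as.vector(rbind(2L * samp - 1L, 2L * samp))

  chrom_of <- rep(seq_along(haps), vapply(haps, nrow, 0L))
  pos_all <- unlist(init$pos)
  hap_all <- do.call(rbind, haps)        # sites x haplotypes
  p_true <- rowMeans(hap_all)
  hap_samp <- hap_all[, hap_cols, drop = FALSE]
  dos <- t(hap_samp[, seq(1L, ncol(hap_samp), 2L), drop = FALSE] +
             hap_samp[, seq(2L, ncol(hap_samp), 2L), drop = FALSE])

  if (is.null(keep_cols)) {
    p_samp <- colMeans(dos) / 2
    maf <- pmin(p_samp, 1 - p_samp)
    keep_cols <- which(maf >= cfg$maf_ascertainment)
    if (length(keep_cols) > cfg$n_segregating_target) {
      keep_cols <- sort(sample(keep_cols, cfg$n_segregating_target))
    } else if (length(keep_cols) < cfg$n_segregating_target) {
      message("only ", length(keep_cols), " of ",
              cfg$n_segregating_target,
              " target markers survive ascertainment")
    }
    if (length(keep_cols) == 0L) {
      stop("no markers survive ascertainment", call. = FALSE)
    }
  }

  dos <- dos[, keep_cols, drop = FALSE]
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(dos)) < cfg$missing_rate
    dos[mask] <- NA_real_
  }
  storage.mode(dos) <- "double"

  map <- marker_map(
    marker_id = paste0("chr", chrom_of[keep_cols], "_", pos_all[keep_cols]),
    chromosome = paste0("chr", chrom_of[keep_cols]),
    position_bp = pos_all[keep_cols],
    allele_ref = "A", allele_alt = "B"
  )
  ord <- order(chrom_of[keep_cols], pos_all[keep_cols])
  panel <- genotype_panel(
    dos[, ord, drop = FALSE], map, population = population,
    sample_ids = paste0(population, "_", seq_len(cfg$sample_size))
  )
  traj <- cfg$ne_trajectory
  span <- max(cfg$n_generations, max(traj[, 1L]) + 1L)
  truth <- list(
    ne_schedule = tibble::tibble(
      generation_ago = seq_len(span) - 1L,
      ne = vapply(seq_len(span) - 1L, function(t) ne_at(traj, t),
                  numeric(1))
    ),
    burn_in = cfg$burn_in,
    true_freqs = p_true[keep_cols][ord],
    initial_freqs = unlist(init$freqs)[keep_cols][ord],
    haplotypes = t(hap_samp[keep_cols, , drop = FALSE][ord, , drop = FALSE]),
    pedigree = list(
      parents_final = run$pedigree[[2L]],
      parents_previous = run$pedigree[[1L]],
      sampled = samp
    ),
    keep_cols = keep_cols,
    seed = cfg$seed
  )
  structure(list(panel = panel, truth = truth), class = "wf_simulation")
}

#' Simulate diverged populations from a shared ancestor
#'
#' Caterpillar split scenario: an ancestral population evolves at the
#' ancestral Ne, and at each split time (generations ago, strictly
#' decreasing) one daughter branches off and evolves independently at
#' its own Ne until the present; the final stem becomes the last
#' population. All panels are genotyped on one common marker set,
#' ascertained by pooled-sample MAF across the daughters (emulating a
#' shared array's common-SNP intersection).
#'
#' @param config A [sim_config()]; its trajectory's ancestral Ne governs
#'   the stem, `sample_size`/`missing_rate`/`maf_ascertainment` apply to
#'   every daughter.
#' @param split_times Generations ago of each branch point; length
#'   `n_populations - 1`, strictly decreasing, all > 0 except the last
#'   which may be 0 (no divergence of the final pair).
#' @param pop_ne Daughter effective sizes (length = number of
#'   populations).
#' @param pop_names Population labels.
#' @return A list of class `wf_split_simulation`: `panels` (list of
#'   [genotype_panel()]s on the shared map) and `truth` (split times,
#'   per-population Ne, per-population true allele frequencies, seed).
#' @export
simulate_split <- function(config, split_times, pop_ne,
                           pop_names = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n_pop <- length(pop_ne)
  if (length(split_times) != n_pop - 1L) {
    stop("need length(pop_ne) - 1 split times", call. = FALSE)
  }
  if (any(diff(split_times) >= 0)) {
    stop("split times must strictly decrease (deepest split first)",
         call. = FALSE)
  }
  if (any(split_times < 0)) stop("split times must be >= 0", call. = FALSE)
  if (is.null(pop_names)) pop_names <- paste0("P", seq_len(n_pop))
  final_sizes <- pop_ne
  last_nes <- config$ne_trajectory[nrow(config$ne_trajectory), 2L]
  final_sizes[c(split_times, split_times[n_pop - 1L]) == 0] <- last_nes
  if (config$sample_size > min(final_sizes)) {
    stop("sample_size exceeds a daughter population's final Ne",
         call. = FALSE)
  }
  with_seed(config$seed,
            simulate_split_impl(config, split_times, pop_ne, pop_names))
}

simulate_split_impl <- function(cfg, split_times, pop_ne, pop_names) {
  n_pop <- length(pop_ne)
  ancestral_ne <- cfg$ne_trajectory[nrow(cfg$ne_trajectory), 2L]
  init <- init_population(cfg, ancestral_ne)
  pos_morgan <- lapply(init$pos, function(p) {
    p * cfg$recomb_rate_cM_per_Mb * 1e-8
  })
  map_len <- rep(cfg$chromosome_length_bp * cfg$recomb_rate_cM_per_Mb * 1e-8,
                 cfg$n_chromosomes)

  mu <- cfg$mutation_theta / (4 * ancestral_ne)
  # stem: burn-in down to the deepest split, then advance between splits
  stem <- run_schedule(init$haps,
                       rep.int(ancestral_ne, cfg$burn_in),
                       pos_morgan, map_len, cfg$mating, mu)
  branch_time <- c(split_times, split_times[n_pop - 1L])
  prev <- split_times[1L]
  runs <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    gap <- prev - branch_time[i]
    if (gap > 0L) {
      stem <- run_schedule(stem$haps, rep.int(ancestral_ne, gap),
                           pos_morgan, map_len, cfg$mating, mu)
      prev <- branch_time[i]
    }
    runs[[i]] <- if (branch_time[i] > 0L) {
      run_schedule(stem$haps, rep.int(pop_ne[i], branch_time[i]),
                   pos_morgan, map_len, cfg$mating, mu)
    } else {
      stem
    }
  }

  # pooled ascertainment over equal-size samples from each daughter
  sims <- vector("list", n_pop)
  for (i in seq_len(n_pop)) {
    sims[[i]] <- finish_population(runs[[i]], init, cfg, pop_names[i],
                                   keep_cols = seq_along(unlist(init$pos)))
  }
  names(sims) <- pop_names
  pooled_dos <- do.call(rbind, lapply(sims, function(s) s$panel$dosages))
  p_pool <- colMeans(pooled_dos, na.rm = TRUE) / 2
  maf_pool <- pmin(p_pool, 1 - p_pool)
  keep <- which(!is.na(maf_pool) & maf_pool >= cfg$maf_ascertainment)
  if (length(keep) > cfg$n_segregating_target) {
    keep <- sort(sample(keep, cfg$n_segregating_target))
  }
  if (length(keep) == 0L) stop("no markers survive pooled ascertainment",
                               call. = FALSE)

  panels <- lapply(sims, function(s) subset_markers(s$panel, keep))
  names(panels) <- pop_names
  truth <- list(
    split_times = split_times,
    pop_ne = pop_ne,
    ancestral_ne = ancestral_ne,
    true_freqs = lapply(sims, function(s) s$truth$true_freqs[keep]),
    seed = cfg$seed
  )
  structure(list(panels = panels, truth = truth),
            class = "wf_split_simulation")
}

#' Ascertain markers by MAF in a reference population
#'
#' Keeps the markers whose MAF in `reference` (default: the panel
#' itself) is at least `maf_threshold` — the deterministic filter that
#' emulates array ascertainment bias: ascertaining in one lineage
#' depresses the MAF spectrum of a diverged lineage evaluated on the
#' same markers.
#'
#' @param panel Panel to filter.
#' @param maf_threshold Minimum reference MAF.
#' @param reference Panel supplying the frequencies (same marker set).
#' @return The filtered [genotype_panel()].
#' @export
ascertain_snps <- function(panel, maf_threshold, reference = panel) {
  if (!identical(reference$map$marker_id, panel$map$marker_id)) {
    stop("reference panel must share the panel's marker set", call. = FALSE)
  }
  maf <- col_maf(reference$dosages)
  keep <- !is.na(maf) & maf >= maf_threshold
  if (!any(keep)) {
    warning("no markers pass the ascertainment threshold", call. = FALSE)
  }
  subset_markers(panel, keep)
}
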