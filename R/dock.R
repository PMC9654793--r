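# Stochastic pose search: population-based (GA) global search over
# translation / orientation / torsions under the grid-interpolated score,
# with a greedy local refinement of the best individual, run n_runs times
# with per-run deterministic seeds.

#' Docking search configuration
#'
#' @param pop_size population size.
#' @param n_gens generations per run.
#' @param elite_n individuals carried over unchanged.
#' @param p_crossover crossover probability per offspring.
#' @param p_mut per-block mutation probability.
#' @param sd_trans translation mutation s.d., Angstrom.
#' @param sd_rot rotation mutation s.d., degrees.
#' @param sd_tor torsion mutation s.d., degrees.
#' @param local_steps greedy refinement steps applied to each run's best.
#' @param rmsd_cutoff pose clustering cutoff, Angstrom.
#' @return list of class `dock_config`.
#' @export
dock_config <- function(pop_size = 50, n_gens = 100, elite_n = 2,
                        p_crossover = 0.8, p_mut = 0.35, sd_trans = 0.6,
                        sd_rot = 20, sd_tor = 30, local_steps = 120,
                        rmsd_cutoff = 2.0) {
  cfg <- list(pop_size = pop_size, n_gens = n_gens, elite_n = elite_n,
              p_crossover = p_crossover, p_mut = p_mut, sd_trans = sd_trans,
              sd_rot = sd_rot, sd_tor = sd_tor, local_steps = local_steps,
              rmsd_cutoff = rmsd_cutoff)
  class(cfg) <- "dock_config"
  cfg
}

#' @noRd
decode_pose <- function(v, n_tor) {
  new_pose(translation = v[1:3], orientation = v[4:7],
           torsions = if (n_tor > 0) v[8:(7 + n_tor)] else numeric(0))
}

#' @noRd
random_genome <- function(lo, hi, n_tor) {
  c(stats::runif(3, lo, hi), random_unit_quat(),
    if (n_tor > 0) stats::runif(n_tor, -180, 180))
}

#' @noRd
mutate_genome <- function(v, n_tor, cfg) {
  if (stats::runif(1) < cfg$p_mut) v[1:3] <- v[1:3] + stats::rnorm(3, 0, cfg$sd_trans)
  if (stats::runif(1) < cfg$p_mut) {
    dq <- quat_from_axis_angle(stats::rnorm(3), stats::rnorm(1, 0, cfg$sd_rot))
    q <- quat_mul(dq, v[4:7])
    v[4:7] <- q / sqrt(sum(q^2))
  }
  if (n_tor > 0) {
    for (k in seq_len(n_tor)) {
      if (stats::runif(1) < cfg$p_mut) {
        v[7 + k] <- ((v[7 + k] + stats::rnorm(1, 0, cfg$sd_tor) + 180) %% 360) - 180
      }
    }
  }
  v
}

#' @noRd
crossover_genomes <- function(a, b, n_tor) {
  child <- a
  if (stats::runif(1) < 0.5) child[1:3] <- b[1:3]
  if (stats::runif(1) < 0.5) child[4:7] <- b[4:7]
  if (n_tor > 0) {
    for (k in seq_len(n_tor)) if (stats::runif(1) < 0.5) child[7 + k] <- b[7 + k]
  }
  child
}

# one GA run; returns list(genome, energy); assumes RNG already seeded
#' @noRd
ga_run <- function(fitness, lo, hi, n_tor, cfg) {
  pop <- lapply(seq_len(cfg$pop_size), function(i) random_genome(lo, hi, n_tor))
  fit <- vapply(pop, fitness, numeric(1))
  best_i <- which.min(fit)
  best <- list(genome = pop[[best_i]], energy = fit[best_i])
  for (g in seq_len(cfg$n_gens)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(min(cfg$elite_n, length(pop)))]]
    while (length(newpop) < cfg$pop_size) {
      pick <- function() {
        i <- sample.int(cfg$pop_size, 2)
        if (fit[i[1]] <= fit[i[2]]) pop[[i[1]]] else pop[[i[2]]]
      }
      child <- pick()
      if (stats::runif(1) < cfg$p_crossover) child <- crossover_genomes(child, pick(), n_tor)
      child <- mutate_genome(child, n_tor, cfg)
      newpop[[length(newpop) + 1]] <- child
    }
    pop <- newpop
    fit <- vapply(pop, fitness, numeric(1))
    i <- which.min(fit)
    if (fit[i] < best$energy) best <- list(genome = pop[[i]], energy = fit[i])
  }
  # greedy local refinement (shrinking random steps)
  v <- best$genome; e <- best$energy
  scale <- 1
  for (s in seq_len(cfg$local_steps)) {
    cand <- v
    cand[1:3] <- cand[1:3] + stats::rnorm(3, 0, 0.3 * cfg$sd_trans * scale)
    dq <- quat_from_axis_angle(stats::rnorm(3), stats::rnorm(1, 0, 0.3 * cfg$sd_rot * scale))
    q <- quat_mul(dq, cand[4:7]); cand[4:7] <- q / sqrt(sum(q^2))
    if (n_tor > 0) {
      cand[8:(7 + n_tor)] <- ((cand[8:(7 + n_tor)] +
        stats::rnorm(n_tor, 0, 0.3 * cfg$sd_tor * scale) + 180) %% 360) - 180
    }
    ec <- fitness(cand)
    if (ec < e) { v <- cand; e <- ec; scale <- min(1, scale * 1.25) }
    else scale <- max(0.05, scale * 0.95)
  }
  list(genome = v, energy = e)
}

#' Dock a ligand into precomputed grid maps
#'
#' Runs `n_runs` independent stochastic searches (GA over rigid-body +
#' torsional degrees of freedom with greedy local refinement), each seeded
#' deterministically from `(seed, run index)`, so results are reproducible
#' and independent of execution order. Each run contributes its final best
#' pose; poses are clustered by symmetry-aware RMSD.
#'
#' @param mol typed, charged `Molecule`.
#' @param grids `GridMaps` covering the search region.
#' @param rec the prepared `Receptor` (used for the final exact rescore).
#' @param params a `ParameterSet`.
#' @param n_runs number of independent runs (>= 1).
#' @param seed integer master seed.
#' @param search_cfg a [dock_config()].
#' @param rescore rescore final poses with the exact (non-grid) function.
#' @return a `DockingResult`: list with `poses` (one final `Pose` per run,
#'   each with `$score`), `best`, `energies`, and `clusters`.
#' @export
dock <- function(mol, grids, rec = NULL, params = default_parameters(),
                 n_runs = 100, seed = 1, search_cfg = dock_config(),
                 rescore = FALSE) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (anyNA(mol$atoms$type_code)) mol <- assign_atom_types(mol, params)
  if (is.null(mol$torsion_tree)) mol <- build_torsion_tree(mol)
  cache <- grid_ligand_cache(mol, params)
  mol <- cache$mol
  n_tor <- length(mol$torsion_tree$branches)
  intra_const <- if (cache$rigid) intra_terms(mol, coords(mol), params) else NULL
  hi_box <- grids$origin + (grids$dims - 1) * grids$spacing
  lo <- grids$origin + 0.1 * (hi_box - grids$origin)
  hi <- hi_box - 0.1 * (hi_box - grids$origin)
  fitness <- function(v) {
    p <- decode_pose(v, n_tor)
    grid_total_fast(grids, cache, realize_pose(mol, p), params, intra_const)
  }
  runs <- lapply(seq_len(n_runs), function(r) {
    with_seed((as.numeric(seed) * 100003 + r * 7919) %% 2147483647,
              function() ga_run(fitness, lo, hi, n_tor, search_cfg))
  })
  energies <- vapply(runs, function(x) x$energy, numeric(1))
  if (all(!is.finite(energies))) stop("no pose inside the grid box was ever found")
  poses <- lapply(runs, function(x) {
    p <- decode_pose(x$genome, n_tor)
    p$score <- if (rescore && !is.null(rec)) {
      binding_free_energy(rec, mol, p, params)
    } else {
      grid_energy(grids, mol, p, params)
    }
    p
  })
  energies <- vapply(poses, function(p) p$score$total, numeric(1))
  ord <- order(energies)
  clusters <- cluster_poses(mol, poses, energies, search_cfg$rmsd_cutoff)
  out <- list(poses = poses, energies = energies,
              best = poses[[ord[1]]], best_run = ord[1], clusters = clusters)
  class(out) <- "DockingResult"
  out
}

#' @export
print.DockingResult <- function(x, ...) {
  cat(sprintf("DockingResult: %d pose(s), best dG = %.4f kcal/mol, %d cluster(s)\n",
              length(x$poses), x$best$score$total, length(x$clusters)))
  invisible(x)
}

# greedy energy-ordered clustering at an RMSD cutoff; each cluster's
# representative is its lowest-energy member
#' @noRd
cluster_poses <- function(mol, poses, energies, rmsd_cutoff = 2.0) {
  ord <- order(energies)
  xyz <- lapply(poses, function(p) realize_pose(mol, p))
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_i <- clusters[[k]]$representative
      if (pose_rmsd(mol, xyz[[i]], xyz[[rep_i]]) <= rmsd_cutoff) {
        clusters[[k]]$members <- c(clusters[[k]]$members, i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1]] <- list(representative = i, members = i)
    }
  }
  clusters
}
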