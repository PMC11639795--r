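## Synthetic-data generators with known ground truth: toy two-chain
## complexes with a constructed contact patch, docked-pose ensembles whose
## best pose is known, affinity corpora with a linear (optionally
## non-linear) truth over Conjoint-Triad features, and trajectories of
## harmonic fluctuation or multi-state hopping. Every generator is a pure
## function of its arguments including the seed.

## Idealised residue: heavy backbone + C-beta, offsets relative to CA kept
## in the xz-plane so inter-chain y-gaps are exact by construction.
TOY_ATOM_OFFSETS <- matrix(
  c(-1.2, 0.0, 0.5,   # N
     0.0, 0.0, 0.0,   # CA
     1.2, 0.0, 0.5,   # C
     1.6, 0.0, 1.6,   # O
     0.0, 0.0, -1.5), # CB
  ncol = 3, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O", "CB"), NULL))

toy_chain_atoms <- function(chain, ca, start_serial) {
  n_res <- nrow(ca)
  rows <- vector("list", n_res)
  serial <- start_serial
  for (i in seq_len(n_res)) {
    xyz <- sweep(TOY_ATOM_OFFSETS, 2, ca[i, ], FUN = "+")
    rows[[i]] <- data.frame(
      model = 1L, serial = serial + seq_len(5) - 1L,
      name = rownames(TOY_ATOM_OFFSETS), altloc = "", resname = "ALA",
      chain = chain, resseq = i, icode = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, bfactor = 0,
      element = substr(rownames(TOY_ATOM_OFFSETS), 1, 1),
      hetero = FALSE, stringsAsFactors = FALSE)
    serial <- serial + 5L
  }
  do.call(rbind, rows)
}

#' Generate a two-chain toy complex with a known buried interface
#'
#' Builds an idealised poly-alanine pair of chains (3.8 Angstrom C-alpha
#' spacing, heavy backbone + C-beta). The contact-patch residues of chain B
#' sit `inter_chain_gap` Angstrom (< 4) above the designated chain-A
#' residues; every other chain-B residue is kept at least 10 Angstrom from
#' chain A, and the chain-A flanks bend away so that only the designated
#' residues lose solvent accessibility on binding. The designated chain-A
#' residues are returned as the ground-truth interface.
#'
#' @param n_residues residues per chain.
#' @param contact_patch contiguous residue indices (1-based) forming the
#'   contact.
#' @param inter_chain_gap A-to-B separation at the patch, Angstrom.
#' @param seed RNG seed for the small coordinate jitter.
#' @param jitter amplitude of the coordinate jitter, Angstrom.
#' @return list with `structure` (radii assigned), `interface` (chain-A
#'   residue keys), `receptor_chains` ("A"), `ligand_chains` ("B") and the
#'   generating `spec`.
#' @export
make_toy_complex <- function(n_residues = 12, contact_patch = 5:7,
                             inter_chain_gap = 3.9, seed = 1,
                             jitter = 0.05) {
  stopifnot(n_residues >= 1, inter_chain_gap > 0)
  patch <- sort(unique(as.integer(contact_patch)))
  if (length(patch) > 0) {
    if (min(patch) < 1 || max(patch) > n_residues)
      stop("contact_patch indices out of 1..n_residues")
    if (length(patch) > 1 && any(diff(patch) != 1))
      stop("contact_patch must be a contiguous run")
  }
  step <- 3.8
  bend <- 5.0   # first off-patch step away from the interface plane
  far <- 6.3    # first off-patch step for chain B (>= 10 A from chain A)
  ca_for_chain <- function(y_patch, away) {
    ca <- matrix(0, n_residues, 3)
    if (length(patch) == 0) {
      ## no patch: plain strand far from the partner
      for (i in seq_len(n_residues))
        ca[i, ] <- c(step * i, y_patch + away * 10, 0)
      return(ca)
    }
    p0 <- min(patch); p1 <- max(patch)
    for (i in seq_len(n_residues)) {
      if (i >= p0 && i <= p1) {
        ca[i, ] <- c(step * i, y_patch, 0)
      } else if (i < p0) {
        ca[i, ] <- c(step * p0 - 1.0,
                     y_patch + away * (bend_off(away) + step * (p0 - i - 1)),
                     0)
      } else {
        ca[i, ] <- c(step * p1 + 1.0,
                     y_patch + away * (bend_off(away) + step * (i - p1 - 1)),
                     0)
      }
    }
    ca
  }
  bend_off <- function(away) if (away > 0) far else bend
  ca_a <- ca_for_chain(0, -1)
  ca_b <- ca_for_chain(inter_chain_gap, +1)
  atoms <- rbind(toy_chain_atoms("A", ca_a, 1L),
                 toy_chain_atoms("B", ca_b, n_residues * 5L + 1L))
  jit <- withr_seed(seed, matrix(stats::runif(nrow(atoms) * 3, -jitter,
                                              jitter), ncol = 3))
  ## jitter only within the xz-plane so constructed y-separations persist
  atoms$x <- atoms$x + jit[, 1]
  atoms$z <- atoms$z + jit[, 3]
  atoms$radius <- NA_real_
  s <- assign_radii(new_structure(atoms))
  interface <- residue_keys(rep("A", length(patch)), patch, "")
  list(structure = s, interface = interface,
       receptor_chains = "A", ligand_chains = "B",
       spec = list(n_residues = n_residues, contact_patch = patch,
                   inter_chain_gap = inter_chain_gap, seed = seed))
}

#' Generate a docked-pose ensemble with a known best pose
#'
#' Pose 0 keeps the ligand at its original (contact) placement; pose k is
#' the ligand rigidly displaced by `k * displacement_step` along a seeded
#' random unit vector oriented away from the receptor, so burial decreases
#' with k and the ground-truth best pose is model 0.
#'
#' @param complex a toy-complex list from [make_toy_complex()] (or any
#'   list with `structure`, `interface`, `receptor_chains`,
#'   `ligand_chains`).
#' @param n_poses number of poses (>= 1).
#' @param displacement_step displacement per pose index, Angstrom.
#' @param seed RNG seed for the displacement direction.
#' @return a [pose_ensemble()] with model ids `0:(n_poses-1)`; ground
#'   truth best = model 0.
#' @export
make_pose_ensemble <- function(complex, n_poses = 10,
                               displacement_step = 2, seed = 1) {
  stopifnot(n_poses >= 1)
  s <- complex$structure
  receptor <- select_structure(s, complex$receptor_chains)
  ligand <- select_structure(s, complex$ligand_chains)
  dir <- withr_seed(seed, {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  })
  rc <- colMeans(structure_coords(receptor))
  lc <- colMeans(structure_coords(ligand))
  outward <- lc - rc
  if (sum(dir * outward) < 0) dir <- -dir  # always move away from receptor
  poses <- lapply(seq_len(n_poses) - 1L, function(k) {
    p <- ligand
    p$atoms$x <- p$atoms$x + k * displacement_step * dir[1]
    p$atoms$y <- p$atoms$y + k * displacement_step * dir[2]
    p$atoms$z <- p$atoms$z + k * displacement_step * dir[3]
    p
  })
  pose_ensemble(receptor, poses, complex$interface,
                model_ids = seq_len(n_poses) - 1L)
}

#' Generate a synthetic affinity corpus with known ground truth
#'
#' Records are random single/double point mutants of the parent peptide;
#' the true affinity is linear in the peptide's Conjoint-Triad counts,
#' `affinity = offset + <w, triad(seq)> (+ optional quadratic term) +
#' N(0, noise_sd)`. The noiseless truth and the true ranking accompany the
#' records so recovery tests never re-derive them.
#'
#' @param n_records number of records (>= 10). The default (1000) is sized
#'   so a random 80:20 split almost surely leaves no substitution
#'   treatment unseen by the training half (coverage analysis in the
#'   methods vignette), making the linear truth recoverable.
#' @param parent parent peptide sequence.
#' @param target target sequence stored in every record (a fixed
#'   60-residue synthetic target by default).
#' @param true_weights length-343 weight vector; seeded `N(0, 1)` draws by
#'   default.
#' @param noise_sd Gaussian noise standard deviation (kcal/mol-like
#'   units).
#' @param nonlinear_scale strength of an optional centred quadratic term
#'   `nonlinear_scale * (<w2, x> - mean)^2` making the truth non-linear in
#'   the features (0 = purely linear).
#' @param offset_mean mean affinity level of the corpus.
#' @param seed RNG seed.
#' @return list with `records` (data.frame `peptide_seq`, `target_seq`,
#'   `affinity`), `true_affinity`, `true_ranking` (record indices, best
#'   first), `true_weights`, `target`, `parent`.
#' @export
make_affinity_corpus <- function(n_records = 1000,
                                 parent = "YIDPKHGGTGSNNEDLR",
                                 target = NULL, true_weights = NULL,
                                 noise_sd = 0.5, nonlinear_scale = 0,
                                 offset_mean = -10, seed = 1) {
  stopifnot(n_records >= 10, noise_sd >= 0)
  validate_sequence(parent, "parent")
  out <- withr_seed(seed, {
    if (is.null(target))
      target <- paste(sample(AA_LETTERS, 60, replace = TRUE), collapse = "")
    if (is.null(true_weights)) true_weights <- stats::rnorm(343)
    stopifnot(length(true_weights) == 343)
    w2 <- if (nonlinear_scale > 0) stats::rnorm(343, sd = 0.3) else NULL
    L <- nchar(parent)
    letters <- strsplit(parent, "")[[1]]
    seqs <- vapply(seq_len(n_records), function(i) {
      v <- letters
      ## double mutations are kept >= 3 positions apart so every triad
      ## window contains at most one substitution; the truth then remains
      ## identifiable from single-substitution treatments (short parents
      ## fall back to single mutations)
      n_mut <- if (L >= 4) sample(1:2, 1) else 1L
      repeat {
        pos <- sample(L, n_mut)
        if (n_mut == 1 || abs(diff(pos)) >= 3) break
      }
      for (p in pos) v[p] <- sample(setdiff(AA_LETTERS, v[p]), 1)
      paste(v, collapse = "")
    }, "")
    X <- t(vapply(seqs, conjoint_triad, numeric(343), normalize = "count"))
    signal <- unname(drop(X %*% true_weights))
    if (!is.null(w2)) {
      q <- unname(drop(X %*% w2))
      signal <- signal + nonlinear_scale * (q - mean(q))^2
    }
    offset <- offset_mean - mean(signal)
    truth <- offset + signal
    seqs <- unname(seqs)
    affinity <- truth + stats::rnorm(n_records, sd = noise_sd)
    list(records = data.frame(peptide_seq = seqs, target_seq = target,
                              affinity = affinity,
                              stringsAsFactors = FALSE),
         true_affinity = truth,
         true_ranking = order(truth),
         true_weights = true_weights, target = target, parent = parent)
  })
  out
}

#' Generate a synthetic trajectory with known fluctuation structure
#'
#' Harmonic mode: every frame displaces each residue rigidly by an
#' isotropic Gaussian vector with that residue's amplitude (per-coordinate
#' standard deviation, Angstrom), emulating harmonic fluctuation about the
#' reference. Hopping mode: `n_states` reference conformers (seeded rigid
#' per-residue offsets) are visited in contiguous blocks with small
#' within-state jitter, emulating discrete conformational states.
#'
#' @param topology a `pep_structure` (e.g. one chain of
#'   [make_toy_complex()]).
#' @param n_frames number of frames (>= 2).
#' @param dt frame spacing, ns (10 ps default, a common save interval).
#' @param amplitudes per-residue amplitude vector (recycled), Angstrom.
#' @param mode `"harmonic"` or `"hopping"`.
#' @param n_states number of states in hopping mode.
#' @param state_sd per-residue offset scale between states, Angstrom.
#' @param jitter within-state jitter in hopping mode, Angstrom.
#' @param seed RNG seed.
#' @return list with `trajectory`, `amplitudes` (per residue) and, in
#'   hopping mode, `state_labels` per frame.
#' @export
make_trajectory <- function(topology, n_frames = 500, dt = 0.01,
                            amplitudes = 0.5,
                            mode = c("harmonic", "hopping"),
                            n_states = 3, state_sd = 3.0, jitter = 0.1,
                            seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 2, all(amplitudes >= 0))
  a <- topology$atoms
  a <- a[a$model == min(a$model), , drop = FALSE]
  topo <- topology
  topo$atoms <- a
  id <- residue_id_of(a)
  res_ids <- unique(id)
  n_res <- length(res_ids)
  amp <- rep_len(amplitudes, n_res)
  atom_res <- match(id, res_ids)
  ref <- cbind(a$x, a$y, a$z)
  out <- withr_seed(seed, {
    coords <- array(0, dim = c(n_frames, nrow(a), 3))
    labels <- NULL
    if (mode == "harmonic") {
      for (f in seq_len(n_frames)) {
        disp <- matrix(stats::rnorm(n_res * 3), n_res, 3) * amp
        coords[f, , ] <- ref + disp[atom_res, , drop = FALSE]
      }
    } else {
      states <- lapply(seq_len(n_states), function(s) {
        if (s == 1) matrix(0, n_res, 3)
        else matrix(stats::rnorm(n_res * 3, sd = state_sd), n_res, 3)
      })
      labels <- rep(seq_len(n_states), each = ceiling(n_frames / n_states),
                    length.out = n_frames)
      for (f in seq_len(n_frames)) {
        disp <- states[[labels[f]]] +
          matrix(stats::rnorm(n_res * 3, sd = jitter), n_res, 3)
        coords[f, , ] <- ref + disp[atom_res, , drop = FALSE]
      }
    }
    list(coords = coords, labels = labels)
  })
  list(trajectory = trajectory(topo, out$coords, dt = dt),
       amplitudes = amp, state_labels = out$labels)
}
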