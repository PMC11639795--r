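## Molecular-dynamics post-analysis: Kabsch superposition, RMSD/RMSF,
## radius of gyration, SASA and hydrogen-bond time series, Cartesian PCA
## and Boltzmann-inverted free-energy landscapes. Internal math is in
## Angstrom; reported series follow the nm / nm^2 convention of MD tools.

KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/(mol K)

#' Construct a trajectory
#'
#' @param topology a `pep_structure` providing atom/residue identities.
#' @param coords a `[frames x atoms x 3]` array (Angstrom) or list of
#'   `atoms x 3` matrices aligned to the topology atoms of its first model.
#' @param times frame times in ns, strictly increasing; default
#'   `0, dt, ...` with `dt = 0.01` ns.
#' @param dt frame spacing in ns used when `times` is missing.
#' @return a `trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL, dt = 0.01) {
  if (is.list(coords))
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  n_atoms <- sum(topology$atoms$model == min(topology$atoms$model))
  if (dim(coords)[2] != n_atoms)
    stop("frames have ", dim(coords)[2], " atoms but topology has ", n_atoms)
  n_frames <- dim(coords)[1]
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * dt
  if (length(times) != n_frames || any(diff(times) <= 0))
    stop("times must be strictly increasing, one per frame")
  structure(list(topology = topology, coords = coords, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, %.3f-%.3f ns\n",
              dim(x$coords)[1], dim(x$coords)[2], min(x$times),
              max(x$times)))
  invisible(x)
}

n_frames <- function(t) dim(t$coords)[1]

## Resolve an atom selection on the trajectory topology: NULL = all atoms,
## "CA"/"backbone" = by atom name, integer vector = atom indices.
resolve_selection <- function(t, selection) {
  a <- t$topology$atoms
  a <- a[a$model == min(a$model), , drop = FALSE]
  if (is.null(selection)) return(seq_len(nrow(a)))
  if (is.character(selection)) {
    idx <- switch(selection,
      CA = which(a$name == "CA"),
      backbone = which(a$name %in% c("N", "CA", "C", "O")),
      which(a$name %in% selection))
    if (length(idx) == 0) stop("selection matched no atoms: ", selection)
    return(idx)
  }
  as.integer(selection)
}

atom_masses <- function(t, idx) {
  a <- t$topology$atoms
  a <- a[a$model == min(a$model), , drop = FALSE]
  m <- ELEMENT_MASSES[a$element[idx]]
  m[is.na(m)] <- ELEMENT_MASS_FALLBACK
  unname(m)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the (optionally
#' mass-weighted) RMSD between two point sets; reflections are excluded by
#' the usual determinant correction.
#'
#' @param ref,mobile `n x 3` coordinate matrices (n >= 3).
#' @param weights optional per-point weights (e.g. masses).
#' @return list with `rotation` (3x3, det +1), `translation` (length 3,
#'   applied after rotation), `rmsd` (Angstrom) and `transformed`
#'   coordinates.
#' @export
kabsch_superpose <- function(ref, mobile, weights = NULL) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  if (!all(dim(ref) == dim(mobile))) stop("coordinate sets differ in shape")
  n <- nrow(ref)
  if (n < 3) stop("need at least 3 points to superpose")
  w <- if (is.null(weights)) rep(1, n) else weights / mean(weights)
  cref <- colSums(ref * w) / sum(w)
  cmob <- colSums(mobile * w) / sum(w)
  P <- sweep(mobile, 2, cmob)
  Q <- sweep(ref, 2, cref)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (abs(det(H)) < 1e-12 && d == 0) {
    warning("degenerate point set: superposition is best-effort")
    d <- 1
  }
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  transformed <- P %*% t(R)
  transformed <- sweep(transformed, 2, cref, FUN = "+")
  diff <- transformed - ref
  rmsd <- sqrt(sum(w * rowSums(diff^2)) / sum(w))
  list(rotation = R, translation = cref - drop(R %*% cmob), rmsd = rmsd,
       transformed = transformed)
}

#' RMSD time series against a reference frame
#'
#' Each frame is Kabsch-superposed on the reference frame over the
#' selection before the deviation is measured.
#'
#' @param t a [trajectory()].
#' @param selection atom selection (`NULL` = all, `"CA"`, `"backbone"`, or
#'   atom indices).
#' @param ref_frame reference frame index (default 1).
#' @return data.frame with `time` (ns) and `rmsd` (nm).
#' @export
rmsd_series <- function(t, selection = NULL, ref_frame = 1) {
  idx <- resolve_selection(t, selection)
  nf <- n_frames(t)
  if (ref_frame < 1 || ref_frame > nf) stop("ref_frame out of range")
  ref <- t$coords[ref_frame, idx, , drop = TRUE]
  vals <- vapply(seq_len(nf), function(f) {
    kabsch_superpose(ref, t$coords[f, idx, , drop = TRUE])$rmsd
  }, 1.0)
  data.frame(time = t$times, rmsd = angstrom_to_nm(vals))
}

## Superpose all frames onto their mean structure (iterated), returning the
## aligned coordinate array restricted to `idx`. With
## `weight_by_variance = TRUE` the second and later iterations weight the
## fit by the inverse of each atom's apparent variance, anchoring the
## superposition on the least mobile atoms so that highly mobile residues
## do not leak rigid-body error into quiet ones (used for RMSF).
superpose_to_mean <- function(t, idx, iterations = 2,
                              weight_by_variance = FALSE) {
  nf <- n_frames(t)
  aligned <- t$coords[, idx, , drop = FALSE]
  ref <- aligned[1, , , drop = TRUE]
  w <- NULL
  for (it in seq_len(iterations)) {
    for (f in seq_len(nf))
      aligned[f, , ] <- kabsch_superpose(ref, aligned[f, , , drop = TRUE],
                                         weights = w)$transformed
    ref <- apply(aligned, c(2, 3), mean)
    if (weight_by_variance) {
      dev <- sweep(aligned, c(2, 3), ref)
      v <- apply(dev^2, 2, mean)
      w <- 1 / (v + 1e-3)
    }
  }
  list(aligned = aligned, mean = ref)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the (iteratively refined) mean structure,
#' with later iterations weighting the fit by inverse per-atom variance so
#' that the least mobile atoms anchor the frame of reference; per-atom
#' RMSF is the square root of the time-averaged squared deviation from the
#' mean position, and residues aggregate their atoms by mass-weighted
#' mean.
#'
#' @inheritParams rmsd_series
#' @return data.frame with residue keys, `resname` and `rmsf` (nm).
#' @export
rmsf <- function(t, selection = NULL) {
  if (n_frames(t) < 2) stop("RMSF needs at least 2 frames")
  idx <- resolve_selection(t, selection)
  sp <- superpose_to_mean(t, idx, iterations = 3,
                          weight_by_variance = TRUE)
  dev2 <- sweep(sp$aligned, c(2, 3), sp$mean)
  per_atom <- sqrt(apply(dev2^2, 2, function(m) mean(rowSums(m))))
  ## dev2^2 summed over xyz, averaged over frames
  a <- t$topology$atoms
  a <- a[a$model == min(a$model), , drop = FALSE][idx, , drop = FALSE]
  masses <- atom_masses(t, idx)
  id <- residue_id_of(a)
  agg_num <- tapply(per_atom * masses, id, sum)
  agg_den <- tapply(masses, id, sum)
  first <- !duplicated(id)
  out <- data.frame(chain = a$chain[first], resseq = a$resseq[first],
                    icode = a$icode[first], resname = a$resname[first],
                    stringsAsFactors = FALSE)
  out$rmsf <- angstrom_to_nm(
    as.numeric(agg_num[id[first]] / agg_den[id[first]]))
  out <- out[order_residue_keys(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Radius of gyration of one conformation
#'
#' Mass-weighted RMS distance of atoms from their centre of mass.
#'
#' @param coords `n x 3` coordinates (Angstrom).
#' @param masses per-atom masses; default all equal.
#' @return radius of gyration in nm.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 1) stop("need at least one atom")
  m <- if (is.null(masses)) rep(1, n) else masses
  if (sum(m) <= 0) stop("total mass must be positive")
  com <- colSums(coords * m) / sum(m)
  angstrom_to_nm(sqrt(sum(m * rowSums(sweep(coords, 2, com)^2)) / sum(m)))
}

#' Radius-of-gyration time series
#'
#' @inheritParams rmsd_series
#' @return data.frame with `time` (ns) and `rg` (nm).
#' @export
rg_series <- function(t, selection = NULL) {
  idx <- resolve_selection(t, selection)
  masses <- atom_masses(t, idx)
  vals <- vapply(seq_len(n_frames(t)), function(f)
    radius_of_gyration(t$coords[f, idx, , drop = TRUE], masses), 1.0)
  data.frame(time = t$times, rg = vals)
}

#' SASA time series
#'
#' Total solvent-accessible surface area of the selection per frame.
#'
#' @inheritParams rmsd_series
#' @param params a [sasa_params()].
#' @param algorithm `"shrake"` or `"lee"`.
#' @return data.frame with `time` (ns) and `sasa` (nm^2).
#' @export
sasa_series <- function(t, params = sasa_params(), selection = NULL,
                        algorithm = "shrake") {
  a <- t$topology$atoms
  a <- a[a$model == min(a$model), , drop = FALSE]
  sub <- if (is.null(selection)) NULL else {
    idx <- resolve_selection(t, selection)
    unique(residue_keys(a$chain[idx], a$resseq[idx], a$icode[idx]))
  }
  vals <- vapply(seq_len(n_frames(t)), function(f) {
    s <- t$topology
    s$atoms <- a
    s$atoms$x <- t$coords[f, , 1]
    s$atoms$y <- t$coords[f, , 2]
    s$atoms$z <- t$coords[f, , 3]
    compute_sasa(s, params, algorithm, subset = sub)$total
  }, 1.0)
  data.frame(time = t$times, sasa = angstrom2_to_nm2(vals))
}

#' Hydrogen-bond count time series
#'
#' @inheritParams rmsd_series
#' @param donors_from,acceptors_from chain-id sets (see [detect_hbonds()]).
#' @param d_max,angle_min hydrogen-bond criteria.
#' @return data.frame with `time` (ns) and `n_hbonds`.
#' @export
hbond_series <- function(t, donors_from, acceptors_from, d_max = 3.5,
                         angle_min = 120) {
  a0 <- t$topology$atoms
  a0 <- a0[a0$model == min(a0$model), , drop = FALSE]
  vals <- vapply(seq_len(n_frames(t)), function(f) {
    s <- t$topology
    s$atoms <- a0
    s$atoms$x <- t$coords[f, , 1]
    s$atoms$y <- t$coords[f, , 2]
    s$atoms$z <- t$coords[f, , 3]
    nrow(detect_hbonds(s, donors_from, acceptors_from, d_max, angle_min))
  }, 1L)
  data.frame(time = t$times, n_hbonds = vals)
}

#' Cartesian principal component analysis of a trajectory
#'
#' Frames are superposed onto the mean structure, flattened to 3N
#' coordinate vectors, and the covariance is eigendecomposed. Eigenvalues
#' are in descending order; each eigenvector's largest-magnitude entry is
#' made positive so projections have a deterministic sign.
#'
#' @inheritParams rmsd_series
#' @param n_components number of projection columns to return.
#' @return list with `eigenvalues` (Angstrom^2, all 3N), `projections`
#'   (frames x n_components, Angstrom) and `vectors`.
#' @export
traj_pca <- function(t, selection = NULL, n_components = 2) {
  nf <- n_frames(t)
  if (nf < 3) stop("PCA needs at least 3 frames")
  idx <- resolve_selection(t, selection)
  sp <- superpose_to_mean(t, idx)
  X <- matrix(sp$aligned, nrow = nf)  # frames x 3N
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  eig <- sv$d^2 / (nf - 1)
  vectors <- sv$v
  flip <- apply(vectors, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  vectors <- sweep(vectors, 2, flip, "*")
  proj <- Xc %*% vectors
  k <- min(n_components, ncol(proj))
  list(eigenvalues = eig, projections = proj[, seq_len(k), drop = FALSE],
       vectors = vectors[, seq_len(k), drop = FALSE])
}

#' Free-energy landscape from 2D projections
#'
#' Boltzmann inversion of the sampled density over two collective
#' coordinates (usually the first two principal components):
#' `F = -kB T ln(P / Pmax)`, so the modal bin has free energy 0. Empty
#' bins are capped at the maximal occupied value plus `kB T` so grids
#' remain finite and plottable.
#'
#' @param proj matrix with at least 2 columns of per-frame projections.
#' @param temperature temperature in K.
#' @param bins number of bins per axis (>= 2).
#' @return a `fel_grid`: `pc1_edges`, `pc2_edges`, `free_energy` matrix
#'   (kcal/mol), `temperature`, `cap`.
#' @export
free_energy_landscape <- function(proj, temperature = 300, bins = 32) {
  proj <- as.matrix(proj)
  stopifnot(ncol(proj) >= 2, nrow(proj) >= 1, bins >= 2)
  x <- proj[, 1]; y <- proj[, 2]
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  xr <- pad(range(x)); yr <- pad(range(y))
  xe <- seq(xr[1], xr[2], length.out = bins + 1)
  ye <- seq(yr[1], yr[2], length.out = bins + 1)
  xi <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1), bins)
  yi <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1), bins)
  counts <- matrix(0, bins, bins)
  for (i in seq_along(xi)) counts[xi[i], yi[i]] <- counts[xi[i], yi[i]] + 1
  kt <- KB_KCAL * temperature
  fe <- matrix(NA_real_, bins, bins)
  occ <- counts > 0
  fe[occ] <- -kt * log(counts[occ] / max(counts))
  cap <- if (any(occ)) max(fe[occ]) + kt else kt
  fe[!occ] <- cap
  structure(list(pc1_edges = xe, pc2_edges = ye, free_energy = fe,
                 temperature = temperature, cap = cap),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf("<fel_grid> %dx%d bins, T=%g K, cap=%.3f kcal/mol\n",
              nrow(x$free_energy), ncol(x$free_energy), x$temperature,
              x$cap))
  invisible(x)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param t a [trajectory()].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_trajectory_pdb <- function(t, path) {
  a0 <- t$topology$atoms
  a0 <- a0[a0$model == min(a0$model), , drop = FALSE]
  frames <- lapply(seq_len(n_frames(t)), function(f) {
    a <- a0
    a$model <- f
    a$x <- t$coords[f, , 1]; a$y <- t$coords[f, , 2]; a$z <- t$coords[f, , 3]
    a
  })
  s <- new_structure(do.call(rbind, frames))
  write_pdb(s, path)
}

#' Read a trajectory from a multi-model PDB
#'
#' @param path PDB path; models become frames.
#' @param dt frame spacing in ns.
#' @return a [trajectory()].
#' @export
read_trajectory_pdb <- function(path, dt = 0.01) {
  s <- read_pdb(path)
  models <- sort(unique(s$atoms$model))
  topo <- s
  topo$atoms <- topo$atoms[topo$atoms$model == models[1], , drop = FALSE]
  coords <- lapply(models, function(m) {
    a <- s$atoms[s$atoms$model == m, , drop = FALSE]
    cbind(a$x, a$y, a$z)
  })
  trajectory(topo, coords, dt = dt)
}
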