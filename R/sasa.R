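## Solvent-accessible surface areas, buried-surface interface analysis and
## hydrogen-bond detection. Two independent SASA algorithms are provided so
## each can serve as a cross-check on the other, the way FreeSASA exposes
## both Shrake-Rupley and Lee-Richards.

#' SASA computation parameters
#'
#' @param probe_radius probe (solvent) radius in Angstrom; 1.4 approximates
#'   a water molecule.
#' @param n_test_points number of Shrake-Rupley test points per atom
#'   (deterministic Fibonacci lattice, no randomness).
#' @param slice_width Lee-Richards slice thickness in Angstrom.
#' @param include_hydrogens include hydrogen atoms in the computation?
#'   Default off, matching the common heavy-atom convention.
#' @return a `sasa_params` list.
#' @export
sasa_params <- function(probe_radius = 1.4, n_test_points = 100,
                        slice_width = 0.25, include_hydrogens = FALSE) {
  stopifnot(probe_radius >= 0, n_test_points >= 12, slice_width > 0)
  structure(list(probe_radius = probe_radius,
                 n_test_points = as.integer(n_test_points),
                 slice_width = slice_width,
                 include_hydrogens = isTRUE(include_hydrogens)),
            class = "sasa_params")
}

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-angle (Fibonacci) lattice; bit-stable for a given `n`, so SASA
#' results carry no run-to-run quadrature jitter.
#'
#' @param n number of points.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

sasa_atom_mask <- function(s, p, model) {
  a <- s$atoms
  mask <- a$model == model
  if (!p$include_hydrogens) mask <- mask & a$element != "H"
  mask
}

sasa_prepare <- function(s, p, model) {
  if (is.null(model)) model <- min(s$atoms$model)
  mask <- sasa_atom_mask(s, p, model)
  a <- s$atoms[mask, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms to compute SASA for (empty structure?)")
  if (any(is.na(a$radius)))
    stop("atom radii not assigned; call assign_radii() first")
  list(atoms = a, coords = cbind(a$x, a$y, a$z), radii = a$radius)
}

sasa_finish <- function(atoms, per_atom_area, p, algorithm, subset_idx) {
  per_atom <- data.frame(chain = atoms$chain, resseq = atoms$resseq,
                         icode = atoms$icode, resname = atoms$resname,
                         name = atoms$name, area = per_atom_area,
                         stringsAsFactors = FALSE)
  per_atom <- per_atom[subset_idx, , drop = FALSE]
  rownames(per_atom) <- NULL
  res <- structure(list(per_atom = per_atom, per_residue = NULL,
                        total = sum(per_atom$area), params = p,
                        algorithm = algorithm),
                   class = "sasa_result")
  aggregate_per_residue(res)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Approximates each atom's accessible surface with a deterministic set of
#' test points on the probe-expanded sphere; points not inside any other
#' expanded sphere are accessible, and the atom's area is the accessible
#' fraction of `4*pi*(r+probe)^2`.
#'
#' @param s a `pep_structure` with radii assigned (see [assign_radii()]).
#' @param p a [sasa_params()] object.
#' @param model model number (default first).
#' @param subset optional residue-key data.frame; areas are computed only
#'   for atoms of those residues (every atom still occludes).
#' @return a `sasa_result` with `per_atom`, `per_residue`, `total` (all in
#'   Angstrom^2) and the parameters used.
#' @export
sasa_shrake_rupley <- function(s, p = sasa_params(), model = NULL,
                               subset = NULL) {
  prep <- sasa_prepare(s, p, model)
  idx <- sasa_subset_index(prep$atoms, subset)
  pts <- fibonacci_sphere(p$n_test_points)
  area <- .sasa_shrake_cpp(prep$coords, prep$radii, p$probe_radius, pts, idx)
  sasa_finish(prep$atoms, area, p, "shrake_rupley", idx)
}

#' Lee-Richards solvent-accessible surface area
#'
#' Integrates the accessible arc length of the probe-expanded sphere over
#' z-slices of width `slice_width`; deterministic.
#'
#' @inheritParams sasa_shrake_rupley
#' @return a `sasa_result` (areas in Angstrom^2).
#' @export
sasa_lee_richards <- function(s, p = sasa_params(), model = NULL,
                              subset = NULL) {
  prep <- sasa_prepare(s, p, model)
  idx <- sasa_subset_index(prep$atoms, subset)
  area <- .sasa_lee_richards_cpp(prep$coords, prep$radii, p$probe_radius,
                                 p$slice_width, idx)
  sasa_finish(prep$atoms, area, p, "lee_richards", idx)
}

sasa_subset_index <- function(atoms, subset) {
  if (is.null(subset)) return(seq_len(nrow(atoms)))
  want <- paste0(subset$chain, "|", subset$resseq, "|", subset$icode)
  idx <- which(residue_id_of(atoms) %in% want)
  idx
}

#' Compute surface area by a named algorithm
#'
#' @inheritParams sasa_shrake_rupley
#' @param algorithm `"shrake"` or `"lee"`.
#' @return a `sasa_result`.
#' @export
compute_sasa <- function(s, p = sasa_params(), algorithm = c("shrake", "lee"),
                         model = NULL, subset = NULL) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "shrake") sasa_shrake_rupley(s, p, model, subset)
  else sasa_lee_richards(s, p, model, subset)
}

#' Aggregate per-atom areas to per-residue areas
#'
#' @param r a `sasa_result`.
#' @return the result with `per_residue` recomputed; residue sums equal the
#'   total by construction.
#' @export
aggregate_per_residue <- function(r) {
  pa <- r$per_atom
  id <- paste0(pa$chain, "|", pa$resseq, "|", pa$icode)
  agg <- tapply(pa$area, id, sum)
  first <- !duplicated(id)
  pr <- data.frame(chain = pa$chain[first], resseq = pa$resseq[first],
                   icode = pa$icode[first], resname = pa$resname[first],
                   stringsAsFactors = FALSE)
  pr$area <- unname(agg[id[first]])
  pr <- pr[order_residue_keys(pr), , drop = FALSE]
  rownames(pr) <- NULL
  r$per_residue <- pr
  r$total <- sum(pa$area)
  r
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> algorithm=%s total=%.2f A^2 (%d atoms, %d residues)\n",
              x$algorithm, x$total, nrow(x$per_atom), nrow(x$per_residue)))
  invisible(x)
}

#' Bound/unbound delta-SASA at a binding site
#'
#' Computes the solvent-accessible surface area of the `site` residues in
#' the unbound receptor (receptor chains alone) and in the bound complex
#' (all chains); their difference is the surface buried by the ligand, the
#' quantity used to score docked poses.
#'
#' @param complex a `pep_structure` holding receptor and ligand chains.
#' @param receptor_chains,ligand_chains disjoint chain-id sets.
#' @param site residue-key data.frame of receptor residues defining the
#'   binding site.
#' @param p a [sasa_params()] object.
#' @param algorithm `"shrake"` or `"lee"`.
#' @return a `delta_sasa_report`: `site_residues`, `unbound_site_sasa`,
#'   `bound_site_sasa`, `delta_sasa` and `per_residue` (columns `unbound`,
#'   `bound`, `delta`), all in Angstrom^2.
#' @export
delta_sasa <- function(complex, receptor_chains, ligand_chains, site,
                       p = sasa_params(), algorithm = "shrake") {
  if (length(intersect(receptor_chains, ligand_chains)) > 0)
    stop("receptor and ligand chain sets overlap: ",
         paste(intersect(receptor_chains, ligand_chains), collapse = ", "))
  if (is.null(site) || nrow(site) == 0) {
    warning("empty binding site: delta-SASA report is all zeros")
    rep0 <- structure(list(site_residues = residue_keys(character(0), integer(0)),
                           unbound_site_sasa = 0, bound_site_sasa = 0,
                           delta_sasa = 0,
                           per_residue = data.frame(), params = p),
                      class = "delta_sasa_report")
    return(rep0)
  }
  if (!all(site$chain %in% receptor_chains))
    stop("site residues must belong to the receptor chains")
  receptor <- select_structure(complex, receptor_chains)
  ## ligand chains must exist in the complex
  select_structure(complex, ligand_chains)
  unbound <- compute_sasa(receptor, p, algorithm, subset = site)
  bound <- compute_sasa(complex, p, algorithm, subset = site)
  ub <- unbound$per_residue
  bd <- bound$per_residue
  key_ub <- paste0(ub$chain, "|", ub$resseq, "|", ub$icode)
  key_bd <- paste0(bd$chain, "|", bd$resseq, "|", bd$icode)
  m <- match(key_ub, key_bd)
  per <- ub[, c("chain", "resseq", "icode", "resname")]
  per$unbound <- ub$area
  per$bound <- bd$area[m]
  per$delta <- per$unbound - per$bound
  structure(list(site_residues = site,
                 unbound_site_sasa = sum(per$unbound),
                 bound_site_sasa = sum(per$bound),
                 delta_sasa = sum(per$unbound) - sum(per$bound),
                 per_residue = per, params = p),
            class = "delta_sasa_report")
}

#' @export
print.delta_sasa_report <- function(x, ...) {
  cat(sprintf("<delta_sasa_report> unbound=%.2f bound=%.2f delta=%.2f A^2 (%d site residues)\n",
              x$unbound_site_sasa, x$bound_site_sasa, x$delta_sasa,
              nrow(x$per_residue)))
  invisible(x)
}

#' Interface residues from a delta-SASA report
#'
#' @param report a `delta_sasa_report`.
#' @param per_residue_cutoff minimal per-residue buried area (Angstrom^2);
#'   1.0 is a standard buried-surface convention.
#' @return residue-key data.frame of residues with `delta >= cutoff`, in
#'   residue-key order.
#' @export
detect_interface <- function(report, per_residue_cutoff = 1.0) {
  per <- report$per_residue
  if (is.null(per) || nrow(per) == 0)
    return(residue_keys(character(0), integer(0)))
  hit <- per[per$delta >= per_residue_cutoff, c("chain", "resseq", "icode"),
             drop = FALSE]
  hit <- hit[order_residue_keys(hit), , drop = FALSE]
  rownames(hit) <- NULL
  hit
}

## --- hydrogen bonds ---------------------------------------------------

## Residue-template donor/acceptor heavy atoms (N/O chemistry only).
HB_DONORS <- list(
  backbone = "N",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1", SER = "OG", THR = "OG1", TYR = "OH")
HB_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

hb_mask <- function(atoms, templates, skip_pro_backbone = FALSE) {
  mask <- atoms$name %in% templates$backbone
  if (skip_pro_backbone) mask <- mask & atoms$resname != "PRO"
  for (res in setdiff(names(templates), "backbone"))
    mask <- mask | (atoms$resname == res & atoms$name %in% templates[[res]])
  mask
}

#' Detect hydrogen bonds between two chain sets
#'
#' Donor and acceptor heavy atoms are identified from residue templates
#' (N/O donors, N/O acceptors). A pair is a hydrogen bond when the
#' donor-acceptor distance is at most `d_max`; when explicit hydrogens are
#' attached to the donor, the best D-H...A angle must also reach
#' `angle_min` (the angle test is skipped for hydrogen-free structures).
#'
#' @param s a `pep_structure`.
#' @param donors_from,acceptors_from chain-id sets supplying donors and
#'   acceptors respectively.
#' @param d_max donor-acceptor distance cutoff, Angstrom.
#' @param angle_min minimal D-H...A angle, degrees.
#' @param model model number (default first).
#' @return data.frame of bonds sorted by donor residue key, with donor and
#'   acceptor identities, `distance` (Angstrom) and `angle` (degrees, `NA`
#'   without hydrogens).
#' @export
detect_hbonds <- function(s, donors_from, acceptors_from, d_max = 3.5,
                          angle_min = 120, model = NULL) {
  a <- s$atoms
  if (is.null(model)) model <- min(a$model)
  a <- a[a$model == model, , drop = FALSE]
  don <- a[a$chain %in% donors_from &
             hb_mask(a, HB_DONORS, skip_pro_backbone = TRUE), , drop = FALSE]
  acc <- a[a$chain %in% acceptors_from & hb_mask(a, HB_ACCEPTORS), ,
           drop = FALSE]
  empty <- data.frame(donor_chain = character(0), donor_resseq = integer(0),
                      donor_icode = character(0), donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_resseq = integer(0),
                      acceptor_icode = character(0),
                      acceptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(don) == 0 || nrow(acc) == 0) return(empty)
  hyd <- a[a$element == "H", , drop = FALSE]
  rows <- vector("list", 0)
  for (i in seq_len(nrow(don))) {
    d <- don[i, ]
    dx <- acc$x - d$x; dy <- acc$y - d$y; dz <- acc$z - d$z
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    same_res <- acc$chain == d$chain & acc$resseq == d$resseq &
      acc$icode == d$icode
    cand <- which(dist <= d_max & !same_res & dist > 0.5)
    if (length(cand) == 0) next
    ## hydrogens covalently attached to this donor (within 1.25 A)
    hsel <- integer(0)
    if (nrow(hyd) > 0) {
      hd <- sqrt((hyd$x - d$x)^2 + (hyd$y - d$y)^2 + (hyd$z - d$z)^2)
      hsel <- which(hd < 1.25 & hyd$chain == d$chain &
                      hyd$resseq == d$resseq & hyd$icode == d$icode)
    }
    for (j in cand) {
      ang <- NA_real_
      ok <- TRUE
      if (length(hsel) > 0) {
        best <- -Inf
        for (h in hsel) {
          v1 <- c(d$x - hyd$x[h], d$y - hyd$y[h], d$z - hyd$z[h])
          v2 <- c(acc$x[j] - hyd$x[h], acc$y[j] - hyd$y[h],
                  acc$z[j] - hyd$z[h])
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          best <- max(best, acos(max(-1, min(1, cosang))) * 180 / pi)
        }
        ang <- best
        ok <- best >= angle_min
      }
      if (!ok) next
      rows[[length(rows) + 1]] <- data.frame(
        donor_chain = d$chain, donor_resseq = d$resseq,
        donor_icode = d$icode, donor_atom = d$name,
        acceptor_chain = acc$chain[j], acceptor_resseq = acc$resseq[j],
        acceptor_icode = acc$icode[j], acceptor_atom = acc$name[j],
        distance = dist[j], angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$donor_chain,
                   residue_key_rank(out$donor_resseq, out$donor_icode),
                   out$donor_atom, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## --- unit helpers ------------------------------------------------------

#' Unit conversions between Angstrom-based and nm-based quantities
#'
#' Internal math is in Angstrom (lengths) and Angstrom^2 (areas); reported
#' trajectory quantities follow the nm/nm^2 convention of MD tooling.
#'
#' @param x numeric vector.
#' @return converted numeric vector.
#' @export
angstrom_to_nm <- function(x) x / 10

#' @rdname angstrom_to_nm
#' @export
angstrom2_to_nm2 <- function(x) x / 100
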