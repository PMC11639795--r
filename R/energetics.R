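## Docked-pose scoring by interface burial and the MM-GBSA decomposition
## ledger. Force-field and GB terms are consumed from external tables; the
## ledger identities and the gamma*SASA non-polar term are computed here.

#' Construct a docked-pose ensemble
#'
#' @param receptor receptor `pep_structure`.
#' @param poses list of ligand `pep_structure` objects (all sharing
#'   topology), or a single multi-model structure whose models are poses.
#' @param site residue-key data.frame of receptor binding-site residues.
#' @param model_ids optional integer ids; defaults to `0:(n-1)` (or the
#'   model numbers for a multi-model structure).
#' @return a `pose_ensemble`.
#' @export
pose_ensemble <- function(receptor, poses, site, model_ids = NULL) {
  if (inherits(poses, "pep_structure")) {
    models <- sort(unique(poses$atoms$model))
    lst <- lapply(models, function(m) {
      p <- poses
      p$atoms <- p$atoms[p$atoms$model == m, , drop = FALSE]
      p$atoms$model <- 1L
      p
    })
    if (is.null(model_ids)) model_ids <- models
    poses <- lst
  }
  if (length(poses) == 0) stop("pose ensemble must contain at least one pose")
  if (is.null(model_ids)) model_ids <- seq_along(poses) - 1L
  if (anyDuplicated(model_ids)) stop("pose model ids must be unique")
  n_atoms <- vapply(poses, function(p) nrow(p$atoms), 1L)
  if (length(unique(n_atoms)) != 1)
    stop("all poses must share the same ligand topology")
  structure(list(receptor = receptor, poses = poses, site = site,
                 model_ids = as.integer(model_ids)),
            class = "pose_ensemble")
}

#' Score every pose by interface delta-SASA
#'
#' The unbound site SASA is computed once on the receptor; each pose's
#' bound SASA comes from the receptor-plus-ligand complex, so the score is
#' the surface buried by that pose.
#'
#' @param e a [pose_ensemble()].
#' @param p a [sasa_params()].
#' @param algorithm `"shrake"` or `"lee"`.
#' @return data.frame of pose scores: `model_id`, `unbound`, `bound`,
#'   `delta` (Angstrom^2), one row per pose.
#' @export
score_poses <- function(e, p = sasa_params(), algorithm = "shrake") {
  if (!inherits(e, "pose_ensemble")) stop("e must be a pose_ensemble")
  if (is.null(e$site) || nrow(e$site) == 0) stop("pose ensemble has empty site")
  unbound <- compute_sasa(e$receptor, p, algorithm, subset = e$site)$total
  bound <- vapply(e$poses, function(pose) {
    cx <- merge_structures(e$receptor, pose)
    compute_sasa(cx, p, algorithm, subset = e$site)$total
  }, 1.0)
  data.frame(model_id = e$model_ids, unbound = unbound, bound = bound,
             delta = unbound - bound)
}

#' Pose scores from a printed bound/unbound SASA table
#'
#' Recomputes `delta = unbound - bound` from tabulated bound and unbound
#' site areas (e.g. a published docking summary).
#'
#' @param df data.frame with columns `model_id` (or `model`), `unbound`,
#'   `bound`.
#' @return pose-score data.frame as from [score_poses()].
#' @export
pose_scores_from_table <- function(df) {
  id <- df$model_id %||% df$model
  if (is.null(id)) stop("table needs a 'model_id' or 'model' column")
  if (is.null(df$unbound) || is.null(df$bound))
    stop("table needs 'unbound' and 'bound' columns")
  out <- data.frame(model_id = id, unbound = df$unbound, bound = df$bound,
                    delta = df$unbound - df$bound)
  if (!is.null(df$peptide)) out$peptide <- df$peptide
  out
}

#' Select the best pose: maximal buried surface
#'
#' @param scores pose-score data.frame ([score_poses()]).
#' @return the single best row; ties are broken by the lowest `model_id`.
#' @export
select_best_pose <- function(scores) {
  if (is.null(scores) || nrow(scores) == 0) stop("no pose scores to select from")
  ord <- order(-scores$delta, scores$model_id)
  best <- scores[ord[1], , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Non-polar solvation term from surface area
#'
#' `ESURF = gamma * SASA`, the usual surface-tension model for the
#' non-polar part of the solvation free energy.
#'
#' @param sasa surface area, Angstrom^2 (>= 0).
#' @param gamma surface tension coefficient, kcal/(mol Angstrom^2);
#'   default 0.0072, the common MM-GBSA value.
#' @return energy in kcal/mol.
#' @export
esurf_from_sasa <- function(sasa, gamma = 0.0072) {
  if (any(sasa < 0)) stop("SASA must be non-negative")
  gamma * sasa
}

#' Bundle MM-GBSA energy components
#'
#' @param EEL electrostatic energy, kcal/mol.
#' @param VDWAALS van der Waals energy, kcal/mol.
#' @param EGB polar (generalized Born) solvation energy, kcal/mol.
#' @param ESURF non-polar solvation energy, kcal/mol.
#' @param entropy_term_TdS the `-T dS` entropy term, kcal/mol (0 when no
#'   entropy estimate is available).
#' @return an `energy_components` list.
#' @export
energy_components <- function(EEL, VDWAALS, EGB, ESURF,
                              entropy_term_TdS = 0) {
  vals <- c(EEL, VDWAALS, EGB, ESURF, entropy_term_TdS)
  if (!all(is.finite(vals))) stop("energy components must be finite")
  structure(list(EEL = EEL, VDWAALS = VDWAALS, EGB = EGB, ESURF = ESURF,
                 entropy_term_TdS = entropy_term_TdS),
            class = "energy_components")
}

#' MM-GBSA decomposition ledger
#'
#' Implements the end-state bookkeeping:
#' gas-phase `GGAS = EEL + VDWAALS`; solvation `GSOLV = EGB + ESURF`;
#' enthalpy `dH = GGAS + GSOLV`; binding `dG = dH - (-T dS)` where the
#' entropy term defaults to zero. When the raw free-energy triple of
#' complex/receptor/ligand is supplied, `dG_from_totals =
#' G_complex - (G_receptor + G_ligand)` is reported alongside.
#'
#' @param components an [energy_components()] object.
#' @param entropy_term_TdS optional override of the `-T dS` term, kcal/mol.
#' @param totals optional `list(G_complex =, G_receptor =, G_ligand =)` of
#'   raw state free energies.
#' @param gamma the surface-tension coefficient recorded with the ledger.
#' @return an `energy_decomposition` with `GGAS`, `GSOLV`, `enthalpy_dH`,
#'   `dG_binding` (all kcal/mol), the components and optionally
#'   `dG_from_totals`. The ledger identities hold exactly.
#' @export
decompose_energy <- function(components, entropy_term_TdS = NULL,
                             totals = NULL, gamma = 0.0072) {
  stopifnot(inherits(components, "energy_components"))
  tds <- entropy_term_TdS %||% components$entropy_term_TdS
  GGAS <- components$EEL + components$VDWAALS
  GSOLV <- components$EGB + components$ESURF
  dH <- GGAS + GSOLV
  dG <- dH - tds
  out <- list(GGAS = GGAS, GSOLV = GSOLV, enthalpy_dH = dH,
              dG_binding = dG, entropy_term_TdS = tds, gamma = gamma,
              components = components)
  if (!is.null(totals)) {
    stopifnot(all(c("G_complex", "G_receptor", "G_ligand") %in% names(totals)))
    out$dG_from_totals <- totals$G_complex -
      (totals$G_receptor + totals$G_ligand)
    out$totals <- totals
  }
  structure(out, class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<energy_decomposition> GGAS=%.2f GSOLV=%.2f ",
                     "dH=%.2f -TdS=%.2f dG=%.2f kcal/mol\n"),
              x$GGAS, x$GSOLV, x$enthalpy_dH, x$entropy_term_TdS,
              x$dG_binding))
  invisible(x)
}

#' Read a per-frame energy-component table
#'
#' Accepts whitespace- or comma-delimited text with a header naming the
#' four components `EEL`, `VDWAALS`, `EGB`, `ESURF` (case-insensitive,
#' any order). A `frame` column is honoured; unknown columns are ignored
#' with a warning.
#'
#' @param path file path.
#' @return data.frame with `frame` plus the four component columns.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("cannot read energy table: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  sep <- if (grepl(",", first)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- toupper(trimws(names(df)))
  required <- c("EEL", "VDWAALS", "EGB", "ESURF")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("energy table is missing required column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(required, "FRAME"))
  if (length(extra) > 0)
    warning("ignoring unknown energy-table column(s): ",
            paste(extra, collapse = ", "))
  out <- data.frame(frame = if ("FRAME" %in% names(df)) df$FRAME
                            else seq_len(nrow(df)))
  for (cn in required) out[[cn]] <- as.numeric(df[[cn]])
  out
}

#' Average an energy table into one decomposition ledger
#'
#' @param table data.frame from [read_energy_table()].
#' @inheritParams decompose_energy
#' @return an `energy_decomposition` of the per-frame means.
#' @export
decompose_energy_table <- function(table, entropy_term_TdS = 0,
                                   gamma = 0.0072) {
  comp <- energy_components(mean(table$EEL), mean(table$VDWAALS),
                            mean(table$EGB), mean(table$ESURF),
                            entropy_term_TdS)
  decompose_energy(comp, gamma = gamma)
}
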