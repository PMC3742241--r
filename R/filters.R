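# Hit filtering: Lipinski's rule of five and key-residue interaction
# checks, plus the final joined report. Donor/acceptor counts follow the
# classic rule-of-five conventions (donors = N/O/S-H groups, acceptors =
# N + O count); logP comes from Open Babel's atom-contribution estimator.

#' Rule-of-five flag from precomputed descriptors
#'
#' Pure predicate behind [lipinski()]: pass requires at most 5 donors, at
#' most 10 acceptors, molecular weight strictly below 500 Da and logP
#' strictly below 5.
#'
#' @param mw molecular weight (Da).
#' @param hbd,hba donor and acceptor counts.
#' @param logp octanol-water partition coefficient estimate.
#' @return logical (vectorized).
#' @export
lipinski_pass <- function(mw, hbd, hba, logp) {
  hbd <= 5 & hba <= 10 & mw < 500 & logp < 5
}

#' Molecular weight of a ligand
#'
#' Standard atomic weights summed over explicit atoms plus implicit
#' hydrogens.
#'
#' @param mol a [ligand_molecule()].
#' @return weight in Da.
#' @export
mol_weight <- function(mol) {
  sum(element_mass(mol$atoms$element)) + 1.008 * sum(implicit_h(mol))
}

#' Estimate logP via Open Babel
#'
#' Atom-contribution (Crippen-style) logP computed by Open Babel through
#' ChemmineOB; the molecule is passed as an in-memory SDF record. An
#' approximation, as any additive logP scheme is.
#'
#' @param mol a [ligand_molecule()].
#' @return numeric logP estimate.
#' @export
mol_logp <- function(mol) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  cs <- conformer_set("mol", mol, list(atom_coords(mol$atoms)))
  write_sdf_library(list(cs), tmp)
  props <- ChemmineR::propOB(suppressWarnings(ChemmineR::read.SDFset(tmp)))
  as.numeric(props$logP[1])
}

#' Lipinski rule-of-five report for one molecule
#'
#' Counts hydrogen-bond donors (N/O/S bearing at least one explicit or
#' implicit hydrogen) and acceptors (every N and O), sums the molecular
#' weight, estimates logP ([mol_logp()] unless supplied) and applies
#' [lipinski_pass()].
#'
#' @param mol a [ligand_molecule()] with perceived bonds and formal
#'   charges.
#' @param molecule_id identifier carried into the report.
#' @param logp optional precomputed logP (skips the Open Babel call).
#' @return one-row data frame: `molecule_id`, `mw`, `hbd_count`,
#'   `hba_count`, `logp`, `lipinski_pass`.
#' @export
lipinski <- function(mol, molecule_id = "mol", logp = NULL) {
  elem <- toupper(mol$atoms$element)
  nH <- total_h(mol)
  hbd <- sum(elem %in% c("N", "O", "S") & nH >= 1L)
  hba <- sum(elem %in% c("N", "O"))
  mw <- mol_weight(mol)
  if (is.null(logp)) logp <- mol_logp(mol)
  data.frame(
    molecule_id = molecule_id, mw = mw, hbd_count = hbd, hba_count = hba,
    logp = logp, lipinski_pass = lipinski_pass(mw, hbd, hba, logp),
    stringsAsFactors = FALSE
  )
}

#' Key-residue interaction check for a ligand pose
#'
#' Marks each named binding-site residue as contacted when the pose makes
#' either a hydrogen bond with it (criteria of [detect_hbonds()]) or an
#' apolar carbon-carbon contact within `apolar_cutoff`. Residues named in
#' the list but absent from the receptor are reported as absent rather
#' than silently uncontacted.
#'
#' @param pose a [ligand_molecule()] whose coordinates sit in the receptor
#'   frame.
#' @param receptor a `pharm_complex` (its protein atoms are used).
#' @param residues character labels, one-letter code plus residue number
#'   (e.g. `"D296"`).
#' @param rules a [perception_rules()] block (hydrogen-bond cutoffs).
#' @param apolar_cutoff apolar contact distance (angstrom).
#' @return data frame with columns `residue`, `present`, `contact`
#'   (`NA` when the residue is absent).
#' @export
key_residue_contacts <- function(pose, receptor, residues,
                                 rules = perception_rules(),
                                 apolar_cutoff = 4.5) {
  prot <- receptor$protein
  plabel <- residue_label(prot$resname, prot$resno)
  tmp <- receptor
  tmp$ligand <- pose
  hb <- detect_hbonds(tmp, rules$hbond_max_da, rules$hbond_min_angle)
  hb_res <- unique(c(hb$donor_res[hb$donor_owner == "protein"],
                     hb$acceptor_res[hb$acceptor_owner == "protein"]))
  lig_c <- which(toupper(pose$atoms$element) == "C")
  lxyz <- atom_coords(pose$atoms)
  out <- data.frame(residue = residues, present = FALSE, contact = NA,
                    stringsAsFactors = FALSE)
  for (k in seq_along(residues)) {
    sel <- which(plabel == residues[k])
    if (length(sel) == 0L) next
    out$present[k] <- TRUE
    hit <- residues[k] %in% hb_res
    if (!hit && length(lig_c) > 0L) {
      apolar <- sel[toupper(prot$element[sel]) == "C" &
                      !(prot$name[sel] %in% c("C", "CA"))]
      if (length(apolar) > 0L) {
        D <- cross_dist(lxyz[lig_c, , drop = FALSE],
                        atom_coords(prot)[apolar, , drop = FALSE])
        hit <- any(D <= apolar_cutoff)
      }
    }
    out$contact[k] <- hit
  }
  out
}

#' Final ranked screening report
#'
#' Joins the screening hit table with per-molecule filter reports and
#' optional external (e.g. docking) scores, applies the configured gates
#' and emits a ranked table with a reasons column naming every failed
#' gate. Gating removes rows from the passing set but never reorders
#' them.
#'
#' @param hits hit table from [screen_library()].
#' @param reports row-bound [lipinski()] reports, optionally with logical
#'   `contact_<RES>` columns (from [key_residue_contacts()]).
#' @param criteria list of gates: `lipinski` (logical), `required_contacts`
#'   (character residue labels), `min_external_score` (numeric). Empty
#'   criteria gate nothing.
#' @param external optional data frame `molecule_id`, `external_score`.
#' @return data frame, one row per hit in rank order, with descriptor
#'   columns, `pass` and `reasons`.
#' @export
final_report <- function(hits, reports, criteria = list(),
                         external = NULL) {
  missing_ids <- setdiff(hits$molecule_id, reports$molecule_id)
  if (length(missing_ids) > 0L) {
    stop("join failure: no filter report for ",
         paste(missing_ids, collapse = ", "))
  }
  out <- merge(hits, reports, by = "molecule_id", sort = FALSE)
  if (!is.null(external)) {
    out <- merge(out, external, by = "molecule_id", all.x = TRUE,
                 sort = FALSE)
  } else {
    out$external_score <- NA_real_
  }
  out <- out[order(out$rank), , drop = FALSE]
  reasons <- rep("", nrow(out))
  pass <- rep(TRUE, nrow(out))
  flag <- function(bad, label) {
    bad[is.na(bad)] <- TRUE
    pass <<- pass & !bad
    reasons <<- ifelse(bad, ifelse(nzchar(reasons),
                                   paste(reasons, label, sep = ";"), label),
                       reasons)
  }
  if (isTRUE(criteria$lipinski)) {
    flag(!out$lipinski_pass, "lipinski")
  }
  for (res in criteria$required_contacts) {
    col <- paste0("contact_", res)
    if (!col %in% names(out)) {
      stop("join failure: missing contact column ", col)
    }
    flag(!out[[col]], paste0("contact:", res))
  }
  if (!is.null(criteria$min_external_score)) {
    flag(out$external_score < criteria$min_external_score,
         "external_score")
  }
  out$pass <- pass
  out$reasons <- reasons
  rownames(out) <- NULL
  out
}
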