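# structural_annotation: geometric detection of disulfide bonds and
# calcium-coordination sites, Shrake-Rupley solvent accessibility and the
# merged per-residue role table (core membership, conservation,
# glycosylation proximity) that drives variant role flags.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' @noRd
protein_atoms <- function(structure) {
  structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
}

#' @noRd
residue_key <- function(atoms) paste(atoms$chain_id, atoms$res_seq, atoms$ins_code)

#' Detect disulfide bonds from cysteine sulfur geometry
#'
#' All cysteine Sg-Sg pairs within `cutoff` are candidate bonds; candidates
#' are accepted greedily nearest-first so that each cysteine joins at most
#' one bond (three bonds per class-A repeat in the native fold). Cysteines
#' lacking an Sg atom are skipped with a warning.
#'
#' @param structure an `ldlr_structure`
#' @param cutoff maximum Sg-Sg distance in angstrom (default 2.5, covalent
#'   range)
#' @return data.frame: chain_a, pos_a, chain_b, pos_b, distance
#' @export
detect_disulfides <- function(structure, cutoff = 2.5) {
  at <- protein_atoms(structure)
  cys <- at[at$res_name == "CYS", , drop = FALSE]
  empty <- data.frame(chain_a = character(), pos_a = integer(),
                      chain_b = character(), pos_b = integer(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!nrow(cys)) return(empty)
  key <- residue_key(cys)
  sg <- cys[cys$atom_name == "SG", , drop = FALSE]
  no_sg <- setdiff(unique(key), residue_key(sg))
  if (length(no_sg))
    warning("cysteine(s) without SG atom skipped: ",
            paste(no_sg, collapse = "; "))
  if (nrow(sg) < 2) return(empty)
  xyz <- as.matrix(sg[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  cand <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used <- logical(nrow(sg))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      chain_a = sg$chain_id[i], pos_a = sg$res_seq[i],
      chain_b = sg$chain_id[j], pos_b = sg$res_seq[j],
      distance = d[i, j], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(pmin(out$pos_a, out$pos_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect calcium coordination sites
#'
#' For each calcium ion, lists every protein oxygen atom (side-chain
#' carboxylate/amide/hydroxyl and backbone carbonyl) within `cutoff` of the
#' ion. A physiologic class-A site has at least four coordinating oxygens;
#' sites with fewer produce a warning but are still reported.
#'
#' @param structure an `ldlr_structure`
#' @param cutoff ion-oxygen distance cutoff in angstrom (default 3.2)
#' @return list of sites, each a list with `ion` (one-row data.frame) and
#'   `atoms` (data.frame: chain_id, res_seq, res_name, atom_name, distance,
#'   sidechain)
#' @export
detect_ca_sites <- function(structure, cutoff = 3.2) {
  ions <- structure_ions(structure)
  if (!nrow(ions)) return(list())
  at <- protein_atoms(structure)
  ox <- at[toupper(at$element) == "O", , drop = FALSE]
  sites <- vector("list", nrow(ions))
  for (k in seq_len(nrow(ions))) {
    if (nrow(ox)) {
      dx <- ox$x - ions$x[k]; dy <- ox$y - ions$y[k]; dz <- ox$z - ions$z[k]
      dist <- sqrt(dx^2 + dy^2 + dz^2)
      hit <- dist <= cutoff
    } else hit <- logical(0)
    atoms <- data.frame(chain_id = ox$chain_id[hit], res_seq = ox$res_seq[hit],
                        res_name = ox$res_name[hit],
                        atom_name = ox$atom_name[hit],
                        distance = if (any(hit)) dist[hit] else numeric(0),
                        stringsAsFactors = FALSE)
    atoms$sidechain <- !(atoms$atom_name %in% BACKBONE_ATOMS)
    atoms <- atoms[order(atoms$distance), , drop = FALSE]
    rownames(atoms) <- NULL
    if (nrow(atoms) < 4)
      warning(sprintf("calcium ion %d has only %d coordinating oxygen(s) within %.1f A",
                      k, nrow(atoms), cutoff))
    sites[[k]] <- list(ion = ions[k, , drop = FALSE], atoms = atoms)
  }
  sites
}

#' @noRd
sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  sphere <- fibonacci_sphere(n_points)
  out <- numeric(n)
  rs <- radii + probe
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rs[i] + rs)^2 & d2 > 1e-12)
    pts <- sweep(sphere * rs[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      exposed <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(exposed)) break
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        exposed <- exposed & dj2 > rs[j]^2
      }
      frac <- mean(exposed)
    } else frac <- 1
    out[i] <- frac * 4 * pi * rs[i]^2
  }
  out
}

#' Solvent-accessible surface area and relative accessibility per residue
#'
#' Shrake-Rupley numerical SASA (probe 1.4 angstrom, 960 deterministic
#' sphere points per atom) over the protein heavy atoms, summed per residue
#' and divided by the residue's theoretical maximum area (Tien et al.
#' reference set), clipped to \[0, 1\].
#'
#' @param structure an `ldlr_structure`
#' @param probe probe radius (angstrom)
#' @param n_points sphere points per atom
#' @return data.frame: chain_id, res_seq, ins_code, res_name, sasa, rsa
#' @export
relative_accessibility <- function(structure, probe = 1.4, n_points = 960) {
  at <- protein_atoms(structure)
  at <- at[toupper(at$element) != "H", , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  area <- sasa_atoms(xyz, vdw_radius(at$element), probe, n_points)
  key <- residue_key(at)
  res <- structure_residues(structure)
  res_key <- paste(res$chain_id, res$res_seq, res$ins_code)
  sasa <- tapply(area, key, sum)[res_key]
  out <- res[, c("chain_id", "res_seq", "ins_code", "res_name")]
  out$sasa <- as.numeric(sasa)
  maxa <- MAX_ASA[aa3_to_1(out$res_name)]
  out$rsa <- pmin(1, pmax(0, out$sasa / maxa))
  out
}

#' Merge structural roles into one annotation record per residue
#'
#' @param structure an `ldlr_structure`
#' @param disulfides output of [detect_disulfides()]
#' @param ca_sites output of [detect_ca_sites()]
#' @param profile optional `ldlr_conservation`; conservation z-scores are
#'   matched by precursor position (profile position = residue `res_seq`)
#' @param glyco_sites integer vector of O-glycosylation positions
#' @param window sequence distance defining glycosylation proximity
#'   (default 5 residues)
#' @param core_rsa burial cutoff defining hydrophobic-core membership
#'   (default RSA <= 0.15)
#' @param rsa optional precomputed [relative_accessibility()] table
#' @return data.frame of class annotations: position, chain_id, res_name,
#'   aa, rsa, is_core, in_disulfide, coordinates_ca, ca_sidechain,
#'   ca_backbone, conservation_z, conserved, near_glyco, glyco_site
#' @export
annotate_residues <- function(structure, disulfides = NULL, ca_sites = NULL,
                              profile = NULL, glyco_sites = integer(),
                              window = 5L, core_rsa = 0.15, rsa = NULL) {
  if (is.null(disulfides)) disulfides <- detect_disulfides(structure)
  if (is.null(ca_sites)) ca_sites <- detect_ca_sites(structure)
  if (is.null(rsa)) rsa <- relative_accessibility(structure)
  res <- structure_residues(structure)
  pos <- res$res_seq
  out <- data.frame(position = pos, chain_id = res$chain_id,
                    res_name = res$res_name, aa = res$aa,
                    rsa = rsa$rsa[match(paste(res$chain_id, res$res_seq, res$ins_code),
                                        paste(rsa$chain_id, rsa$res_seq, rsa$ins_code))],
                    stringsAsFactors = FALSE)
  out$is_core <- !is.na(out$rsa) & out$rsa <= core_rsa
  ss_pos <- unique(c(disulfides$pos_a, disulfides$pos_b))
  out$in_disulfide <- out$position %in% ss_pos & out$aa == "C"

  ca_atoms <- do.call(rbind, lapply(ca_sites, `[[`, "atoms"))
  if (is.null(ca_atoms) || !nrow(ca_atoms)) {
    out$coordinates_ca <- out$ca_sidechain <- out$ca_backbone <- FALSE
  } else {
    sc_pos <- unique(ca_atoms$res_seq[ca_atoms$sidechain])
    bb_pos <- unique(ca_atoms$res_seq[!ca_atoms$sidechain])
    out$ca_sidechain <- out$position %in% sc_pos
    out$ca_backbone <- out$position %in% bb_pos
    out$coordinates_ca <- out$ca_sidechain | out$ca_backbone
  }

  if (!is.null(profile)) {
    p <- profile$profile
    idx <- match(out$position, p$position)
    out$conservation_z <- p$score_z[idx]
    out$conserved <- !is.na(idx) & p$conserved[idx]
  } else {
    out$conservation_z <- NA_real_
    out$conserved <- FALSE
  }

  glyco_sites <- as.integer(glyco_sites)
  outside <- glyco_sites[glyco_sites < min(pos) - window |
                           glyco_sites > max(pos) + window]
  if (length(outside))
    warning("glycosylation position(s) outside the structure ignored: ",
            paste(outside, collapse = ", "))
  if (length(glyco_sites)) {
    dmin <- vapply(out$position,
                   function(p) min(abs(p - glyco_sites)), numeric(1))
    out$near_glyco <- dmin <= window
    out$glyco_site <- dmin == 0
  } else {
    out$near_glyco <- out$glyco_site <- FALSE
  }
  out
}

#' Structural role flags for each variant
#'
#' * `alters_disulfide`: the reference residue is a disulfide-bonded
#'   cysteine and the substitution removes it (alt != Cys).
#' * `alters_ca_site`: the residue coordinates calcium through a side-chain
#'   oxygen, or through backbone carbonyls only when the substitution is to
#'   or from Pro/Gly (backbone geometry change).
#' * `at_conserved`, `at_core`, `near_glyco`, `at_glyco`: positional roles.
#' * `in_any_class`: union of conserved / disulfide / calcium flags — the
#'   "structurally informed" membership used in the summary counts.
#'
#' Variants at unannotated positions get all-false flags with a warning.
#'
#' @param variants data.frame with ref_aa, position, alt_aa
#' @param annotations output of [annotate_residues()]
#' @return `variants` with logical flag columns appended
#' @export
variant_role_flags <- function(variants, annotations) {
  idx <- match(variants$position, annotations$position)
  if (any(is.na(idx)))
    warning("variant position(s) without annotation: ",
            paste(unique(variants$position[is.na(idx)]), collapse = ", "))
  ann <- annotations[idx, , drop = FALSE]
  ok <- !is.na(idx)
  variants$alters_disulfide <- ok & !is.na(ann$in_disulfide) &
    ann$in_disulfide & variants$ref_aa == "C" & variants$alt_aa != "C"
  progly <- variants$ref_aa %in% c("P", "G") | variants$alt_aa %in% c("P", "G")
  variants$alters_ca_site <- ok &
    ((!is.na(ann$ca_sidechain) & ann$ca_sidechain) |
       (!is.na(ann$ca_backbone) & ann$ca_backbone & progly))
  variants$at_conserved <- ok & !is.na(ann$conserved) & ann$conserved
  variants$at_core <- ok & !is.na(ann$is_core) & ann$is_core
  variants$near_glyco <- ok & !is.na(ann$near_glyco) & ann$near_glyco
  variants$at_glyco <- ok & !is.na(ann$glyco_site) & ann$glyco_site
  variants$in_any_class <- variants$at_conserved | variants$alters_disulfide |
    variants$alters_ca_site
  variants
}

#' Read a glycosylation-site position list
#'
#' @param path text file, one precursor position per line; `#` comments
#'   allowed
#' @return integer vector
#' @export
read_glyco_sites <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  as.integer(lines[nzchar(lines)])
}
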