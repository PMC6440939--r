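# quality_metrics: the model-quality panel — Ramachandran core/allowed
# fractions and outlier z, intramolecular hydrogen-bond participation,
# atomic clash rate z, and a coarse contact-potential ("dope-like")
# z-score against sequence-shuffled decoys. Reference constants are coarse
# package-level calibrations; the metrics are meant for relative
# comparison between models, and their invariants (frame independence,
# oracle equality, helix limits) are the tested surface.

RAMA_REFERENCE <- list(outlier_mu = 0.02, outlier_sd = 0.02)
CLASH_REFERENCE <- list(rate_mu = 8, rate_sd = 6)  # clashes per 1000 atoms

#' Backbone dihedral angles per residue
#'
#' @param structure an `ldlr_structure`
#' @return data.frame: chain_id, res_seq, res_name, phi, psi (degrees, `NA`
#'   at chain termini or breaks)
#' @export
backbone_dihedrals <- function(structure) {
  at <- protein_atoms(structure)
  res <- structure_residues(structure)
  n <- nrow(res)
  get_atom <- function(i, name) {
    hit <- at[at$chain_id == res$chain_id[i] & at$res_seq == res$res_seq[i] &
                at$ins_code == res$ins_code[i] & at$atom_name == name, ,
              drop = FALSE]
    if (nrow(hit)) as.numeric(hit[1, c("x", "y", "z")]) else NULL
  }
  phi <- psi <- rep(NA_real_, n)
  linked <- function(i, j) {
    # peptide bond present between residues i and j (C_i - N_j ~ 1.33 A)
    if (res$chain_id[i] != res$chain_id[j]) return(FALSE)
    ci <- get_atom(i, "C"); nj <- get_atom(j, "N")
    !is.null(ci) && !is.null(nj) && vnorm(nj - ci) < 2.0
  }
  for (i in seq_len(n)) {
    ni <- get_atom(i, "N"); cai <- get_atom(i, "CA"); ci <- get_atom(i, "C")
    if (is.null(ni) || is.null(cai) || is.null(ci)) next
    if (i > 1 && linked(i - 1, i)) {
      cp <- get_atom(i - 1, "C")
      phi[i] <- dihedral_angle(cp, ni, cai, ci)
    }
    if (i < n && linked(i, i + 1)) {
      nn <- get_atom(i + 1, "N")
      psi[i] <- dihedral_angle(ni, cai, ci, nn)
    }
  }
  data.frame(chain_id = res$chain_id, res_seq = res$res_seq,
             res_name = res$res_name, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

#' @noRd
in_box <- function(phi, psi, phi_lo, phi_hi, psi_lo, psi_hi) {
  phi >= phi_lo & phi <= phi_hi & psi >= psi_lo & psi <= psi_hi
}

#' @noRd
rama_general <- function(phi, psi) {
  core <- in_box(phi, psi, -160, -30, -80, -5) |
    (in_box(phi, psi, -180, -45, 90, 180) | in_box(phi, psi, -180, -45, -180, -165))
  allowed <- core |
    in_box(phi, psi, -180, -20, -120, 45) |
    in_box(phi, psi, -180, -20, 45, 180) |
    in_box(phi, psi, -180, -20, -180, -135) |
    in_box(phi, psi, 20, 100, -40, 90)
  list(core = core, allowed = allowed)
}

#' @noRd
rama_proline <- function(phi, psi) {
  core <- in_box(phi, psi, -110, -40, -60, -10) |
    in_box(phi, psi, -110, -40, 110, 180)
  allowed <- core |
    in_box(phi, psi, -120, -30, -80, 30) |
    in_box(phi, psi, -120, -30, 90, 180) |
    in_box(phi, psi, -120, -30, -180, -160)
  list(core = core, allowed = allowed)
}

#' Classify backbone dihedrals into Ramachandran regions
#'
#' Analytic basin definitions (alpha, beta and left-alpha boxes; glycine
#' additionally gets the mirror-image basins, proline a restricted phi
#' range) standing in for a reference density grid.
#'
#' @param phi,psi numeric vectors (degrees)
#' @param res_name 3-letter residue names
#' @return character vector "core"/"allowed"/"outlier"
#' @export
rama_region <- function(phi, psi, res_name) {
  g <- rama_general(phi, psi)
  gm <- rama_general(-phi, -psi)  # mirrored basins for glycine
  p <- rama_proline(phi, psi)
  is_gly <- res_name == "GLY"
  is_pro <- res_name == "PRO"
  core <- ifelse(is_pro, p$core, ifelse(is_gly, g$core | gm$core, g$core))
  allowed <- ifelse(is_pro, p$allowed,
                    ifelse(is_gly, g$allowed | gm$allowed, g$allowed))
  out <- rep("outlier", length(phi))
  out[allowed] <- "allowed"
  out[core] <- "core"
  out
}

#' Ramachandran statistics for a structure
#'
#' Core and allowed fractions (allowed is cumulative, so core <= allowed)
#' over residues with both phi and psi defined, plus an outlier z-score
#' against the shipped reference (`outlier_mu` 0.02, `outlier_sd` 0.02).
#'
#' @param structure an `ldlr_structure`
#' @return list: core_fraction, allowed_fraction, outlier_fraction,
#'   outlier_z, n_residues
#' @export
ramachandran_stats <- function(structure) {
  di <- backbone_dihedrals(structure)
  ok <- !is.na(di$phi) & !is.na(di$psi)
  if (!any(ok))
    stop("no residue with both phi and psi defined (chain too short?)")
  region <- rama_region(di$phi[ok], di$psi[ok], di$res_name[ok])
  core <- mean(region == "core")
  allowed <- mean(region != "outlier")
  outlier <- mean(region == "outlier")
  list(core_fraction = core, allowed_fraction = allowed,
       outlier_fraction = outlier,
       outlier_z = (outlier - RAMA_REFERENCE$outlier_mu) / RAMA_REFERENCE$outlier_sd,
       n_residues = sum(ok))
}

SIDECHAIN_DONOR_ATOMS <- c("NE", "NH1", "NH2", "NZ", "ND1", "NE2", "ND2",
                           "NE1", "OG", "OG1", "OH")

#' List intramolecular hydrogen bonds
#'
#' Heavy-atom criterion: donor (backbone N except proline, plus side-chain
#' N/O donor atoms) to acceptor oxygen distance <= `dist_cutoff` and
#' antecedent-donor-acceptor angle >= `angle_cutoff`. Same-residue pairs
#' and backbone-backbone pairs of adjacent residues are excluded.
#'
#' @param structure an `ldlr_structure`
#' @param dist_cutoff donor-acceptor distance (default 3.5 angstrom)
#' @param angle_cutoff minimum angle at the donor (default 120 degrees)
#' @return data.frame: donor_res, donor_atom, acceptor_res, acceptor_atom,
#'   distance, angle
#' @export
hbond_list <- function(structure, dist_cutoff = 3.5, angle_cutoff = 120) {
  at <- protein_atoms(structure)
  don <- at[(at$atom_name == "N" & at$res_name != "PRO") |
              at$atom_name %in% SIDECHAIN_DONOR_ATOMS, , drop = FALSE]
  acc <- at[toupper(at$element) == "O", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(don))) {
    same_res <- at$chain_id == don$chain_id[i] & at$res_seq == don$res_seq[i] &
      at$ins_code == don$ins_code[i]
    ante_pool <- at[same_res & !(at$atom_name == don$atom_name[i]), , drop = FALSE]
    if (!nrow(ante_pool)) next
    dpos <- as.numeric(don[i, c("x", "y", "z")])
    dd <- sqrt((ante_pool$x - dpos[1])^2 + (ante_pool$y - dpos[2])^2 +
                 (ante_pool$z - dpos[3])^2)
    ante <- as.numeric(ante_pool[which.min(dd), c("x", "y", "z")])
    da <- sqrt((acc$x - dpos[1])^2 + (acc$y - dpos[2])^2 + (acc$z - dpos[3])^2)
    cand <- which(da <= dist_cutoff)
    for (j in cand) {
      if (acc$chain_id[j] == don$chain_id[i] &&
          acc$res_seq[j] == don$res_seq[i] &&
          acc$ins_code[j] == don$ins_code[i]) next
      both_bb <- don$atom_name[i] %in% BACKBONE_ATOMS &
        acc$atom_name[j] %in% BACKBONE_ATOMS
      if (both_bb && acc$chain_id[j] == don$chain_id[i] &&
          abs(acc$res_seq[j] - don$res_seq[i]) < 2) next
      apos <- as.numeric(acc[j, c("x", "y", "z")])
      ang <- bond_angle(ante, dpos, apos)
      if (ang < angle_cutoff) next
      rows[[length(rows) + 1]] <- data.frame(
        donor_res = don$res_seq[i], donor_atom = don$atom_name[i],
        acceptor_res = acc$res_seq[j], acceptor_atom = acc$atom_name[j],
        distance = da[j], angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(donor_res = integer(), donor_atom = character(),
                      acceptor_res = integer(), acceptor_atom = character(),
                      distance = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Fraction of residues participating in intramolecular hydrogen bonds
#'
#' A residue participates if it appears as donor or acceptor in at least
#' one bond (backbone and side-chain bonds count alike).
#'
#' @inheritParams hbond_list
#' @return fraction in \[0, 1\]
#' @export
hbond_fraction <- function(structure, dist_cutoff = 3.5, angle_cutoff = 120) {
  hb <- hbond_list(structure, dist_cutoff, angle_cutoff)
  res <- structure_residues(structure)
  mean(res$res_seq %in% c(hb$donor_res, hb$acceptor_res))
}

#' Count steric clashes between non-bonded heavy atoms
#'
#' A clash is a heavy-atom pair in different residues closer than the sum
#' of van der Waals radii minus `tolerance`. Backbone-backbone pairs of
#' chain-adjacent residues and disulfide Sg-Sg pairs are excluded as
#' covalent/constrained geometry. Neighbor search uses spatial binning;
#' the brute-force pair scan is kept as the test oracle.
#'
#' @param structure an `ldlr_structure`
#' @param tolerance subtracted from the radius sum (default 0.4 angstrom)
#' @return integer clash count
#' @export
count_clashes <- function(structure, tolerance = 0.4) {
  at <- protein_atoms(structure)
  at <- at[toupper(at$element) != "H", , drop = FALSE]
  n <- nrow(at)
  if (n < 2) return(0L)
  r <- vdw_radius(at$element)
  max_cut <- max(r) * 2 - tolerance
  cell <- max(max_cut, 1)
  ix <- floor(at$x / cell); iy <- floor(at$y / cell); iz <- floor(at$z / cell)
  cell_id <- paste(ix, iy, iz)
  cells <- split(seq_len(n), cell_id)
  coords <- unique(data.frame(ix, iy, iz))
  count <- 0L
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)

  # disulfide partner lookup: atoms within 3 covalent bonds of the S-S
  # bridge (SG-SG, SG-CB of the partner) are constrained geometry
  sg_idx <- which(at$atom_name == "SG")
  ss_partner <- list()
  if (length(sg_idx) > 1) {
    for (a1 in sg_idx) for (a2 in sg_idx) {
      if (a2 <= a1) next
      d <- sqrt((at$x[a1] - at$x[a2])^2 + (at$y[a1] - at$y[a2])^2 +
                  (at$z[a1] - at$z[a2])^2)
      if (d <= 2.5) {
        k1 <- paste(at$chain_id[a1], at$res_seq[a1])
        k2 <- paste(at$chain_id[a2], at$res_seq[a2])
        ss_partner[[k1]] <- k2; ss_partner[[k2]] <- k1
      }
    }
  }
  is_clash_pair <- function(i, j) {
    d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
    if (d >= r[i] + r[j] - tolerance) return(FALSE)
    same_chain <- at$chain_id[i] == at$chain_id[j]
    if (same_chain && at$res_seq[i] == at$res_seq[j] &&
        at$ins_code[i] == at$ins_code[j]) return(FALSE)
    if (same_chain && abs(at$res_seq[i] - at$res_seq[j]) == 1 &&
        at$atom_name[i] %in% BACKBONE_ATOMS &&
        at$atom_name[j] %in% BACKBONE_ATOMS) return(FALSE)
    ki <- paste(at$chain_id[i], at$res_seq[i])
    kj <- paste(at$chain_id[j], at$res_seq[j])
    if ((at$atom_name[i] == "SG" && identical(ss_partner[[ki]], kj) &&
         at$atom_name[j] %in% c("SG", "CB")) ||
        (at$atom_name[j] == "SG" && identical(ss_partner[[kj]], ki) &&
         at$atom_name[i] %in% c("SG", "CB"))) return(FALSE)
    TRUE
  }
  for (rw in seq_len(nrow(coords))) {
    here <- cells[[paste(coords$ix[rw], coords$iy[rw], coords$iz[rw])]]
    for (o in seq_len(nrow(offsets))) {
      key <- paste(coords$ix[rw] + offsets$dx[o], coords$iy[rw] + offsets$dy[o],
                   coords$iz[rw] + offsets$dz[o])
      there <- cells[[key]]
      if (is.null(there)) next
      for (i in here) for (j in there) {
        if (j <= i) next
        if (is_clash_pair(i, j)) count <- count + 1L
      }
    }
  }
  count
}

#' Clash z-score for a structure
#'
#' Clash rate per 1000 heavy atoms, standardized against the shipped
#' reference (`rate_mu` 8, `rate_sd` 6 per 1000 atoms). Positive z means
#' more clashes than a typical experimental structure.
#'
#' @inheritParams count_clashes
#' @return list: n_clashes, rate_per_1000, z
#' @export
clash_zscore <- function(structure, tolerance = 0.4) {
  at <- protein_atoms(structure)
  n_atoms <- sum(toupper(at$element) != "H")
  n_cl <- count_clashes(structure, tolerance)
  rate <- 1000 * n_cl / n_atoms
  list(n_clashes = n_cl, rate_per_1000 = rate,
       z = (rate - CLASH_REFERENCE$rate_mu) / CLASH_REFERENCE$rate_sd)
}

#' @noRd
load_contact_potential <- function() {
  path <- system.file("extdata", "contact_potential.tsv",
                      package = "ldlrstruct")
  tab <- utils::read.delim(path, comment.char = "#")
  pot <- array(0, dim = c(4, 4, 3),
               dimnames = list(c("h", "p", "b", "a"), c("h", "p", "b", "a"),
                               c("bin_0_5", "bin_5_6.5", "bin_6.5_8")))
  for (i in seq_len(nrow(tab))) {
    for (b in dimnames(pot)[[3]]) {
      pot[tab$class_a[i], tab$class_b[i], b] <- tab[[make.names(b)]][i]
      pot[tab$class_b[i], tab$class_a[i], b] <- tab[[make.names(b)]][i]
    }
  }
  pot
}

#' @noRd
contact_score <- function(xyz, classes, pot, min_sep = 5L) {
  n <- nrow(xyz)
  score <- 0
  for (i in seq_len(n - min_sep)) {
    js <- (i + min_sep):n
    d <- sqrt((xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
                (xyz[js, 3] - xyz[i, 3])^2)
    bin <- findInterval(d, c(0, 5, 6.5, 8))
    hit <- bin >= 1 & bin <= 3 & d <= 8
    if (any(hit))
      score <- score + sum(pot[cbind(classes[i], classes[js[hit]],
                                     dimnames(pot)[[3]][bin[hit]])])
  }
  score
}

#' Contact-potential ("dope-like") z-score against shuffled decoys
#'
#' The native score sums a shipped log-odds contact potential over
#' Cb-Cb (Ca for glycine) pairs with sequence separation > 4, binned by
#' distance. Decoys shuffle the residue identities on the fixed
#' coordinates; `z = (native - mean(decoys)) / sd(decoys)`, so more
#' negative means a more favorably ordered sequence-structure pairing.
#' Deterministic for a given `seed`. When all decoy scores coincide with
#' the native score the z is 0 by convention.
#'
#' @param structure an `ldlr_structure`
#' @param n_decoys number of shuffled decoys (>= 20)
#' @param seed RNG seed
#' @return list: z, native_score, decoy_mean, decoy_sd, n_decoys
#' @export
potential_zscore <- function(structure, n_decoys = 100, seed = 1) {
  if (n_decoys < 20) stop("n_decoys must be >= 20")
  at <- protein_atoms(structure)
  res <- structure_residues(structure)
  pick <- function(i) {
    nm <- if (res$res_name[i] == "GLY") "CA" else "CB"
    hit <- at[at$chain_id == res$chain_id[i] & at$res_seq == res$res_seq[i] &
                at$atom_name == nm, , drop = FALSE]
    if (!nrow(hit))
      hit <- at[at$chain_id == res$chain_id[i] &
                  at$res_seq == res$res_seq[i] & at$atom_name == "CA", ,
                drop = FALSE]
    if (nrow(hit)) as.numeric(hit[1, c("x", "y", "z")]) else rep(NA_real_, 3)
  }
  xyz <- t(vapply(seq_len(nrow(res)), pick, numeric(3)))
  ok <- stats::complete.cases(xyz)
  xyz <- xyz[ok, , drop = FALSE]
  classes <- RESIDUE_CLASS[res$aa[ok]]
  if (nrow(xyz) <= 5)
    stop("structure too small: no residue pair beyond sequence separation 4")
  pot <- load_contact_potential()
  native <- contact_score(xyz, classes, pot)
  set.seed(seed)
  decoys <- vapply(seq_len(n_decoys), function(k)
    contact_score(xyz, sample(classes), pot), numeric(1))
  mu <- mean(decoys); sdv <- stats::sd(decoys)
  z <- if (sdv < 1e-12) {
    if (abs(native - mu) < 1e-9) 0 else sign(native - mu) * Inf
  } else (native - mu) / sdv
  list(z = z, native_score = native, decoy_mean = mu, decoy_sd = sdv,
       n_decoys = n_decoys)
}

#' Full model-quality report for one structure
#'
#' @param structure an `ldlr_structure`
#' @param n_decoys,seed passed to [potential_zscore()]
#' @return list of class `ldlr_quality`: rama_core_fraction,
#'   rama_allowed_fraction, rama_outlier_z, hbond_fraction, clash_z,
#'   potential_z, plus the underlying detail lists
#' @export
quality_report <- function(structure, n_decoys = 100, seed = 1) {
  rama <- ramachandran_stats(structure)
  hb <- hbond_fraction(structure)
  cl <- clash_zscore(structure)
  pz <- potential_zscore(structure, n_decoys = n_decoys, seed = seed)
  structure(list(id = structure$id, condition = structure$condition_label,
                 rama_core_fraction = rama$core_fraction,
                 rama_allowed_fraction = rama$allowed_fraction,
                 rama_outlier_z = rama$outlier_z,
                 hbond_fraction = hb,
                 clash_z = cl$z, potential_z = pz$z,
                 detail = list(rama = rama, clash = cl, potential = pz)),
            class = "ldlr_quality")
}
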