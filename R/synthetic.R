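# synthetic_data: generators for every input the pipeline consumes —
# class-A-like mini-domain structures with planted disulfide and calcium
# geometry, ideal-dihedral helix fixtures, coordinate perturbation for
# decoys, MSAs with planted conserved columns, and variant/ddG tables with
# planted clinical classes, role flags and condition differences. Every
# generator is a pure function of its arguments and seed, and every
# planted feature is written to a machine-readable truth object.

IDEAL_GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                   b_c_o = 1.231, b_ca_cb = 1.530, b_s_s = 2.05,
                   b_ca_o_ion = 2.4,
                   a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
                   a_ca_c_o = 120.5)

#' @noRd
atom_row <- function(atom_name, element, res_seq, res_name, xyz,
                     record = "ATOM", chain = "A") {
  data.frame(record = record, atom_name = atom_name, element = element,
             chain_id = chain, res_name = res_name,
             res_seq = as.integer(res_seq), ins_code = "",
             x = xyz[1], y = xyz[2], z = xyz[3],
             occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
}

#' Build an ideal-geometry backbone from dihedral angles
#'
#' Natural-extension chain construction with ideal bond lengths and angles
#' (N-Ca 1.458, Ca-C 1.525, C-N 1.329 angstrom). Residue i takes phi\[i\]
#' and psi\[i\]; omega is trans throughout. Carbonyl oxygens and (optionally)
#' Cb atoms are added with ideal geometry.
#'
#' @param n number of residues
#' @param phi,psi dihedral vectors (degrees), recycled to length `n`
#' @param with_cb add Cb atoms
#' @return list of per-residue coordinate lists (N, CA, C, O, CB)
#' @export
build_ideal_backbone <- function(n, phi = -57, psi = -47, with_cb = TRUE) {
  g <- IDEAL_GEOM
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  C <- place_atom(c(0, 0, 1), N, CA, g$b_ca_c, g$a_n_ca_c, 0)
  for (i in seq_len(n)) {
    O <- place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, psi[i] + 180)
    res[[i]] <- list(N = N, CA = CA, C = C, O = O)
    if (with_cb)
      res[[i]]$CB <- place_atom(C, N, CA, g$b_ca_cb, 110.5, -122.5)
    if (i < n) {
      N2 <- place_atom(N, CA, C, g$b_c_n, g$a_ca_c_n, psi[i])
      CA2 <- place_atom(CA, C, N2, g$b_n_ca, g$a_c_n_ca, 180)
      C2 <- place_atom(C, N2, CA2, g$b_ca_c, g$a_n_ca_c, phi[i + 1])
      N <- N2; CA <- CA2; C <- C2
    }
  }
  res
}

#' Ideal secondary-structure fixture
#'
#' A single chain with uniform dihedrals: the default is a canonical
#' alpha-helix (phi -57, psi -47); pass e.g. phi -139 / psi 135 for an
#' extended strand. Used by the quality-metric limit tests.
#'
#' @param n residues
#' @param phi,psi uniform dihedrals (degrees)
#' @param sequence one-letter sequence (default all-Ala)
#' @param id structure id
#' @return an `ldlr_structure`
#' @export
build_helix_structure <- function(n = 20, phi = -57, psi = -47,
                                  sequence = NULL, id = "helix") {
  if (is.null(sequence)) sequence <- strrep("A", n)
  aa <- strsplit(sequence, "")[[1]]
  stopifnot(length(aa) == n)
  bb <- build_ideal_backbone(n, phi, psi, with_cb = TRUE)
  rows <- list()
  for (i in seq_len(n)) {
    rn <- aa1_to_3(aa[i])
    rows[[length(rows) + 1]] <- atom_row("N", "N", i, rn, bb[[i]]$N)
    rows[[length(rows) + 1]] <- atom_row("CA", "C", i, rn, bb[[i]]$CA)
    rows[[length(rows) + 1]] <- atom_row("C", "C", i, rn, bb[[i]]$C)
    rows[[length(rows) + 1]] <- atom_row("O", "O", i, rn, bb[[i]]$O)
    if (aa[i] != "G")
      rows[[length(rows) + 1]] <- atom_row("CB", "C", i, rn, bb[[i]]$CB)
  }
  new_structure(id, do.call(rbind, rows), condition_label = "synthetic")
}

#' @noRd
align_to_x <- function(coords_list) {
  # rotate a residue list so the first->last CA vector lies on +x, first CA
  # at the origin
  cas <- t(vapply(coords_list, `[[`, numeric(3), "CA"))
  origin <- cas[1, ]
  u <- unit(cas[nrow(cas), ] - origin)
  target <- c(1, 0, 0)
  v <- cross3(u, target); s <- vnorm(v); cmat <- sum(u * target)
  R <- if (s < 1e-9) diag(3) * sign(cmat) else {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    diag(3) + vx + vx %*% vx * ((1 - cmat) / s^2)
  }
  lapply(coords_list, function(r) lapply(r, function(p) as.numeric(R %*% (p - origin))))
}

#' @noRd
shift_residues <- function(coords_list, f) lapply(coords_list, function(r) lapply(r, f))

#' Build a class-A-like synthetic mini-domain with planted geometry
#'
#' A 40-residue (default) hairpin of two antiparallel ideal helices joined
#' by a short schematic loop, with three planted disulfide bonds
#' (Sg-Sg = 2.05 angstrom exactly), one calcium ion coordinated by four
#' aspartate side-chain oxygens and two backbone carbonyls at 2.4 angstrom
#' exactly, and hydrophobic residues facing the helix-helix interface
#' (lower accessibility than outward-facing residues). Side chains are
#' schematic: Cb plus the functionally required terminal atom (Sg for Cys,
#' Od1 for Asp). Deterministic given `seed`; the sequence at unconstrained
#' positions is seeded random.
#'
#' @param n_residues chain length (default 40; minimum 24)
#' @param disulfide_pairs list of position pairs to crosslink; the defaults
#'   pair interface-facing positions of the two helices
#' @param ca_sidechain positions becoming Asp side-chain coordinators
#' @param ca_backbone positions contributing backbone carbonyl oxygens
#' @param core_positions interface-facing hydrophobic positions (defaults
#'   chosen on the inward-facing helical phase of the default layout)
#' @param seed RNG seed
#' @return list: `structure` (an `ldlr_structure`) and `truth` (planted
#'   disulfide pairs, calcium coordinators, core positions, sequence)
#' @export
build_minidomain <- function(n_residues = 40,
                             disulfide_pairs = list(c(4, 36), c(7, 33), c(11, 29)),
                             ca_sidechain = c(17, 19, 21, 24),
                             ca_backbone = c(20, 22),
                             core_positions = c(3, 14, 18, 23, 25, 26),
                             seed = 1) {
  if (n_residues < 24) stop("mini-domain needs >= 24 residues")
  ss_pos <- unlist(disulfide_pairs)
  if (anyDuplicated(ss_pos)) stop("disulfide pairs must be disjoint")
  special <- c(ss_pos, ca_sidechain, ca_backbone, core_positions)
  if (any(special < 1 | special > n_residues))
    stop("planted positions outside 1..n_residues")
  if (anyDuplicated(c(ss_pos, ca_sidechain, core_positions)))
    stop("planted roles must not overlap")

  len_a <- (n_residues - 4) %/% 2
  len_b <- n_residues - 4 - len_a
  helix_a <- align_to_x(build_ideal_backbone(len_a))
  helix_b <- align_to_x(build_ideal_backbone(len_b))
  span_a <- helix_a[[len_a]]$CA[1]
  d_sep <- 11
  flip <- function(p) c(-p[1], -p[2], p[3])
  helix_b <- shift_residues(helix_b, function(p) {
    q <- flip(p); q + c(span_a, d_sep, 0)
  })

  # schematic loop bridging helix A's C-terminus and helix B's N-terminus,
  # arcing up and away from both helix ends
  p_start <- helix_a[[len_a]]$C
  p_end <- helix_b[[1]]$N
  loop <- vector("list", 4)
  for (k in 1:4) {
    t <- k / 5
    centre <- (1 - t) * p_start + t * p_end +
      c(4.5 * sin(pi * t), 0, 3.0 * sin(pi * t))
    dirv <- unit(p_end - p_start)
    loop[[k]] <- list(N = centre - 0.6 * dirv, CA = centre,
                      C = centre + 0.6 * dirv, O = centre + c(0, 0, 1.23))
  }
  backbone <- c(helix_a, loop, helix_b)

  # side chains stick out radially from each helix axis with a small tilt
  # toward the N-terminus, as in a real helix; loop residues stay Cb-less
  radial_cb <- function(idx_range, nterm_x) {
    cas <- t(vapply(backbone[idx_range], `[[`, numeric(3), "CA"))
    centroid <- colMeans(cas)
    for (i in idx_range) {
      v <- backbone[[i]]$CA - centroid
      v[1] <- 0
      dir_cb <- unit(unit(v) + c(0.35 * nterm_x, 0, 0))
      backbone[[i]]$CB <<- backbone[[i]]$CA + IDEAL_GEOM$b_ca_cb * dir_cb
    }
  }
  radial_cb(seq_len(len_a), -1)
  radial_cb((len_a + 5):n_residues, 1)

  # sequence assignment
  set.seed(seed)
  aa <- rep(NA_character_, n_residues)
  aa[ss_pos] <- "C"
  aa[ca_sidechain] <- "D"
  aa[core_positions] <- sample(c("L", "I", "V", "F"), length(core_positions),
                               replace = TRUE)
  loop_idx <- (len_a + 1):(len_a + 4)
  filler <- setdiff(seq_len(n_residues), c(ss_pos, ca_sidechain, core_positions))
  aa[intersect(filler, loop_idx)] <- "G"
  filler <- setdiff(filler, loop_idx)
  aa[filler] <- sample(c("A", "S", "T", "N", "Q", "E", "K"), length(filler),
                       replace = TRUE)

  # planted disulfides: Sg pair centred between the two Cb atoms
  sg <- list()
  for (pair in disulfide_pairs) {
    cb1 <- backbone[[pair[1]]]$CB %||% backbone[[pair[1]]]$CA
    cb2 <- backbone[[pair[2]]]$CB %||% backbone[[pair[2]]]$CA
    mid <- (cb1 + cb2) / 2
    axis <- unit(cb2 - cb1)
    sg[[as.character(pair[1])]] <- mid - axis * IDEAL_GEOM$b_s_s / 2
    sg[[as.character(pair[2])]] <- mid + axis * IDEAL_GEOM$b_s_s / 2
  }

  # calcium site: ion above the loop, planted oxygens at exactly 2.4 A
  loop_centre <- Reduce(`+`, lapply(backbone[loop_idx], `[[`, "CA")) / 4
  ion <- loop_centre + c(4, 0, 8)
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  od1 <- list()
  for (k in seq_along(ca_sidechain))
    od1[[as.character(ca_sidechain[k])]] <-
      ion + oct[k, ] * IDEAL_GEOM$b_ca_o_ion
  for (k in seq_along(ca_backbone))
    backbone[[ca_backbone[k]]]$O <-
      ion + oct[length(ca_sidechain) + k, ] * IDEAL_GEOM$b_ca_o_ion

  rows <- list()
  for (i in seq_len(n_residues)) {
    rn <- aa1_to_3(aa[i])
    bb <- backbone[[i]]
    rows[[length(rows) + 1]] <- atom_row("N", "N", i, rn, bb$N)
    rows[[length(rows) + 1]] <- atom_row("CA", "C", i, rn, bb$CA)
    rows[[length(rows) + 1]] <- atom_row("C", "C", i, rn, bb$C)
    rows[[length(rows) + 1]] <- atom_row("O", "O", i, rn, bb$O)
    if (aa[i] != "G" && !is.null(bb$CB))
      rows[[length(rows) + 1]] <- atom_row("CB", "C", i, rn, bb$CB)
    if (!is.null(sg[[as.character(i)]]))
      rows[[length(rows) + 1]] <- atom_row("SG", "S", i, rn, sg[[as.character(i)]])
    if (!is.null(od1[[as.character(i)]]))
      rows[[length(rows) + 1]] <- atom_row("OD1", "O", i, rn,
                                           od1[[as.character(i)]])
  }
  rows[[length(rows) + 1]] <- atom_row("CA", "CA", n_residues + 1, "CA", ion,
                                       record = "HETATM")
  st <- new_structure("minidomain", do.call(rbind, rows),
                      condition_label = "synthetic")
  truth <- list(disulfide_pairs = disulfide_pairs,
                ca_sidechain = ca_sidechain, ca_backbone = ca_backbone,
                n_ca_oxygens = length(ca_sidechain) + length(ca_backbone),
                core_positions = core_positions,
                sequence = paste(aa, collapse = ""))
  list(structure = st, truth = truth)
}

#' Add seeded Gaussian coordinate noise to a structure
#'
#' @param structure an `ldlr_structure`
#' @param magnitude noise standard deviation per coordinate (angstrom)
#' @param seed RNG seed
#' @return the perturbed `ldlr_structure`
#' @export
perturb_structure <- function(structure, magnitude, seed = 1) {
  stopifnot(magnitude >= 0)
  if (magnitude == 0) return(structure)
  set.seed(seed)
  n <- nrow(structure$atoms)
  structure$atoms$x <- structure$atoms$x + stats::rnorm(n, 0, magnitude)
  structure$atoms$y <- structure$atoms$y + stats::rnorm(n, 0, magnitude)
  structure$atoms$z <- structure$atoms$z + stats::rnorm(n, 0, magnitude)
  structure
}

#' Synthetic MSA with planted conserved columns
#'
#' Planted columns are invariant (one seeded letter down the whole
#' alignment); background columns are drawn uniformly from a six-letter
#' alphabet, so their per-column entropy sits far from zero once a few
#' dozen rows are present. Row 1 is the reference and is never gapped.
#'
#' @param n_rows,n_cols alignment dimensions
#' @param conserved_columns integer positions to plant
#' @param seed RNG seed
#' @return list: `msa` (character vector of rows) and `truth`
#'   (conserved_columns)
#' @export
synth_msa <- function(n_rows = 50, n_cols = 40,
                      conserved_columns = seq(4, 40, by = 4), seed = 1) {
  if (length(conserved_columns) &&
      any(conserved_columns < 1 | conserved_columns > n_cols))
    stop("conserved_columns outside 1..n_cols")
  set.seed(seed)
  background <- c("A", "S", "T", "N", "Q", "E")
  m <- matrix(sample(background, n_rows * n_cols, replace = TRUE),
              n_rows, n_cols)
  for (col in conserved_columns)
    m[, col] <- sample(AA1, 1)
  msa <- apply(m, 1, paste, collapse = "")
  names(msa) <- c("ref", paste0("homolog", seq_len(n_rows - 1)))[seq_len(n_rows)]
  list(msa = msa, truth = list(conserved_columns = sort(conserved_columns)))
}

#' @noRd
exact_counts <- function(n, fractions) {
  # integer counts summing to n, proportional to fractions (largest
  # remainder via cumulative rounding)
  diff(c(0L, round(cumsum(fractions) * n)))
}

#' @noRd
rtrunc_norm <- function(n, mean, sd, lim) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[abs(x) <= lim])
  }
  out[seq_len(n)]
}

#' Synthetic variant and ddG tables with planted truth
#'
#' Generates unique missense protein changes at positions inside the
#' class-A entries of `map`, with planted clinical classes (realized via
#' source records that harmonize to the intended class), planted
#' structural-role flags, per-condition ddG values drawn from
#' class-specific distributions, and condition differences planted firmly
#' inside the gray / orange / red bands so category recovery is exact.
#'
#' Default ddG distributions: pathogenic shifted normal (+2.5, sd 1.5);
#' benign normal (0, 0.3) truncated to |ddg| <= 0.6 (never past the
#' significance threshold); VUS an equal mixture of the two.
#'
#' @param map an `ldlr_domain_map`
#' @param n_variants number of unique variants
#' @param class_fractions named fractions (pathogenic, benign, vus) summing
#'   to 1
#' @param delta_fractions named fractions (gray, orange, red) summing to 1
#' @param role_fractions named fractions of variants carrying each planted
#'   flag (conserved, disulfide, ca); these may overlap
#' @param seed RNG seed
#' @return list: `records` (long source-record table with some duplicated
#'   rows, columns source, raw_class, ref_aa, position, alt_aa, hgvs_p),
#'   `ddg` (per-variant ddg_extracellular / ddg_endosomal), `truth`
#'   (per-variant planted class, flags, delta category)
#' @export
synth_variant_table <- function(map, n_variants = 400,
                                class_fractions = c(pathogenic = 0.3,
                                                    benign = 0.2, vus = 0.5),
                                delta_fractions = c(gray = 0.56,
                                                    orange = 0.14, red = 0.30),
                                role_fractions = c(conserved = 0.35,
                                                   disulfide = 0.15, ca = 0.12),
                                seed = 1) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-9,
            abs(sum(delta_fractions) - 1) < 1e-9)
  spans <- map[map$class == "classA", , drop = FALSE]
  if (!nrow(spans)) stop("map has no classA entries")
  positions <- unlist(Map(seq, spans$start, spans$end))
  if (n_variants > length(positions) * 19)
    stop("n_variants exceeds available position x substitution space")
  set.seed(seed)
  ref_by_pos <- stats::setNames(sample(AA1, length(positions), replace = TRUE),
                                positions)
  pool_pos <- sample(rep(positions, length.out = max(n_variants * 2,
                                                     length(positions))))
  chosen <- data.frame(position = integer(), alt_aa = character(),
                       stringsAsFactors = FALSE)
  taken <- character(0)
  for (p in pool_pos) {
    if (nrow(chosen) >= n_variants) break
    alt <- sample(setdiff(AA1, ref_by_pos[as.character(p)]), 1)
    key <- paste(p, alt)
    if (key %in% taken) next
    taken <- c(taken, key)
    chosen <- rbind(chosen, data.frame(position = p, alt_aa = alt,
                                       stringsAsFactors = FALSE))
  }
  if (nrow(chosen) < n_variants)
    stop("could not draw enough unique variants; increase map size")
  chosen$ref_aa <- ref_by_pos[as.character(chosen$position)]

  cls <- sample(rep(names(class_fractions),
                    exact_counts(n_variants, class_fractions)))
  cat_delta <- sample(rep(names(delta_fractions),
                          exact_counts(n_variants, delta_fractions)))

  ddg_extra <- numeric(n_variants)
  ddg_extra[cls == "pathogenic"] <- stats::rnorm(sum(cls == "pathogenic"), 2.5, 1.5)
  ddg_extra[cls == "benign"] <- rtrunc_norm(sum(cls == "benign"), 0, 0.3, 0.6)
  n_vus <- sum(cls == "vus")
  mix <- stats::runif(n_vus) < 0.5
  vus_vals <- numeric(n_vus)
  vus_vals[mix] <- stats::rnorm(sum(mix), 2.5, 1.5)
  vus_vals[!mix] <- rtrunc_norm(sum(!mix), 0, 0.3, 0.6)
  ddg_extra[cls == "vus"] <- vus_vals

  delta <- numeric(n_variants)
  delta[cat_delta == "gray"] <- stats::runif(sum(cat_delta == "gray"), 0, 1.5)
  delta[cat_delta == "orange"] <- stats::runif(sum(cat_delta == "orange"), 1.9, 2.9)
  delta[cat_delta == "red"] <- stats::runif(sum(cat_delta == "red"), 3.2, 6.0)
  sign_flip <- sample(c(-1, 1), n_variants, replace = TRUE)
  ddg_endo <- ddg_extra - sign_flip * delta

  flags <- sapply(names(role_fractions), function(r)
    sample(c(rep(TRUE, round(role_fractions[[r]] * n_variants)),
             rep(FALSE, n_variants - round(role_fractions[[r]] * n_variants)))))
  colnames(flags) <- c("at_conserved", "alters_disulfide", "alters_ca_site")

  hgvs <- sprintf("p.%s%d%s", chosen$ref_aa, chosen$position, chosen$alt_aa)
  truth <- data.frame(chosen[, c("ref_aa", "position", "alt_aa")],
                      hgvs_p = hgvs, clinical_class = cls,
                      ddg_extracellular = ddg_extra, ddg_endosomal = ddg_endo,
                      delta_category = cat_delta, flags,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$position, truth$alt_aa), , drop = FALSE]
  rownames(truth) <- NULL

  one_record <- function(i) {
    cc <- truth$clinical_class[i]
    src <- switch(cc,
                  pathogenic = sample(list(c("clinvar", "Pathogenic"),
                                           c("clinvar", "Likely pathogenic"),
                                           c("hgmd", "DM"),
                                           c("lovd", "ACGS class 5")), 1)[[1]],
                  benign = sample(list(c("clinvar", "Benign"),
                                       c("clinvar", "Likely benign"),
                                       c("lovd", "ACGS class 1")), 1)[[1]],
                  vus = sample(list(c("clinvar", "Uncertain significance"),
                                    c("population", "")), 1)[[1]])
    data.frame(source = src[1], raw_class = src[2],
               ref_aa = truth$ref_aa[i], position = truth$position[i],
               alt_aa = truth$alt_aa[i], hgvs_p = truth$hgvs_p[i],
               stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, lapply(seq_len(nrow(truth)), one_record))
  # duplicate a seeded subset across a second source to exercise dedup
  dup_idx <- sample(nrow(records), max(1, nrow(records) %/% 10))
  dups <- records[dup_idx, , drop = FALSE]
  dups$source <- "population"; dups$raw_class <- ""
  records <- rbind(records, dups)
  records <- records[sample(nrow(records)), , drop = FALSE]
  rownames(records) <- NULL

  ddg <- data.frame(variant = truth$hgvs_p,
                    ddg_extracellular = truth$ddg_extracellular,
                    ddg_endosomal = truth$ddg_endosomal,
                    stringsAsFactors = FALSE)
  list(records = records, ddg = ddg, truth = truth)
}

#' Write a complete synthetic fixture directory
#'
#' Produces every file the pipeline reads: `mini.pdb`, `domains.tsv`,
#' `msa.fasta`, `variants.tsv`, `ddg.tsv`, `glyco.txt` and `truth.json`.
#' All content is synthetic and deterministic given `seed`.
#'
#' @param dir output directory (created if needed)
#' @param seed RNG seed
#' @param n_variants variants in the planted table
#' @return list of generated objects, invisibly
#' @export
write_fixture_dir <- function(dir, seed = 1, n_variants = 400) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mini <- build_minidomain(seed = seed)
  write_structure(mini$structure, file.path(dir, "mini.pdb"))
  map <- synthetic_domain_map()
  utils::write.table(as.data.frame(map), file.path(dir, "domains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  msa <- synth_msa(seed = seed)
  write_alignment_fasta(msa$msa, file.path(dir, "msa.fasta"))
  tab <- synth_variant_table(map, n_variants = n_variants, seed = seed)
  utils::write.table(data.frame(source = tab$records$source,
                                classification = tab$records$raw_class,
                                hgvs_p = tab$records$hgvs_p),
                     file.path(dir, "variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tab$ddg, file.path(dir, "ddg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  glyco <- seq(5, 35, by = 10)
  writeLines(as.character(glyco), file.path(dir, "glyco.txt"))
  truth <- list(minidomain = mini$truth, msa = msa$truth,
                variants = tab$truth, glyco_sites = glyco)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(minidomain = mini, map = map, msa = msa, variants = tab,
                 glyco = glyco))
}

#' Synthetic seven-repeat domain map
#'
#' A map with the architecture of the LDLR ligand-binding region — seven
#' ~40-residue class-A repeats with short linkers, then EGF-like domains —
#' in synthetic coordinates. Used by generators and tests; not a claim
#' about the real receptor (see `extdata/ldlr_domains.tsv` for the
#' UniProt-derived map).
#'
#' @param numbering_offset signal-peptide length (default 21)
#' @return an `ldlr_domain_map`
#' @export
synthetic_domain_map <- function(numbering_offset = 21L) {
  starts <- 25 + (0:6) * 42
  entries <- data.frame(domain_name = paste0("LA", 1:7), class = "classA",
                        start = starts, end = starts + 39,
                        stringsAsFactors = FALSE)
  egf <- data.frame(domain_name = c("EGF1", "EGF2"), class = "EGF",
                    start = c(320, 360), end = c(358, 398),
                    stringsAsFactors = FALSE)
  domain_map(rbind(entries, egf), numbering_offset = numbering_offset)
}
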