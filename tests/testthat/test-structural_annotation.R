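test_that("planted disulfides are detected exactly and geometry rules hold", {
  md <- build_minidomain(seed = 3)
  ss <- detect_disulfides(md$structure)
  got <- sort(apply(cbind(pmin(ss$pos_a, ss$pos_b),
                          pmax(ss$pos_a, ss$pos_b)), 1, paste, collapse = "-"))
  want <- sort(vapply(md$truth$disulfide_pairs,
                      function(p) paste(sort(p), collapse = "-"), character(1)))
  expect_equal(got, want)
  expect_true(all(ss$distance <= 2.5))

  # two cysteines 6 angstrom apart: no bond
  far <- make_cys_structure(rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_equal(nrow(detect_disulfides(far)), 0L)

  # three mutually close cysteines: greedy keeps the single closest pair
  tri <- make_cys_structure(rbind(c(0, 0, 0), c(2.0, 0, 0), c(0, 2.2, 0)))
  bonds <- detect_disulfides(tri)
  expect_equal(nrow(bonds), 1L)
  expect_equal(sort(c(bonds$pos_a, bonds$pos_b)), c(1L, 2L))
})

test_that("disulfide detection is invariant to rigid-body transforms", {
  md <- build_minidomain(seed = 2)
  R <- ldlrstruct:::random_rotation(99)
  st2 <- transform_structure(md$structure, R, c(12, -8, 4))
  ss1 <- detect_disulfides(md$structure)
  ss2 <- detect_disulfides(st2)
  expect_equal(ss1[, c("pos_a", "pos_b")], ss2[, c("pos_a", "pos_b")])
  expect_equal(ss1$distance, ss2$distance, tolerance = 1e-9)
})

test_that("calcium sites list the planted coordinating oxygens", {
  md <- build_minidomain(seed = 1)
  sites <- detect_ca_sites(md$structure)
  expect_length(sites, 1L)
  atoms <- sites[[1]]$atoms
  expect_equal(nrow(atoms), md$truth$n_ca_oxygens)
  expect_setequal(atoms$res_seq[atoms$sidechain], md$truth$ca_sidechain)
  expect_setequal(atoms$res_seq[!atoms$sidechain], md$truth$ca_backbone)
  expect_equal(atoms$distance, rep(2.4, nrow(atoms)), tolerance = 1e-6)

  # degenerate cutoff finds nothing
  expect_warning(empty <- detect_ca_sites(md$structure, cutoff = 0),
                 "coordinating")
  expect_equal(nrow(empty[[1]]$atoms), 0L)

  # ion far from all oxygens: zero coordinators with a warning
  lone <- md$structure
  ion_row <- which(lone$atoms$is_hetero)
  lone$atoms$x[ion_row] <- lone$atoms$x[ion_row] + 50
  expect_warning(s2 <- detect_ca_sites(lone), "only 0")
  expect_equal(nrow(s2[[1]]$atoms), 0L)

  # no ions at all: empty list, not an error
  noion <- md$structure
  noion$atoms <- noion$atoms[!noion$atoms$is_hetero, ]
  expect_equal(detect_ca_sites(noion), list())
})

test_that("relative accessibility has the exposure limits and matches dense sampling", {
  gly <- make_free_glycine()
  rsa <- relative_accessibility(gly)
  expect_gt(rsa$rsa, 0.9)  # an isolated residue is fully exposed

  cage <- make_cage_structure()
  rsa_cage <- relative_accessibility(cage)
  enclosed <- rsa_cage$rsa[rsa_cage$res_seq == 1]
  expect_lt(enclosed, 0.05)

  # dense independent sampling agrees on the enclosed residue's area
  oracle_area <- oracle_residue_sasa(cage, 1, n_points = 10000)
  package_area <- rsa_cage$sasa[rsa_cage$res_seq == 1]
  expect_equal(package_area, oracle_area, tolerance = max(1, 0.15 * oracle_area))

  # adding occluders can only reduce accessibility
  md <- build_minidomain(seed = 1)
  base <- relative_accessibility(md$structure)
  fewer <- md$structure
  fewer$atoms <- fewer$atoms[fewer$atoms$res_seq <= 20 | fewer$atoms$is_hetero, ]
  sparse <- relative_accessibility(fewer)
  shared <- sparse$res_seq
  expect_true(all(sparse$sasa + 1e-9 >=
                    base$sasa[match(shared, base$res_seq)]))

  # decomposition is additive: residue areas sum to the structure total
  expect_equal(sum(base$sasa),
               sum(ldlrstruct:::sasa_atoms(
                 as.matrix(md$structure$atoms[!md$structure$atoms$is_hetero &
                                                toupper(md$structure$atoms$element) != "H",
                                              c("x", "y", "z")]),
                 ldlrstruct:::vdw_radius(
                   md$structure$atoms$element[!md$structure$atoms$is_hetero]))),
               tolerance = 0.01)
  expect_true(all(base$rsa >= 0 & base$rsa <= 1))
})

test_that("interface-facing hydrophobic positions are more buried", {
  md <- build_minidomain(seed = 1)
  rsa <- relative_accessibility(md$structure)
  core <- md$truth$core_positions
  expect_lt(mean(rsa$rsa[rsa$res_seq %in% core]),
            mean(rsa$rsa[!rsa$res_seq %in% core]))
})

test_that("residue annotations merge all roles and respect the glyco window", {
  md <- build_minidomain(seed = 1)
  m <- synth_msa(n_rows = 30, n_cols = 40, conserved_columns = c(4, 7, 11),
                 seed = 4)
  pr <- conservation_profile(m$msa)
  ann <- annotate_residues(md$structure, profile = pr,
                           glyco_sites = c(10L), window = 5L)
  expect_equal(nrow(ann), 40L)
  # window boundary: |pos - site| == window is near, window + 1 is not
  expect_true(ann$near_glyco[ann$position == 15])
  expect_false(ann$near_glyco[ann$position == 16])
  expect_true(ann$glyco_site[ann$position == 10])
  expect_true(all(ann$near_glyco[ann$glyco_site]))
  # core flag consistent with rsa threshold
  expect_true(all(ann$rsa[ann$is_core] <= 0.15))
  # out-of-range site warns and is ignored
  expect_warning(annotate_residues(md$structure, glyco_sites = c(900L)),
                 "outside")

  # field-by-field oracle recomputation
  ss <- detect_disulfides(md$structure)
  expect_setequal(ann$position[ann$in_disulfide],
                  unique(c(ss$pos_a, ss$pos_b)))
  expect_setequal(ann$position[ann$ca_sidechain], md$truth$ca_sidechain)
  expect_setequal(ann$position[ann$ca_backbone], md$truth$ca_backbone)
  expect_equal(ann$conservation_z,
               pr$profile$score_z[match(ann$position, pr$profile$position)])
})

test_that("variant role flags implement the substitution rules", {
  md <- build_minidomain(seed = 1)
  ann <- annotate_residues(md$structure)
  seqv <- strsplit(md$truth$sequence, "")[[1]]
  cys <- md$truth$disulfide_pairs[[1]][1]
  d_sc <- md$truth$ca_sidechain[1]
  g_bb <- md$truth$ca_backbone[1]   # glycine contributing a backbone oxygen

  v <- data.frame(ref_aa = c(seqv[cys], seqv[d_sc], seqv[g_bb], seqv[g_bb]),
                  position = c(cys, d_sc, g_bb, g_bb),
                  alt_aa = c("R", "K", "A", "S"),
                  stringsAsFactors = FALSE)
  fl <- variant_role_flags(v, ann)
  expect_true(fl$alters_disulfide[1])      # bonded Cys lost
  expect_true(fl$alters_ca_site[2])        # side-chain coordinator
  # backbone-only coordination: Gly substitution changes backbone geometry
  expect_true(fl$alters_ca_site[3])
  expect_true(fl$alters_ca_site[4])
  expect_equal(fl$in_any_class,
               fl$at_conserved | fl$alters_disulfide | fl$alters_ca_site)

  # backbone-only coordination without Pro/Gly involvement does not flag
  ann_mod <- ann
  ann_mod$ca_backbone[ann_mod$position == d_sc] <- TRUE
  ann_mod$ca_sidechain[ann_mod$position == d_sc] <- FALSE
  v2 <- data.frame(ref_aa = seqv[d_sc], position = d_sc, alt_aa = "E",
                   stringsAsFactors = FALSE)
  expect_false(variant_role_flags(v2, ann_mod)$alters_ca_site)

  # unannotated position: all flags false, with a warning
  v3 <- data.frame(ref_aa = "A", position = 999L, alt_aa = "V")
  expect_warning(fl3 <- variant_role_flags(v3, ann), "without annotation")
  expect_false(any(unlist(fl3[, c("alters_disulfide", "alters_ca_site",
                                  "at_conserved", "in_any_class")])))
})
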