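test_that("Spearman correlation matches the manual rank-then-Pearson oracle", {
  expect_equal(spearman_rho(1:4, 1:4), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1)
  set.seed(31)
  for (k in 1:5) {
    x <- rnorm(20); y <- 0.4 * x + rnorm(20)
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
    # with ties
    xt <- round(x); yt <- round(y)
    if (sd(xt) > 0 && sd(yt) > 0)
      expect_equal(spearman_rho(xt, yt), oracle_spearman(xt, yt),
                   tolerance = 1e-12)
  }
  x <- rnorm(10)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, -x), -1)
  expect_error(spearman_rho(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_rho(1:3, 1:4), "length")
})

test_that("rank-sum statistics match the brute-force pair count", {
  set.seed(41)
  for (k in 1:6) {
    x <- rnorm(sample(4:12, 1)); y <- rnorm(sample(4:12, 1))
    v <- data.frame(clinical_class = c(rep("pathogenic", length(x)),
                                       rep("benign", length(y))),
                    ddg_extracellular = c(x, y), grp = "all")
    cmp <- ddg_distribution_compare(v, group_column = "grp")
    row <- cmp[cmp$class_a == "pathogenic" & cmp$class_b == "benign", ]
    expect_equal(row$statistic, oracle_rank_sum_W(x, y))
  }
})

test_that("rank-sum comparisons detect a planted shift and not a null", {
  set.seed(8)
  null_v <- data.frame(
    clinical_class = rep(c("pathogenic", "benign"), each = 40),
    ddg_extracellular = rnorm(80), grp = "all")
  p_null <- ddg_distribution_compare(null_v, group_column = "grp")
  row <- p_null[p_null$class_b == "benign" & p_null$class_a == "pathogenic", ]
  expect_gt(row$p_value, 0.01)

  shift_v <- data.frame(
    clinical_class = rep(c("pathogenic", "benign"), each = 50),
    ddg_extracellular = c(rnorm(50) + 3, rnorm(50)), grp = "all")
  p_shift <- ddg_distribution_compare(shift_v, group_column = "grp")
  row2 <- p_shift[p_shift$class_b == "benign" & p_shift$class_a == "pathogenic", ]
  expect_lt(row2$p_value, 0.001)
  expect_gt(row2$frac_exceed_a, row2$frac_exceed_b)
})

test_that("class counts recover planted truth and satisfy the union bound", {
  map <- synthetic_domain_map()
  tab <- synth_variant_table(map, n_variants = 250, seed = 12)
  tr <- tab$truth
  tr$domain_class <- "classA"
  cc <- class_counts(tr, domain_filter = "classA")
  expect_equal(cc$n_total, 250L)
  expect_equal(cc$n_conserved, sum(tr$at_conserved))
  expect_equal(cc$n_disulfide, sum(tr$alters_disulfide))
  expect_equal(cc$n_ca, sum(tr$alters_ca_site))
  expect_lte(cc$n_union, cc$n_conserved + cc$n_disulfide + cc$n_ca)
  expect_lte(cc$n_union, cc$n_total)
  expect_equal(sum(unlist(cc$n_by_clinical)), cc$n_total)
  expect_equal(sum(unlist(cc$n_delta)), cc$n_total)

  # empty input and full-overlap corner cases
  empty <- class_counts(tr[0, , drop = FALSE])
  expect_equal(empty$n_total, 0L)
  expect_equal(empty$n_union, 0L)
  one <- tr[1, , drop = FALSE]
  one$at_conserved <- one$alters_disulfide <- one$alters_ca_site <- TRUE
  cc1 <- class_counts(one)
  expect_equal(cc1$n_union, 1L)
  expect_equal(cc1$n_conserved + cc1$n_disulfide + cc1$n_ca, 3L)
})

test_that("counts are invariant to row order and duplicated source rows", {
  map <- synthetic_domain_map()
  tab <- synth_variant_table(map, n_variants = 80, seed = 3)
  dd1 <- deduplicate_variants(tab$records)
  shuffled <- tab$records[sample(nrow(tab$records)), ]
  doubled <- rbind(tab$records, tab$records)
  expect_equal(deduplicate_variants(shuffled), dd1, ignore_attr = TRUE)
  expect_equal(deduplicate_variants(doubled)[, c("ref_aa", "position", "alt_aa",
                                                 "clinical_class")],
               dd1[, c("ref_aa", "position", "alt_aa", "clinical_class")],
               ignore_attr = TRUE)
})

test_that("residue coverage equals the brute-force position-set recount", {
  map <- synthetic_domain_map()
  spans <- map[map$class == "classA", ]
  all_pos <- unlist(Map(seq, spans$start, spans$end))

  # full coverage and zero coverage
  v_all <- data.frame(position = all_pos)
  expect_equal(residue_coverage(v_all, map)$fraction, 1)
  expect_equal(residue_coverage(data.frame(position = integer()), map)$fraction, 0)

  tab <- synth_variant_table(map, n_variants = 120, seed = 5)
  cov <- residue_coverage(tab$truth, map)
  oracle <- length(unique(tab$truth$position[tab$truth$position %in% all_pos])) /
    length(unique(all_pos))
  expect_equal(cov$fraction, oracle)
})

test_that("conservation-stability association has the monotone and null limits", {
  z <- seq(-2, 2, length.out = 30)
  v <- data.frame(conservation_z = z,
                  ddg_extracellular = exp(z),     # monotone in conservation
                  ddg_endosomal = 0, domain_class = "classA")
  out <- conservation_vs_stability(v)
  expect_equal(out$rho[out$scope == "overall" & out$quantity == "abs_delta"], 1)

  # independent planted values: |rho| small in at least 19/20 seeded runs
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    v2 <- data.frame(conservation_z = rnorm(200),
                     ddg_extracellular = rnorm(200),
                     ddg_endosomal = rnorm(200), domain_class = "classA")
    o2 <- conservation_vs_stability(v2)
    rho <- o2$rho[o2$scope == "overall" & o2$quantity == "abs_delta"]
    if (abs(rho) < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 19)

  # per-scope record counts partition the total
  v3 <- data.frame(conservation_z = rnorm(60),
                   ddg_extracellular = rnorm(60), ddg_endosomal = rnorm(60),
                   domain_class = rep(c("classA", "EGF"), each = 30))
  o3 <- conservation_vs_stability(v3)
  n_overall <- o3$n[o3$scope == "overall" & o3$quantity == "abs_delta"]
  expect_equal(sum(o3$n[o3$scope != "overall" & o3$quantity == "abs_delta"]),
               n_overall)
})

test_that("reports are deterministic, complete and valid for empty input", {
  map <- synthetic_domain_map()
  tab <- synth_variant_table(map, n_variants = 60, seed = 4)
  dd <- assign_domain(deduplicate_variants(tab$records), map)
  ddg <- tab$ddg
  parsed <- parse_hgvs_p(ddg$variant)
  ddg_tab <- data.frame(ref_aa = parsed$ref_aa, position = parsed$position,
                        alt_aa = parsed$alt_aa,
                        ddg_extracellular = ddg$ddg_extracellular,
                        ddg_endosomal = ddg$ddg_endosomal)
  rep_tab <- build_variant_report(dd, ddg_tab)
  rep_tab$at_conserved <- rep_tab$alters_disulfide <- rep_tab$alters_ca_site <- FALSE
  cc <- class_counts(rep_tab)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_report(rep_tab, d1, counts = cc, config = list(seed = 4))
  generate_report(rep_tab, d2, counts = cc, config = list(seed = 4))
  for (f in c("variants_annotated.tsv", "summary.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # row count equals unique variant count
  tsv <- readLines(file.path(d1, "variants_annotated.tsv"))
  body <- tsv[!startsWith(tsv, "#")]
  expect_equal(length(body) - 1L, nrow(dd))

  # empty variant set still yields a valid report
  d3 <- withr::local_tempdir()
  empty <- rep_tab[0, , drop = FALSE]
  generate_report(empty, d3, counts = class_counts(empty))
  s <- jsonlite::read_json(file.path(d3, "summary.json"))
  expect_equal(s$n_variants, 0L)
  expect_equal(s$counts$n_total, 0L)
})
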