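test_that("HGVS protein parsing handles 3-letter, 1-letter and rejects non-missense", {
  p <- parse_hgvs_p(c("p.Cys27Arg", "p.C27R", "Cys27Arg", "p.(Cys27Arg)",
                      "p.D147D", "p.Asp147=", "p.Trp66Glyfs*12",
                      "p.Trp23Ter", "p.W23*", "gibberish", "p.Xyz12Arg"))
  expect_equal(p$status[1:4], rep("ok", 4))
  expect_equal(p$ref_aa[1:4], rep("C", 4))
  expect_equal(p$position[1:4], rep(27L, 4))
  expect_equal(p$alt_aa[1:4], rep("R", 4))
  expect_equal(p$reason[5:6], rep("synonymous", 2))
  expect_equal(p$reason[7], "frameshift")
  expect_equal(p$reason[8:9], rep("nonsense", 2))
  expect_equal(p$reason[10:11], rep("unparsable", 2))
})

test_that("clinical harmonization follows the pathogenic-dominant rules", {
  rec <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(source = m[, 1], raw_class = m[, 2], stringsAsFactors = FALSE)
  }
  expect_equal(harmonize_classification(rec("clinvar", "Likely pathogenic")),
               "pathogenic")
  expect_equal(harmonize_classification(rec("hgmd", "DM")), "pathogenic")
  expect_equal(harmonize_classification(rec("lovd", "ACGS class 4")),
               "pathogenic")
  # pathogenic criteria dominate a benign label
  expect_equal(harmonize_classification(rec("lovd", "ACGS 2", "hgmd", "DM")),
               "pathogenic")
  expect_equal(harmonize_classification(rec("clinvar", "Benign")), "benign")
  expect_equal(harmonize_classification(rec("lovd", "ACGS class 1")), "benign")
  expect_equal(harmonize_classification(
    rec("clinvar", "Uncertain significance", "population", "")), "vus")
  # strict HGMD: DM? is not a disease-mutation call
  expect_equal(harmonize_classification(rec("hgmd", "DM?")), "vus")
  # ClinVar conflicting reports are not a criterion
  expect_equal(harmonize_classification(
    rec("clinvar", "Conflicting interpretations of pathogenicity")), "vus")
  expect_error(harmonize_classification(rec("dbsnp", "x")), "unknown source")
})

test_that("harmonization is monotone in pathogenic evidence", {
  set.seed(11)
  labels <- list(c("clinvar", "Benign"), c("clinvar", "Uncertain significance"),
                 c("lovd", "ACGS class 2"), c("population", ""),
                 c("hgmd", "DM?"))
  for (k in 1:25) {
    base <- do.call(rbind, lapply(sample(labels, sample(1:4, 1), replace = TRUE),
                                  function(v) data.frame(source = v[1],
                                                         raw_class = v[2])))
    with_dm <- rbind(base, data.frame(source = "hgmd", raw_class = "DM"))
    expect_equal(harmonize_classification(with_dm), "pathogenic")
  }
})

test_that("deduplication keys on the protein change and merges sources", {
  recs <- data.frame(
    source = c("clinvar", "hgmd", "clinvar"),
    raw_class = c("Pathogenic", "DM", "Uncertain significance"),
    ref_aa = c("C", "C", "C"), position = c(27L, 27L, 27L),
    alt_aa = c("R", "R", "G"), stringsAsFactors = FALSE)
  dd <- deduplicate_variants(recs)
  expect_equal(nrow(dd), 2L)
  expect_equal(dd$n_sources[dd$alt_aa == "R"], 2L)
  expect_equal(dd$clinical_class[dd$alt_aa == "R"], "pathogenic")

  # synthetic table with a known number of distinct keys
  set.seed(5)
  n <- 50
  tab <- data.frame(source = "clinvar", raw_class = "Uncertain significance",
                    ref_aa = "A",
                    position = sample(100:115, n, replace = TRUE),
                    alt_aa = sample(c("V", "T", "G"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  n_unique <- length(unique(paste(tab$position, tab$alt_aa)))  # one-line scan
  expect_equal(nrow(deduplicate_variants(tab)), n_unique)

  # idempotent and order-invariant
  dd1 <- deduplicate_variants(tab)
  dd2 <- deduplicate_variants(tab[sample(nrow(tab)), ])
  expect_equal(dd1, dd2, ignore_attr = TRUE)

  # conflicting reference residues at one position are excluded and flagged
  bad <- rbind(tab, data.frame(source = "lovd", raw_class = "ACGS 3",
                               ref_aa = "W", position = tab$position[1],
                               alt_aa = "G", stringsAsFactors = FALSE))
  ddb <- deduplicate_variants(bad)
  expect_false(tab$position[1] %in% ddb$position)
  expect_gt(nrow(attr(ddb, "flagged")), 0)
})

test_that("every deduplicated variant carries exactly one clinical class", {
  map <- synthetic_domain_map()
  for (seed in c(2, 9)) {
    tab <- synth_variant_table(map, n_variants = 120, seed = seed)
    dd <- deduplicate_variants(tab$records)
    expect_true(all(dd$clinical_class %in% c("pathogenic", "benign", "vus")))
    counts <- table(dd$clinical_class)
    expect_equal(sum(counts), nrow(dd))
  }
})

test_that("domain assignment equals the brute-force span scan", {
  map <- synthetic_domain_map()
  tab <- synth_variant_table(map, n_variants = 150, seed = 3)
  dd <- assign_domain(deduplicate_variants(tab$records), map)
  oracle <- vapply(dd$position, function(p) {
    for (i in seq_len(nrow(map)))
      if (map$start[i] <= p && p <= map$end[i]) return(map$domain_name[i])
    NA_character_
  }, character(1))
  expect_equal(dd$domain_name, oracle)
  expect_true(is.na(domain_of(24, map)))  # before the first repeat
})

test_that("numbering frame auto-detection recognizes mature-frame tables", {
  set.seed(7)
  ref_seq <- random_aa_string(300)
  seqv <- strsplit(ref_seq, "")[[1]]
  pos_prec <- sample(30:290, 40)
  recs_prec <- data.frame(ref_aa = seqv[pos_prec], position = pos_prec,
                          stringsAsFactors = FALSE)
  det <- detect_numbering_frame(recs_prec, ref_seq)
  expect_equal(det$frame, "precursor")
  expect_equal(nrow(det$records), 40L)

  recs_mat <- data.frame(ref_aa = seqv[pos_prec], position = pos_prec - 21L,
                         stringsAsFactors = FALSE)
  det2 <- detect_numbering_frame(recs_mat, ref_seq)
  expect_equal(det2$frame, "mature")
  expect_equal(det2$records$position, pos_prec)

  # a record whose stated reference matches neither frame is excluded
  bad <- rbind(recs_prec,
               data.frame(ref_aa = setdiff(c("A", "C"), seqv[100])[1],
                          position = 100L))
  det3 <- detect_numbering_frame(bad, ref_seq)
  expect_equal(nrow(det3$excluded), nrow(bad) - nrow(det3$records))
})

test_that("variant tables read from disk preserve records and reasons", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\tclassification\thgvs_p",
               "clinvar\tPathogenic\tp.Cys46Arg",
               "hgmd\tDM\tp.C46R",
               "clinvar\tBenign\tp.Trp66Glyfs*12",
               "lovd\tACGS class 2\tp.Asp147Glu"), f)
  tab <- read_variant_table(f)
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "rejected")$reason, "frameshift")
  dd <- deduplicate_variants(tab)
  expect_equal(nrow(dd), 2L)
})
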