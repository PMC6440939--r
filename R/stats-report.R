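# stats_report: the summary statistics of the analysis — structural-class
# counts and their union, condition-difference category counts, residue
# coverage, Spearman correlation between conditions, rank-sum comparisons
# of ddG distributions across clinical classes — and the deterministic
# report writer.

#' Spearman rank correlation
#'
#' Average-rank tie handling (rank then Pearson), via [stats::cor()].
#'
#' @param x,y equal-length numeric vectors (n >= 3)
#' @return rho in \[-1, 1\]
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Round-half-up percentage in the report's display style
#' @noRd
pct <- function(k, n) {
  if (n == 0) return(0)
  floor(100 * k / n + 0.5)
}

#' Structural-class and category counts over a variant table
#'
#' Counts unique missense variants carrying each structural flag, the
#' union ("affects one of the structurally informed classes"), the
#' clinical-class partition, and the gray/orange/red condition-difference
#' categories (complete records only).
#'
#' @param variants data.frame with columns position, clinical_class, the
#'   role flags at_conserved / alters_disulfide / alters_ca_site and
#'   (optionally) delta_category and domain_class
#' @param domain_filter optional domain class label (e.g. "classA"); rows
#'   must then carry `domain_class`
#' @return list of class `ldlr_class_counts`: n_total, n_conserved,
#'   n_disulfide, n_ca, n_union, n_by_clinical, n_delta (gray/orange/red),
#'   percentages
#' @export
class_counts <- function(variants, domain_filter = NULL) {
  v <- variants
  if (!is.null(domain_filter)) {
    if (!"domain_class" %in% names(v))
      stop("domain_filter given but variants lack domain_class")
    v <- v[!is.na(v$domain_class) & v$domain_class %in% domain_filter, ,
           drop = FALSE]
  }
  n <- nrow(v)
  n_cons <- sum(v$at_conserved, na.rm = TRUE)
  n_ss <- sum(v$alters_disulfide, na.rm = TRUE)
  n_ca <- sum(v$alters_ca_site, na.rm = TRUE)
  n_union <- sum(v$at_conserved | v$alters_disulfide | v$alters_ca_site,
                 na.rm = TRUE)
  clin <- table(factor(v$clinical_class,
                       levels = c("pathogenic", "benign", "vus")))
  delta <- if ("delta_category" %in% names(v))
    table(factor(v$delta_category, levels = c("gray", "orange", "red")))
  else table(factor(character(), levels = c("gray", "orange", "red")))
  n_complete <- sum(!is.na(v$delta_category %||% NA))
  out <- list(n_total = n, n_conserved = n_cons, n_disulfide = n_ss,
              n_ca = n_ca, n_union = n_union,
              n_by_clinical = as.list(as.integer(clin)) |>
                stats::setNames(names(clin)),
              n_delta = as.list(as.integer(delta)) |>
                stats::setNames(names(delta)),
              pct_delta = as.list(vapply(as.integer(delta), pct,
                                         numeric(1), n = max(1, sum(delta)))) |>
                stats::setNames(names(delta)),
              pct_union = pct(n_union, max(1, n)))
  class(out) <- "ldlr_class_counts"
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of domain residues covered by at least one variant
#'
#' @param variants data.frame with a `position` column
#' @param map an `ldlr_domain_map`
#' @param class_filter domain class(es) to include (default "classA")
#' @return list: fraction, n_covered, n_residues
#' @export
residue_coverage <- function(variants, map, class_filter = "classA") {
  spans <- map[map$class %in% class_filter, , drop = FALSE]
  dom_pos <- unique(unlist(Map(seq, spans$start, spans$end)))
  covered <- intersect(unique(variants$position), dom_pos)
  list(fraction = length(covered) / length(dom_pos),
       n_covered = length(covered), n_residues = length(dom_pos))
}

#' Compare ddG distributions across clinical classes within domain groups
#'
#' Two-sided Wilcoxon rank-sum tests (exact for small groups, normal
#' approximation with continuity correction otherwise, as
#' [stats::wilcox.test()] does) for each clinical-class pair within each
#' domain group, plus the fraction of each class exceeding the
#' significance threshold. Raw p-values are reported; a Benjamini-Hochberg
#' column is appended, clearly labelled, but not used for any decision.
#'
#' @param variants data.frame with columns clinical_class, a ddG column
#'   named by `ddg_column`, and a grouping column named by `group_column`
#' @param ddg_column which ddG column to compare (default
#'   "ddg_extracellular")
#' @param group_column grouping column (default "domain_class"); use a
#'   constant column to compare across the whole set
#' @param threshold destabilization threshold for the exceedance fraction
#' @return data.frame: group, class_a, class_b, n_a, n_b, statistic,
#'   p_value, p_bh, frac_exceed_a, frac_exceed_b
#' @export
ddg_distribution_compare <- function(variants,
                                     ddg_column = "ddg_extracellular",
                                     group_column = "domain_class",
                                     threshold = 0.6) {
  pairs <- list(c("pathogenic", "vus"), c("pathogenic", "benign"),
                c("vus", "benign"))
  groups <- unique(variants[[group_column]])
  groups <- groups[!is.na(groups)]
  rows <- list()
  for (g in groups) {
    vg <- variants[!is.na(variants[[group_column]]) &
                     variants[[group_column]] == g, , drop = FALSE]
    for (pr in pairs) {
      xa <- vg[[ddg_column]][vg$clinical_class == pr[1]]
      xb <- vg[[ddg_column]][vg$clinical_class == pr[2]]
      xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
      if (!length(xa) || !length(xb)) next
      wt <- suppressWarnings(stats::wilcox.test(xa, xb,
                                                alternative = "two.sided"))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, class_a = pr[1], class_b = pr[2],
        n_a = length(xa), n_b = length(xb),
        statistic = unname(wt$statistic), p_value = wt$p.value,
        frac_exceed_a = mean(xa > threshold),
        frac_exceed_b = mean(xb > threshold), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(group = character(), class_a = character(),
                      class_b = character(), n_a = integer(), n_b = integer(),
                      statistic = numeric(), p_value = numeric(),
                      p_bh = numeric(), frac_exceed_a = numeric(),
                      frac_exceed_b = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("group", "class_a", "class_b", "n_a", "n_b", "statistic",
          "p_value", "p_bh", "frac_exceed_a", "frac_exceed_b")]
}

#' Association between conservation and stability quantities
#'
#' Spearman rho and p ([stats::cor.test()]) between per-variant
#' conservation z and (a) the absolute condition difference, (b) the
#' extracellular ddG — overall and within each domain class.
#'
#' @param variants data.frame with conservation_z, ddg_extracellular,
#'   ddg_endosomal, domain_class
#' @return data.frame: scope, quantity, n, rho, p_value
#' @export
conservation_vs_stability <- function(variants) {
  v <- variants
  v$abs_delta <- abs(v$ddg_extracellular - v$ddg_endosomal)
  scopes <- c(list(overall = rep(TRUE, nrow(v))),
              lapply(stats::setNames(nm = unique(v$domain_class[!is.na(v$domain_class)])),
                     function(g) !is.na(v$domain_class) & v$domain_class == g))
  rows <- list()
  for (sc in names(scopes)) {
    for (q in c("abs_delta", "ddg_extracellular")) {
      ok <- scopes[[sc]] & is.finite(v$conservation_z) & is.finite(v[[q]])
      if (sum(ok) < 3 || stats::sd(v$conservation_z[ok]) == 0 ||
          stats::sd(v[[q]][ok]) == 0) next
      ct <- suppressWarnings(stats::cor.test(v$conservation_z[ok], v[[q]][ok],
                                             method = "spearman"))
      rows[[length(rows) + 1]] <- data.frame(
        scope = sc, quantity = q, n = sum(ok),
        rho = unname(ct$estimate), p_value = ct$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(scope = character(), quantity = character(),
                      n = integer(), rho = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble the annotated variant table for reporting
#'
#' Joins unique variants with their ddG records and computes stability
#' classes and condition-difference categories.
#'
#' @param variants deduplicated variants ([deduplicate_variants()]),
#'   optionally already carrying role flags and domain assignment
#' @param ddg output of [load_ddg_table()] (or the generator's ddg table
#'   parsed the same way)
#' @param thresholds an [stability_thresholds()]
#' @return the merged data.frame with stability_extracellular,
#'   stability_endosomal, condition_delta, delta_category columns
#' @export
build_variant_report <- function(variants, ddg,
                                 thresholds = stability_thresholds()) {
  key_v <- paste(variants$ref_aa, variants$position, variants$alt_aa)
  key_d <- paste(ddg$ref_aa, ddg$position, ddg$alt_aa)
  idx <- match(key_v, key_d)
  variants$ddg_extracellular <- ddg$ddg_extracellular[idx]
  variants$ddg_endosomal <- ddg$ddg_endosomal[idx]
  fe <- is.finite(variants$ddg_extracellular)
  fn <- is.finite(variants$ddg_endosomal)
  variants$stability_extracellular <- NA_character_
  variants$stability_extracellular[fe] <-
    classify_stability(variants$ddg_extracellular[fe], thresholds)
  variants$stability_endosomal <- NA_character_
  variants$stability_endosomal[fn] <-
    classify_stability(variants$ddg_endosomal[fn], thresholds)
  variants$condition_delta <- variants$ddg_extracellular - variants$ddg_endosomal
  variants$delta_category <- condition_difference(variants$ddg_extracellular,
                                                  variants$ddg_endosomal,
                                                  thresholds)
  variants
}

#' Write the deterministic analysis report
#'
#' Emits `summary.json` (counts, correlations, configuration echo),
#' `variants_annotated.tsv` (one row per unique variant, `#`-prefixed
#' metadata header) and one `quality_<id>.json` per supplied quality
#' report. Output is byte-identical across runs on identical input: rows
#' are sorted, numbers are written with full precision and no timestamps
#' are embedded.
#'
#' @param variants annotated variant table ([build_variant_report()])
#' @param out_dir output directory (created if needed)
#' @param counts optional [class_counts()] result
#' @param correlations optional [conservation_vs_stability()] result
#' @param comparisons optional [ddg_distribution_compare()] result
#' @param quality optional list of `ldlr_quality` reports
#' @param config named list echoed into every output header
#' @return invisible character vector of files written
#' @export
generate_report <- function(variants, out_dir, counts = NULL,
                            correlations = NULL, comparisons = NULL,
                            quality = NULL, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)

  v <- variants[order(variants$position, variants$ref_aa, variants$alt_aa), ,
                drop = FALSE]
  tsv <- file.path(out_dir, "variants_annotated.tsv")
  hdr <- c("# ldlrstruct annotated variant table",
           "# positive ddG_fold = destabilizing (FoldX sign convention)",
           sprintf("# config: %s", jsonlite::toJSON(config, auto_unbox = TRUE)))
  con <- file(tsv, "w")
  writeLines(hdr, con)
  utils::write.table(v, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  files <- c(files, tsv)

  summary <- list(config = config,
                  n_variants = nrow(v),
                  counts = if (!is.null(counts)) unclass(counts),
                  correlations = correlations,
                  comparisons = comparisons)
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, sj)

  for (q in quality %||% list()) {
    qf <- file.path(out_dir, sprintf("quality_%s.json", q$id))
    jsonlite::write_json(unclass(q)[setdiff(names(q), "detail")], qf,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, qf)
  }
  invisible(files)
}
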