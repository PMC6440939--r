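# variant_catalog: HGVS protein-change parsing, source-record
# deduplication and clinical harmonization across ClinVar-, HGMD- and
# LOVD-style classifications. The analysis is missense-only: nonsense,
# frameshift and synonymous notations are rejected with a reason code.

VARIANT_SOURCES <- c("clinvar", "hgmd", "lovd", "population")

#' Parse HGVS protein notation into a missense change
#'
#' Accepts `p.Cys27Arg`, `p.C27R`, `Cys27Arg` and parenthesized forms
#' `p.(Cys27Arg)`. Three-letter codes are mapped to one-letter. Non-missense
#' notations are rejected rather than errored, with a machine-readable
#' reason.
#'
#' @param text character vector of HGVS protein strings
#' @return data.frame with columns raw_hgvs, ref_aa, position, alt_aa,
#'   status ("ok"/"rejected"), reason ("" | "nonsense" | "frameshift" |
#'   "synonymous" | "unparsable")
#' @export
parse_hgvs_p <- function(text) {
  out <- data.frame(raw_hgvs = as.character(text),
                    ref_aa = NA_character_, position = NA_integer_,
                    alt_aa = NA_character_, status = "rejected",
                    reason = "unparsable", stringsAsFactors = FALSE)
  core <- sub("^p\\.", "", trimws(text))
  core <- sub("^\\((.*)\\)$", "\\1", core)

  fs <- grepl("fs", core, ignore.case = TRUE)
  out$reason[fs] <- "frameshift"
  nonsense <- !fs & (grepl("(Ter|\\*)$", core) | grepl("\\*\\d", core))
  out$reason[nonsense] <- "nonsense"

  m3 <- regmatches(core, regexec("^([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2}|=)$", core))
  m1 <- regmatches(core, regexec("^([A-Z])(\\d+)([A-Z]|=)$", core))
  for (i in seq_along(core)) {
    if (fs[i] || nonsense[i]) next
    ref <- alt <- NA_character_; pos <- NA_integer_
    if (length(m3[[i]])) {
      ref <- aa3_to_1(m3[[i]][2])
      pos <- as.integer(m3[[i]][3])
      alt <- if (m3[[i]][4] == "=") ref else aa3_to_1(m3[[i]][4])
      if (m3[[i]][4] %in% c("Ter")) { out$reason[i] <- "nonsense"; next }
    } else if (length(m1[[i]])) {
      ref <- toupper(m1[[i]][2])
      pos <- as.integer(m1[[i]][3])
      alt <- if (m1[[i]][4] == "=") ref else toupper(m1[[i]][4])
    } else next
    if (is.na(ref) || is.na(alt) || !(ref %in% AA1) || !(alt %in% AA1)) next
    if (identical(ref, alt)) { out$reason[i] <- "synonymous"; next }
    if (is.na(pos) || pos < 1) next
    out$ref_aa[i] <- ref; out$position[i] <- pos; out$alt_aa[i] <- alt
    out$status[i] <- "ok"; out$reason[i] <- ""
  }
  out
}

#' @noRd
is_pathogenic_criterion <- function(source, raw_class) {
  rc <- tolower(trimws(raw_class))
  src <- tolower(source)
  acgs <- suppressWarnings(as.integer(gsub("[^0-9]", "", rc)))
  (src == "clinvar" & grepl("pathogenic", rc) & !grepl("conflict", rc)) |
    (src == "hgmd" & trimws(raw_class) == "DM") |
    (src == "lovd" & !is.na(acgs) & acgs %in% c(4L, 5L))
}

#' @noRd
is_benign_criterion <- function(source, raw_class) {
  rc <- tolower(trimws(raw_class))
  src <- tolower(source)
  acgs <- suppressWarnings(as.integer(gsub("[^0-9]", "", rc)))
  (src == "clinvar" & grepl("benign", rc) & !grepl("conflict", rc)) |
    (src == "lovd" & !is.na(acgs) & acgs %in% c(1L, 2L))
}

#' Harmonize source classifications into one clinical class
#'
#' A variant is pathogenic if any source meets a pathogenic criterion:
#' (likely) pathogenic in ClinVar, `DM` in HGMD, or ACGS class 4/5 in LOVD.
#' It is benign only if some source meets a benign criterion ((likely)
#' benign in ClinVar or ACGS class 1/2 in LOVD) and no pathogenic criterion
#' holds. Everything else — including population-database presence alone —
#' is a VUS.
#'
#' @param records data.frame with columns source, raw_class
#' @return one of "pathogenic", "benign", "vus"
#' @export
harmonize_classification <- function(records) {
  if (!nrow(records)) stop("harmonize_classification needs >= 1 record")
  bad <- setdiff(tolower(records$source), VARIANT_SOURCES)
  if (length(bad)) stop("unknown source(s): ", paste(bad, collapse = ", "))
  if (any(is_pathogenic_criterion(records$source, records$raw_class)))
    return("pathogenic")
  if (any(is_benign_criterion(records$source, records$raw_class)))
    return("benign")
  "vus"
}

#' Deduplicate source records into unique protein-level variants
#'
#' Uniqueness is at the protein-change level (ref, position, alt). Sources
#' for the same change are merged and harmonized together. Positions where
#' sources disagree on the reference amino acid are excluded entirely and
#' reported in the `flagged` attribute.
#'
#' @param records data.frame with columns source, raw_class, ref_aa,
#'   position, alt_aa (numbering already normalized)
#' @return data.frame of unique variants: ref_aa, position, alt_aa,
#'   clinical_class, n_sources, sources (collapsed string); attribute
#'   `flagged` holds excluded conflicting records
#' @export
deduplicate_variants <- function(records) {
  if (!nrow(records)) {
    out <- data.frame(ref_aa = character(), position = integer(),
                      alt_aa = character(), clinical_class = character(),
                      n_sources = integer(), sources = character(),
                      stringsAsFactors = FALSE)
    attr(out, "flagged") <- records
    return(out)
  }
  refs_by_pos <- tapply(records$ref_aa, records$position,
                        function(r) length(unique(r)))
  conflict_pos <- as.integer(names(refs_by_pos)[refs_by_pos > 1])
  flagged <- records[records$position %in% conflict_pos, , drop = FALSE]
  records <- records[!records$position %in% conflict_pos, , drop = FALSE]

  key <- paste(records$ref_aa, records$position, records$alt_aa)
  split_idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(split_idx, function(idx) {
    r <- records[idx, , drop = FALSE]
    data.frame(ref_aa = r$ref_aa[1], position = r$position[1],
               alt_aa = r$alt_aa[1],
               clinical_class = harmonize_classification(r),
               n_sources = nrow(r),
               sources = paste(sort(unique(tolower(r$source))), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$ref_aa, out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  out
}

#' Read a delimited variant table and parse its HGVS column
#'
#' @param path CSV or TSV with columns source, classification, hgvs_p
#' @return data.frame of parsed missense records (source, raw_class, ref_aa,
#'   position, alt_aa, raw_hgvs); rejected rows are kept in attribute
#'   `rejected` with their reason codes
#' @export
read_variant_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "\"")
  needed <- c("source", "classification", "hgvs_p")
  if (!all(needed %in% names(tab)))
    stop("variant table needs columns: ", paste(needed, collapse = ", "))
  parsed <- parse_hgvs_p(tab$hgvs_p)
  ok <- parsed$status == "ok"
  out <- data.frame(source = tolower(tab$source[ok]),
                    raw_class = tab$classification[ok],
                    ref_aa = parsed$ref_aa[ok], position = parsed$position[ok],
                    alt_aa = parsed$alt_aa[ok], raw_hgvs = parsed$raw_hgvs[ok],
                    stringsAsFactors = FALSE)
  rej <- cbind(tab[!ok, needed, drop = FALSE],
               reason = parsed$reason[!ok])
  attr(out, "rejected") <- rej
  out
}

#' Detect whether variant positions use mature or precursor numbering
#'
#' Checks the stated reference amino acids against the canonical precursor
#' sequence in both frames and picks the better-matching one. Records whose
#' reference residue matches neither frame after conversion should be
#' excluded by the caller.
#'
#' @param records parsed records (ref_aa, position)
#' @param ref_seq canonical precursor sequence (single string)
#' @param offset signal-peptide length (default 21)
#' @return list(frame = "precursor"|"mature", match_fraction, converted
#'   records with precursor positions, excluded records)
#' @export
detect_numbering_frame <- function(records, ref_seq, offset = 21L) {
  seqv <- strsplit(ref_seq, "")[[1]]
  at <- function(pos) ifelse(pos >= 1 & pos <= length(seqv), seqv[pos], NA)
  frac_prec <- mean(at(records$position) == records$ref_aa, na.rm = TRUE)
  frac_mat <- mean(at(records$position + offset) == records$ref_aa, na.rm = TRUE)
  frame <- if (isTRUE(frac_mat > frac_prec)) "mature" else "precursor"
  conv <- records
  if (frame == "mature") conv$position <- conv$position + offset
  match_ok <- at(conv$position) == conv$ref_aa & !is.na(at(conv$position))
  list(frame = frame,
       match_fraction = if (frame == "mature") frac_mat else frac_prec,
       records = conv[match_ok, , drop = FALSE],
       excluded = conv[!match_ok, , drop = FALSE])
}

#' Assign each variant to the domain containing its position
#'
#' @param variants data.frame with a `position` column (precursor frame)
#' @param map an `ldlr_domain_map`
#' @return `variants` with a `domain_name` column (`NA` outside all domains)
#'   and a `domain_class` column
#' @export
assign_domain <- function(variants, map) {
  variants$domain_name <- domain_of(variants$position, map)
  idx <- match(variants$domain_name, map$domain_name)
  variants$domain_class <- ifelse(is.na(idx), NA_character_, map$class[idx])
  variants
}
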