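# alignment_conservation: cysteine-anchored pairwise alignment (used to
# map class-A repeats onto their template with the conserved disulfide
# cysteines forced into register) and entropy-based per-residue
# conservation scoring from a multiple sequence alignment.

#' @noRd
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' @noRd
gap_cost <- function(len, gap_open, gap_extend) {
  if (len == 0) 0 else gap_open + len * gap_extend
}

#' @noRd
align_segment <- function(sa, sb, submat, gap_open, gap_extend) {
  if (!nchar(sa) && !nchar(sb))
    return(list(a = "", b = "", score = 0))
  if (!nchar(sa))
    return(list(a = strrep("-", nchar(sb)), b = sb,
                score = -gap_cost(nchar(sb), gap_open, gap_extend)))
  if (!nchar(sb))
    return(list(a = sa, b = strrep("-", nchar(sa)),
                score = -gap_cost(nchar(sa), gap_open, gap_extend)))
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(sa),
                                      Biostrings::AAString(sb),
                                      substitutionMatrix = submat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend,
                                      type = "global")
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Global alignment with anchored residue pairs
#'
#' Needleman–Wunsch-style global alignment (BLOSUM62, affine gaps) subject
#' to a set of anchor pairs that must share a column — used to force the
#' six conserved disulfide-bonding cysteines of a class-A repeat into
#' register with the template. The problem decomposes into independent
#' global alignments of the inter-anchor segments; segment alignment is
#' delegated to [Biostrings::pairwiseAlignment()].
#'
#' @param seq_a,seq_b ungapped amino-acid strings
#' @param anchors list (or 2-column matrix) of (i, j) 1-based position
#'   pairs, strictly increasing in both coordinates
#' @param gap_open,gap_extend affine gap penalties (positive costs;
#'   defaults 10 and 0.5)
#' @return list of class `ldlr_alignment`: seq_a, seq_b (gapped, equal
#'   length), anchor_pairs, score
#' @export
constrained_global_align <- function(seq_a, seq_b, anchors = list(),
                                     gap_open = 10, gap_extend = 0.5) {
  if (is.matrix(anchors)) anchors <- asplit(anchors, 1)
  ai <- vapply(anchors, `[`, numeric(1), 1)
  aj <- vapply(anchors, `[`, numeric(1), 2)
  if (length(ai)) {
    if (any(ai < 1 | ai > nchar(seq_a) | aj < 1 | aj > nchar(seq_b)))
      stop("anchor outside sequence range")
    if (any(diff(ai) <= 0) || any(diff(aj) <= 0))
      stop("anchors must be strictly increasing in both sequences (crossing anchors)")
  }
  submat <- blosum62_matrix()
  ca <- strsplit(seq_a, "")[[1]]
  cb <- strsplit(seq_b, "")[[1]]

  bounds_a <- c(0, ai, nchar(seq_a) + 1)
  bounds_b <- c(0, aj, nchar(seq_b) + 1)
  out_a <- character(0); out_b <- character(0); score <- 0
  for (k in seq_len(length(ai) + 1)) {
    sa <- substr(seq_a, bounds_a[k] + 1, bounds_a[k + 1] - 1)
    sb <- substr(seq_b, bounds_b[k] + 1, bounds_b[k + 1] - 1)
    seg <- align_segment(sa, sb, submat, gap_open, gap_extend)
    out_a <- c(out_a, seg$a); out_b <- c(out_b, seg$b)
    score <- score + seg$score
    if (k <= length(ai)) {
      out_a <- c(out_a, ca[ai[k]]); out_b <- c(out_b, cb[aj[k]])
      score <- score + submat[ca[ai[k]], cb[aj[k]]]
    }
  }
  aln_a <- paste(out_a, collapse = ""); aln_b <- paste(out_b, collapse = "")
  stopifnot(gsub("-", "", aln_a) == seq_a, gsub("-", "", aln_b) == seq_b)
  structure(list(seq_a = aln_a, seq_b = aln_b,
                 anchor_pairs = Map(c, ai, aj), score = score),
            class = "ldlr_alignment")
}

# ---------------------------------------------------------------------------
# Conservation

#' Per-residue conservation profile from a multiple sequence alignment
#'
#' For every alignment column in which the reference row has a residue, the
#' raw score is `1 - H/Hmax` with `H` the Shannon entropy of the amino-acid
#' distribution in that column (gaps excluded) and `Hmax = log(20)`.
#' Raw scores are then z-normalized across the protein. A position is
#' flagged conserved when it is an invariant column (raw score 1) or its
#' z-score reaches `threshold`. Columns with no residues besides the
#' reference are excluded (`NA` score).
#'
#' @param msa character vector of equal-length aligned sequences (or a named
#'   list); `-` and `.` are gaps
#' @param ref_index which row is the reference protein (default 1)
#' @param threshold conservation z-score flag cutoff (default 1.5)
#' @return list of class `ldlr_conservation`: data.frame `profile`
#'   (position, column, score_raw, score_z, conserved), n_sequences,
#'   threshold. `position` is the 1-based ungapped reference coordinate.
#' @export
conservation_profile <- function(msa, ref_index = 1, threshold = 1.5) {
  msa <- as.character(unlist(msa))
  if (length(unique(nchar(msa))) != 1)
    stop("MSA rows differ in length")
  rows <- do.call(rbind, strsplit(toupper(msa), ""))
  rows[rows == "."] <- "-"
  ref <- rows[ref_index, ]
  cols <- which(ref != "-")
  score_raw <- rep(NA_real_, length(cols))
  for (k in seq_along(cols)) {
    col <- rows[, cols[k]]
    if (nrow(rows) > 1 && !any(col[-ref_index] %in% AA1)) next  # gaps-only column
    aas <- col[col %in% AA1]
    if (!length(aas)) next
    p <- table(aas) / length(aas)
    h <- -sum(p * log(p))
    score_raw[k] <- 1 - h / log(20)
  }
  usable <- !is.na(score_raw)
  mu <- mean(score_raw[usable])
  sdv <- stats::sd(score_raw[usable])
  score_z <- if (is.na(sdv) || sdv < .Machine$double.eps^0.5)
    rep(0, length(score_raw)) else (score_raw - mu) / sdv
  score_z[!usable] <- NA_real_
  invariant <- !is.na(score_raw) & score_raw >= 1 - 1e-12
  conserved <- invariant | (!is.na(score_z) & score_z >= threshold)
  structure(list(profile = data.frame(position = seq_along(cols),
                                      column = cols,
                                      score_raw = score_raw,
                                      score_z = score_z,
                                      conserved = conserved),
                 n_sequences = nrow(rows), threshold = threshold),
            class = "ldlr_conservation")
}

#' Re-threshold a conservation profile
#'
#' Deterministic flag recomputation at a different z cutoff (invariant
#' columns stay flagged; `-Inf` flags everything with a defined score).
#'
#' @param profile an `ldlr_conservation`
#' @param threshold z-score cutoff
#' @return logical vector per reference position
#' @export
classify_conserved <- function(profile, threshold) {
  p <- profile$profile
  invariant <- !is.na(p$score_raw) & p$score_raw >= 1 - 1e-12
  invariant | (!is.na(p$score_z) & p$score_z >= threshold)
}

#' Read an aligned FASTA file into a character vector
#'
#' @param path aligned FASTA
#' @return named character vector of gapped sequences
#' @export
read_alignment_fasta <- function(path) {
  aln <- Biostrings::readAAMultipleAlignment(path, format = "fasta")
  as.character(Biostrings::unmasked(aln))
}

#' Write aligned sequences as FASTA
#'
#' @param seqs named character vector of gapped sequences
#' @param path output file
#' @return `path`, invisibly
#' @export
write_alignment_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
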