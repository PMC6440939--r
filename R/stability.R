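# stability: per-condition ddG_fold ingest, stability-class thresholds
# (0.6 / 1.8 kcal/mol) and the endosomal-vs-extracellular difference
# categories (gray < 1.8 <= orange <= 3.0 < red, kcal/mol). Positive ddG
# is destabilizing throughout (FoldX sign convention). A simplified
# interpretable estimator is provided so synthetic end-to-end runs need no
# external energy function; it is not a FoldX reimplementation.

#' Stability thresholds (kcal/mol)
#'
#' `significant` (0.6) separates neutral from (de)stabilizing,
#' `strong` (1.8) marks strongly destabilizing and is also the lower edge
#' of the orange condition-difference band, `severe` (3.0) is the red-band
#' edge.
#'
#' @param significant,strong,severe positive, strictly increasing
#' @return list of class `ldlr_thresholds`
#' @export
stability_thresholds <- function(significant = 0.6, strong = 1.8,
                                 severe = 3.0) {
  if (!(significant > 0 && significant < strong && strong < severe))
    stop("need 0 < significant < strong < severe")
  structure(list(significant = significant, strong = strong, severe = severe),
            class = "ldlr_thresholds")
}

#' Classify a ddG_fold value into a stability class
#'
#' @param ddg numeric vector, kcal/mol (positive = destabilizing)
#' @param thresholds an [stability_thresholds()] object
#' @return character vector: "stabilizing", "neutral", "destabilizing" or
#'   "strongly_destabilizing"
#' @export
classify_stability <- function(ddg, thresholds = stability_thresholds()) {
  if (any(!is.finite(ddg)))
    stop("non-finite ddG value")
  t <- thresholds
  out <- rep("neutral", length(ddg))
  out[ddg < -t$significant] <- "stabilizing"
  out[ddg > t$significant] <- "destabilizing"
  out[ddg > t$strong] <- "strongly_destabilizing"
  out
}

#' Categorize the between-condition stability difference
#'
#' `d = |ddg_extracellular - ddg_endosomal|`; `d < strong` is gray,
#' `strong <= d <= severe` orange (closed band) and `d > severe` red.
#' Records missing either condition give `NA`.
#'
#' @param ddg_extracellular,ddg_endosomal numeric vectors, kcal/mol
#' @param thresholds an [stability_thresholds()] object
#' @return character vector "gray"/"orange"/"red" (`NA` for partial records)
#' @export
condition_difference <- function(ddg_extracellular, ddg_endosomal,
                                 thresholds = stability_thresholds()) {
  d <- abs(ddg_extracellular - ddg_endosomal)
  out <- rep(NA_character_, length(d))
  ok <- is.finite(d)
  out[ok & d < thresholds$strong] <- "gray"
  out[ok & d >= thresholds$strong & d <= thresholds$severe] <- "orange"
  out[ok & d > thresholds$severe] <- "red"
  out
}

#' Load a per-condition ddG table
#'
#' @param path CSV/TSV with columns variant (HGVS protein or `C27R` form),
#'   ddg_extracellular, ddg_endosomal (either may be missing per row)
#' @return data.frame: ref_aa, position, alt_aa, ddg_extracellular,
#'   ddg_endosomal, partial (logical). Duplicate rows with identical values
#'   collapse; conflicting duplicates are an error. Non-numeric ddG rows
#'   are dropped and reported in attribute `rejected`.
#' @export
load_ddg_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE, quote = "\"")
  if (!all(c("variant", "ddg_extracellular", "ddg_endosomal") %in% names(tab)))
    stop("ddG table needs columns variant, ddg_extracellular, ddg_endosomal")
  parsed <- parse_hgvs_p(tab$variant)
  keep <- parsed$status == "ok"
  de <- suppressWarnings(as.numeric(tab$ddg_extracellular))
  dn <- suppressWarnings(as.numeric(tab$ddg_endosomal))
  bad_num <- keep & is.na(de) & is.na(dn) &
    !(is.na(tab$ddg_extracellular) & is.na(tab$ddg_endosomal))
  rejected <- tab[!keep | bad_num, , drop = FALSE]
  keep <- keep & !bad_num
  out <- data.frame(ref_aa = parsed$ref_aa[keep],
                    position = parsed$position[keep],
                    alt_aa = parsed$alt_aa[keep],
                    ddg_extracellular = de[keep], ddg_endosomal = dn[keep],
                    stringsAsFactors = FALSE)
  key <- paste(out$ref_aa, out$position, out$alt_aa)
  if (anyDuplicated(key)) {
    groups <- split(seq_len(nrow(out)), key)
    conflict <- names(groups)[vapply(groups, function(idx) {
      nrow(unique(out[idx, c("ddg_extracellular", "ddg_endosomal")])) > 1
    }, logical(1))]
    if (length(conflict))
      stop("conflicting duplicate ddG rows for: ",
           paste(conflict, collapse = ", "))
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out$partial <- is.na(out$ddg_extracellular) | is.na(out$ddg_endosomal)
  out <- out[order(out$position, out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' @noRd
default_estimator_params <- function() {
  path <- system.file("extdata", "ddg_estimator_params.tsv",
                      package = "ldlrstruct")
  tab <- utils::read.delim(path, comment.char = "#")
  stats::setNames(tab$value, tab$term)
}

#' Simplified structure-based ddG estimate for a missense change
#'
#' A deterministic, interpretable score built from five terms evaluated on
#' an idealized side-chain swap (the mutant side chain is represented as an
#' effective sphere at the Cb position): steric clash gain, lost side-chain
#' hydrogen-bonding capability, burial-weighted hydropathy change
#' (Kyte-Doolittle), a fixed penalty for removing a disulfide-bonded
#' cysteine, and a fixed penalty when a side-chain calcium coordinator
#' loses its oxygen. Weights ship in `extdata/ddg_estimator_params.tsv`.
#' This is a toy for synthetic tests — not an empirical energy function —
#' and is never used where measured or FoldX-computed tables exist.
#'
#' @param structure an `ldlr_structure`
#' @param ref_aa,position,alt_aa the change (one-letter, precursor position)
#' @param annotations optional precomputed [annotate_residues()] table
#' @param params named weight vector (defaults from the shipped table)
#' @return list: ddg (kcal/mol, positive destabilizing) and `terms`, the
#'   per-term breakdown
#' @export
estimate_ddg <- function(structure, ref_aa, position, alt_aa,
                         annotations = NULL, params = NULL) {
  if (is.null(params)) params <- default_estimator_params()
  res <- structure_residues(structure)
  row <- which(res$res_seq == position)
  if (!length(row)) stop("position ", position, " not in structure")
  row <- row[1]
  if (!identical(res$aa[row], ref_aa))
    stop(sprintf("reference mismatch at %d: structure has %s, change states %s",
                 position, res$aa[row], ref_aa))
  if (identical(ref_aa, alt_aa))
    return(list(ddg = 0, terms = c(clash = 0, hbond = 0, hydropathy = 0,
                                   disulfide = 0, calcium = 0)))
  if (is.null(annotations))
    annotations <- annotate_residues(structure)
  ann <- annotations[match(position, annotations$position), , drop = FALSE]
  rsa <- if (is.na(ann$rsa)) 0.5 else ann$rsa

  # steric: overlap of the effective mutant side-chain sphere at Cb with
  # surrounding atoms, minus the same for the native side chain
  at <- protein_atoms(structure)
  cb <- at[at$res_seq == position & at$atom_name == "CB", , drop = FALSE]
  clash_gain <- 0
  if (nrow(cb)) {
    env <- at[at$res_seq != position, , drop = FALSE]
    d <- sqrt((env$x - cb$x[1])^2 + (env$y - cb$y[1])^2 + (env$z - cb$z[1])^2)
    renv <- vdw_radius(env$element)
    overlap <- function(r_sc) sum(pmax(0, r_sc + renv - d))
    clash_gain <- max(0, overlap(sidechain_radius(alt_aa)) -
                        overlap(sidechain_radius(ref_aa)))
  }
  hb_lost <- max(0, SIDECHAIN_HB[ref_aa] - SIDECHAIN_HB[alt_aa])
  hydro <- (KD_HYDROPATHY[ref_aa] - KD_HYDROPATHY[alt_aa]) * (1 - rsa)
  ss <- if (isTRUE(ann$in_disulfide) && ref_aa == "C" && alt_aa != "C") 1 else 0
  ca_loss <- if (isTRUE(ann$ca_sidechain) && ref_aa %in% SIDECHAIN_HAS_O &&
                 !(alt_aa %in% SIDECHAIN_HAS_O)) 1 else 0

  terms <- c(clash = unname(params["w_clash"] * clash_gain),
             hbond = unname(params["w_hbond"] * hb_lost),
             hydropathy = unname(params["w_hydropathy"] * hydro),
             disulfide = unname(params["w_disulfide"] * ss),
             calcium = unname(params["w_calcium"] * ca_loss))
  list(ddg = sum(terms), terms = terms)
}
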