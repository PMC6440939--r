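# Amino-acid reference tables used across the package. All values are
# standard literature constants; positions index the one-letter alphabet.

#' @noRd
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @noRd
AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' @noRd
AA3_TO_1 <- stats::setNames(names(AA3), unname(AA3))

# Parent mapping for common modified residues found in coordinate files.
#' @noRd
NONSTANDARD_PARENT <- c(MSE = "MET", SEC = "CYS", PYL = "LYS",
                        CSO = "CYS", SEP = "SER", TPO = "THR", PTR = "TYR")

# Kyte-Doolittle hydropathy.
#' @noRd
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Theoretical maximum accessible surface area (Tien et al. 2013), A^2.
#' @noRd
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
             Q = 225, E = 223, G = 104, H = 224, I = 197,
             L = 201, K = 236, M = 224, F = 240, P = 159,
             S = 155, T = 172, W = 285, Y = 263, V = 174)

# Mean residue volumes (A^3), Zamyatnin-style set.
#' @noRd
RESIDUE_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
                    Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
                    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
                    S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

# Side-chain hydrogen-bond capability (donor + acceptor heavy-atom count).
#' @noRd
SIDECHAIN_HB <- c(A = 0, R = 3, N = 2, D = 2, C = 1,
                  Q = 2, E = 2, G = 0, H = 2, I = 0,
                  L = 0, K = 1, M = 1, F = 0, P = 0,
                  S = 1, T = 1, W = 1, Y = 1, V = 0)

# Residues whose side chain carries at least one oxygen atom (candidate
# calcium coordinators through the side chain).
#' @noRd
SIDECHAIN_HAS_O <- c("D", "E", "N", "Q", "S", "T", "Y")

# Coarse residue classes for the contact potential:
# h hydrophobic, p polar, b basic (+), a acidic (-).
#' @noRd
RESIDUE_CLASS <- c(A = "h", R = "b", N = "p", D = "a", C = "h",
                   Q = "p", E = "a", G = "p", H = "p", I = "h",
                   L = "h", K = "b", M = "h", F = "h", P = "p",
                   S = "p", T = "p", W = "h", Y = "p", V = "h")

# Van der Waals radii by element symbol (A). Unlisted elements fall back
# to carbon.
#' @noRd
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, SE = 1.90, CA = 2.31)

#' @noRd
vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_RADII[["C"]]
  unname(r)
}

# Effective side-chain sphere radius from residue volume, used by the
# simplified ddG estimator's steric term.
#' @noRd
sidechain_radius <- function(aa) {
  v <- RESIDUE_VOLUME[aa]
  unname((3 * v / (4 * pi))^(1 / 3))
}

#' @noRd
aa3_to_1 <- function(res_name) {
  out <- AA3_TO_1[toupper(res_name)]
  unname(out)
}

#' @noRd
aa1_to_3 <- function(aa) unname(AA3[toupper(aa)])

#' @noRd
is_standard_aa3 <- function(res_name) toupper(res_name) %in% unname(AA3)
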