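# Independent oracles used to cross-check the implementation: plain-loop
# brute-force recomputations with no shared code path beyond the atom
# table format.

# average ranks computed by hand (no base rank())
oracle_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

# Spearman via manual ranks + manual Pearson formula
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Mann-Whitney U for x (the W statistic wilcox.test reports)
oracle_rank_sum_W <- function(x, y) {
  w <- 0
  for (xi in x) for (yj in y)
    w <- w + (xi > yj) + 0.5 * (xi == yj)
  w
}

# Gotoh global affine alignment score; gap of length L costs
# open + L * ext (the package's stated convention)
oracle_align_score <- function(a, b, open = 10, ext = 0.5, submat) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- submat[ca[i], cb[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force O(n^2) clash count over the same exclusion rules
oracle_clash_count <- function(structure, tolerance = 0.4) {
  at <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  at <- at[toupper(at$element) != "H", , drop = FALSE]
  bb <- c("N", "CA", "C", "O", "OXT")
  r <- sapply(toupper(at$element), function(e)
    switch(e, C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, 1.70))
  n <- nrow(at)
  sg <- which(at$atom_name == "SG")
  partner <- rep(NA_integer_, n)
  for (a1 in sg) for (a2 in sg) {
    if (a2 <= a1) next
    d <- sqrt(sum((at[a1, c("x", "y", "z")] - at[a2, c("x", "y", "z")])^2))
    if (d <= 2.5) { partner[a1] <- at$res_seq[a2]; partner[a2] <- at$res_seq[a1] }
  }
  count <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                (at$z[i] - at$z[j])^2)
    if (d >= r[i] + r[j] - tolerance) next
    same_chain <- at$chain_id[i] == at$chain_id[j]
    if (same_chain && at$res_seq[i] == at$res_seq[j]) next
    if (same_chain && abs(at$res_seq[i] - at$res_seq[j]) == 1 &&
        at$atom_name[i] %in% bb && at$atom_name[j] %in% bb) next
    if (at$atom_name[i] == "SG" && !is.na(partner[i]) &&
        partner[i] == at$res_seq[j] && at$atom_name[j] %in% c("SG", "CB")) next
    if (at$atom_name[j] == "SG" && !is.na(partner[j]) &&
        partner[j] == at$res_seq[i] && at$atom_name[i] %in% c("SG", "CB")) next
    count <- count + 1L
  }
  count
}

# brute-force hydrogen-bond participating residues
oracle_hbond_residues <- function(structure, dist_cutoff = 3.5,
                                  angle_cutoff = 120) {
  at <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  bb <- c("N", "CA", "C", "O", "OXT")
  sc_don <- c("NE", "NH1", "NH2", "NZ", "ND1", "NE2", "ND2", "NE1",
              "OG", "OG1", "OH")
  ang3 <- function(a, b, c) {
    v1 <- (a - b) / sqrt(sum((a - b)^2)); v2 <- (c - b) / sqrt(sum((c - b)^2))
    acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
  }
  participating <- integer(0)
  don_idx <- which((at$atom_name == "N" & at$res_name != "PRO") |
                     at$atom_name %in% sc_don)
  acc_idx <- which(toupper(at$element) == "O")
  for (i in don_idx) {
    same <- which(at$res_seq == at$res_seq[i] & at$chain_id == at$chain_id[i] &
                    at$atom_name != at$atom_name[i])
    if (!length(same)) next
    dpos <- as.numeric(at[i, c("x", "y", "z")])
    dmin <- Inf; ante <- NULL
    for (k in same) {
      dk <- sqrt(sum((as.numeric(at[k, c("x", "y", "z")]) - dpos)^2))
      if (dk < dmin) { dmin <- dk; ante <- as.numeric(at[k, c("x", "y", "z")]) }
    }
    for (j in acc_idx) {
      if (at$res_seq[j] == at$res_seq[i] && at$chain_id[j] == at$chain_id[i]) next
      if (at$atom_name[i] %in% bb && at$atom_name[j] %in% bb &&
          at$chain_id[j] == at$chain_id[i] &&
          abs(at$res_seq[j] - at$res_seq[i]) < 2) next
      apos <- as.numeric(at[j, c("x", "y", "z")])
      if (sqrt(sum((apos - dpos)^2)) > dist_cutoff) next
      if (ang3(ante, dpos, apos) < angle_cutoff) next
      participating <- c(participating, at$res_seq[i], at$res_seq[j])
    }
  }
  sort(unique(participating))
}

# direct numeric SASA of one residue with dense spherical sampling,
# independent of the package routine
oracle_residue_sasa <- function(structure, res_seq, n_points = 10000,
                                probe = 1.4) {
  at <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  radii <- sapply(toupper(at$element), function(e)
    switch(e, C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, 1.70))
  set.seed(42)
  u <- matrix(stats::rnorm(3 * n_points), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  total <- 0
  idx <- which(at$res_seq == res_seq)
  for (i in idx) {
    ri <- radii[i] + probe
    pts <- sweep(u * ri, 2, as.numeric(at[i, c("x", "y", "z")]), "+")
    blocked <- rep(FALSE, n_points)
    for (j in seq_len(nrow(at))) {
      if (j == i) next
      rj <- radii[j] + probe
      dj2 <- (pts[, 1] - at$x[j])^2 + (pts[, 2] - at$y[j])^2 +
        (pts[, 3] - at$z[j])^2
      blocked <- blocked | dj2 < rj^2
    }
    total <- total + mean(!blocked) * 4 * pi * ri^2
  }
  unname(total)
}

# a glycine fully enclosed in a spherical cage of carbon atoms
make_cage_structure <- function(cage_radius = 5, n_cage = 150) {
  gly <- data.frame(record = "ATOM",
                    atom_name = c("N", "CA", "C", "O"),
                    element = c("N", "C", "C", "O"), chain_id = "A",
                    res_name = "GLY", res_seq = 1L, ins_code = "",
                    x = c(-1.4, 0, 1.4, 2.0), y = c(0, 0, 0.4, 1.4),
                    z = 0, occupancy = 1, b_factor = 0,
                    stringsAsFactors = FALSE)
  sph <- ldlrstruct:::fibonacci_sphere(n_cage) * cage_radius
  cage <- data.frame(record = "ATOM", atom_name = "CA", element = "C",
                     chain_id = "B", res_name = "ALA",
                     res_seq = seq_len(n_cage) + 10L, ins_code = "",
                     x = sph[, 1], y = sph[, 2], z = sph[, 3],
                     occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
  new_structure("cage", rbind(gly, cage))
}

# single-residue helper structure
make_free_glycine <- function() {
  atoms <- data.frame(record = "ATOM",
                      atom_name = c("N", "CA", "C", "O"),
                      element = c("N", "C", "C", "O"), chain_id = "A",
                      res_name = "GLY", res_seq = 1L, ins_code = "",
                      x = c(-1.4, 0, 1.4, 2.0), y = c(0, 0, 0.4, 1.4),
                      z = 0, occupancy = 1, b_factor = 0,
                      stringsAsFactors = FALSE)
  new_structure("free_gly", atoms)
}

# tiny hand-built structure with arbitrary cysteine SG positions
make_cys_structure <- function(sg_positions) {
  rows <- list()
  for (k in seq_len(nrow(sg_positions))) {
    base <- c(sg_positions[k, 1], sg_positions[k, 2], sg_positions[k, 3])
    rows[[length(rows) + 1]] <- data.frame(
      record = "ATOM", atom_name = c("N", "CA", "C", "O", "CB", "SG"),
      element = c("N", "C", "C", "O", "C", "S"), chain_id = "A",
      res_name = "CYS", res_seq = as.integer(k), ins_code = "",
      x = base[1] + c(-20, -19, -18, -17.5, -19, 0),
      y = base[2] + c(0, 0, 0, 1, 1.5, 0) + 5 * k,
      z = base[3], occupancy = 1, b_factor = 0, stringsAsFactors = FALSE)
    # SG sits exactly at the requested position
    rows[[length(rows)]]$x[6] <- base[1]
    rows[[length(rows)]]$y[6] <- base[2]
    rows[[length(rows)]]$z[6] <- base[3]
  }
  new_structure("cys_toy", do.call(rbind, rows))
}

blosum62 <- function() ldlrstruct:::blosum62_matrix()

random_aa_string <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n,
               replace = TRUE), collapse = "")
}
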