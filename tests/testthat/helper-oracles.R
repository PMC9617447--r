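# Independent oracles and fixture builders shared across test files.

# the 21 node labels of the documented labelling scheme (type x role)
ALL_ITYPES <- c("HBA", "HBD", "ION_PPLUS", "ION_PMINUS", "ARO", "HYD", "MET")
ALL_LABELS <- as.vector(t(outer(ALL_ITYPES, c("ligand", "protein", "centre"),
                                paste, sep = ":")))

# brute-force Floyd-Warshall all-pairs shortest paths (test oracle,
# independent of the Dijkstra production path)
fw_oracle <- function(w) {
  d <- w
  n <- nrow(w)
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# random complete labelled graph with weights in {1, 10, 20, ..., 100} deci-A
random_complete_graph <- function(n_nodes) {
  w <- matrix(0L, n_nodes, n_nodes)
  vals <- sample(c(1L, seq(10L, 100L, by = 10L)),
                 n_nodes * (n_nodes - 1) / 2, replace = TRUE)
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  structure(list(labels = sample(ALL_LABELS, n_nodes, replace = TRUE),
                 weights = w, source = "random"),
            class = "interaction_graph")
}

# exhaustive path-feature enumeration for a graph: one string per unordered
# node pair, canonicalised alphabetically (any fixed canonical form yields
# the same multiset matching)
enumerate_features <- function(graph) {
  sp <- fw_oracle(graph$weights)
  n <- length(graph$labels)
  keys <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    lab <- sort(c(graph$labels[i], graph$labels[j]))
    keys <- c(keys, paste(lab[1], lab[2], sp[i, j]))
  }
  keys
}

# nn similarity by exhaustive pair-of-pairs counting
nn_oracle <- function(g1, g2) {
  f1 <- enumerate_features(g1)
  f2 <- enumerate_features(g2)
  sum(outer(f1, f2, "=="))
}

# brute-force MAD-heuristic oracle using sorted copies only
mad_oracle <- function(s) {
  n <- length(s)
  med_sorted <- function(v) {
    v <- sort(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  med <- med_sorted(s)
  mad <- med_sorted(abs(s - med))
  min(1, max(1 / n, sum(abs(s - med) > 3 * mad) / n))
}

# one-triplet builder for graph tests
triplet1 <- function(itype, lig, prot, res_name = "RES", res_id = 1L) {
  ipa_triplets(itype, matrix(lig, ncol = 3), matrix(prot, ncol = 3),
               res_name, res_id, 1L)
}

# tiny protein built from a coordinate matrix of C.3 atoms, plus a
# single-atom ligand, for the clustering / binding-site tests
make_frame <- function(protein_xyz, ligand_xyz = c(0, 0, 0),
                       frame_index = 0L, res_id = NULL) {
  n <- nrow(protein_xyz)
  if (is.null(res_id)) res_id <- seq_len(n)
  prot <- mol2_structure(data.frame(
    atom_id = seq_len(n), name = paste0("CA", seq_len(n)),
    x = protein_xyz[, 1], y = protein_xyz[, 2], z = protein_xyz[, 3],
    sybyl_type = "C.3", res_id = res_id, res_name = "GLY"), NULL, "prot")
  ligand_xyz <- matrix(ligand_xyz, ncol = 3)
  lig <- mol2_structure(data.frame(
    atom_id = seq_len(nrow(ligand_xyz)), name = "C1",
    x = ligand_xyz[, 1], y = ligand_xyz[, 2], z = ligand_xyz[, 3],
    sybyl_type = "C.3", res_id = 1L, res_name = "LIG"), NULL, "lig")
  complex_frame(prot, lig, frame_index)
}

# random 10-atom structure for MOL2 round-trip tests
random_structure <- function() {
  n <- 10L
  atoms <- data.frame(
    atom_id = seq_len(n), name = paste0("A", seq_len(n)),
    x = round(stats::runif(n, -20, 20), 4),
    y = round(stats::runif(n, -20, 20), 4),
    z = round(stats::runif(n, -20, 20), 4),
    sybyl_type = sample(c("C.3", "N.3", "O.3", "C.ar", "S.3"), n,
                        replace = TRUE),
    res_id = sample(1:3, n, replace = TRUE),
    res_name = "RES",
    charge = round(stats::runif(n, -0.5, 0.5), 4)
  )
  bonds <- data.frame(a1 = 1:(n - 1), a2 = 2:n,
                      order = sample(c("1", "2", "ar", "am"), n - 1,
                                     replace = TRUE))
  mol2_structure(atoms, bonds, "RANDOM")
}
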