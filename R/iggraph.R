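# Interaction graphs: complete labeled graphs over IPAs with integer deci-A
# edge weights. Distances are rounded to the nearest Angstrom (ties round
# half up) and stored as integers in tenths of an Angstrom so that all later
# shortest-path arithmetic is exact; overlapping IPAs (rounded distance 0)
# get weight 1 deci-A (0.1 A) so the edge still exists.

ROLES <- c("ligand", "protein", "centre")

# fixed total order over the 21 node labels, used to canonicalise label pairs
node_label_levels <- function() {
  as.vector(t(outer(ITYPES, ROLES, paste, sep = ":")))
}

round_half_up <- function(x) floor(x + 0.5)

triplet_points <- function(triplets) {
  n <- nrow(triplets)
  if (!n) return(list(xyz = matrix(numeric(), ncol = 3), labels = character()))
  xyz <- rbind(
    as.matrix(triplets[, c("lx", "ly", "lz")]),
    as.matrix(triplets[, c("px", "py", "pz")]),
    as.matrix(triplets[, c("cx", "cy", "cz")])
  )
  labels <- c(paste0(triplets$itype, ":ligand"),
              paste0(triplets$itype, ":protein"),
              paste0(triplets$itype, ":centre"))
  # interleave so nodes appear triplet by triplet (L, P, C per interaction)
  idx <- as.vector(t(matrix(seq_len(3 * n), ncol = 3)))
  list(xyz = xyz[idx, , drop = FALSE], labels = labels[idx])
}

#' Build the complete interaction graph from IPA triplets
#'
#' Three nodes per triplet (ligand, protein, centre), labelled interaction
#' type x role; every node pair is connected, with weight equal to the
#' Euclidean distance rounded to the nearest Angstrom (half up) expressed in
#' deci-Angstrom integers, and 1 deci-A for overlapping IPAs (distance
#' rounding to 0).
#'
#' @param triplets an [ipa_triplets()] table with at least one row.
#' @param source provenance string stored on the graph.
#' @return object of class `interaction_graph`: `labels` (character),
#'   `weights` (symmetric integer matrix, deci-A), `source`.
#' @export
build_graph <- function(triplets, source = "") {
  if (is.null(triplets) || nrow(triplets) == 0) {
    stop("cannot build an interaction graph from zero triplets")
  }
  pts <- triplet_points(triplets)
  d <- as.matrix(stats::dist(pts$xyz))
  w <- round_half_up(d) * 10L
  w[w == 0L] <- 1L
  diag(w) <- 0L
  storage.mode(w) <- "integer"
  dimnames(w) <- NULL
  structure(list(labels = pts$labels, weights = w, source = source),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes (%d interactions)%s\n",
              length(x$labels), length(x$labels) / 3,
              if (nzchar(x$source)) paste0(" from ", x$source) else ""))
  invisible(x)
}

#' Drop hydrophobic interactions (Polar variant)
#'
#' Removes every HYD triplet and keeps all other types (aromatic and metal
#' included), preserving order.
#'
#' @param triplets an [ipa_triplets()] table.
#' @return filtered [ipa_triplets()] table.
#' @export
filter_polar <- function(triplets) {
  out <- triplets[triplets$itype != "HYD", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ipa_triplets", "data.frame")
  out
}

#' Write IPA triplets as a MOL2 pseudo-atom file
#'
#' One pseudo-atom per IPA. The atom name encodes the role (L/P/C plus the
#' interaction index), the residue name encodes the interaction type, and
#' the status-bit column carries the protein residue annotation
#' (`NAME.NUMBER`) and ligand atom id.
#'
#' @param triplets an [ipa_triplets()] table.
#' @param path output path; `NULL` returns lines only.
#' @return MOL2 lines, invisibly.
#' @export
write_ipa <- function(triplets, path = NULL) {
  n <- nrow(triplets)
  if (n == 0) {
    atoms <- data.frame(atom_id = integer(), name = character(),
                        x = numeric(), y = numeric(), z = numeric(),
                        sybyl_type = character(), res_id = integer(),
                        res_name = character(), charge = numeric())
  } else {
    role_xyz <- function(role, cols) {
      data.frame(name = paste0(role, seq_len(n)),
                 x = triplets[[cols[1]]], y = triplets[[cols[2]]],
                 z = triplets[[cols[3]]], stringsAsFactors = FALSE)
    }
    atoms <- rbind(role_xyz("L", c("lx", "ly", "lz")),
                   role_xyz("P", c("px", "py", "pz")),
                   role_xyz("C", c("cx", "cy", "cz")))
    idx <- rep(seq_len(n), 3)
    atoms$atom_id <- seq_len(3 * n)
    atoms$sybyl_type <- "Du"
    atoms$res_id <- idx
    atoms$res_name <- triplets$itype[idx]
    atoms$charge <- 0
    atoms$status <- sprintf("%s.%d/%d", triplets$res_name[idx],
                            triplets$res_id[idx], triplets$ligand_atom[idx])
  }
  st <- mol2_structure(atoms, NULL, "IPA")
  if (nrow(atoms)) st$atoms$status <- atoms$status
  write_mol2(st, path)
}

#' Read IPA triplets from a MOL2 pseudo-atom file
#'
#' Inverse of [write_ipa()]. Centre pseudo-atoms that are not at the
#' midpoint of their ligand/protein pair trigger a validation warning and
#' are recomputed.
#'
#' @param path file path, or `text` lines.
#' @param text optional character vector of MOL2 lines.
#' @return an [ipa_triplets()] table.
#' @export
read_ipa <- function(path = NULL, text = NULL) {
  st <- read_mol2(path, text)
  a <- st$atoms
  if (!nrow(a)) return(empty_triplets())
  role <- substr(a$name, 1, 1)
  if (!all(role %in% c("L", "P", "C"))) {
    stop("unknown IPA role code in atom names: ",
         paste(unique(role[!role %in% c("L", "P", "C")]), collapse = ", "))
  }
  if (!all(a$res_name %in% ITYPES)) {
    stop("unknown interaction type code: ",
         paste(unique(a$res_name[!a$res_name %in% ITYPES]), collapse = ", "))
  }
  idx <- as.integer(substring(a$name, 2))
  n <- max(idx)
  pick <- function(r) a[role == r, ][order(idx[role == r]), ]
  L <- pick("L"); P <- pick("P"); C <- pick("C")
  if (nrow(L) != n || nrow(P) != n || nrow(C) != n) {
    stop("incomplete IPA triplets in file")
  }
  ann <- L$status
  res_name <- sub("\\..*$", "", ann)
  rest <- sub("^[^.]*\\.", "", ann)
  res_id <- as.integer(sub("/.*$", "", rest))
  ligand_atom <- as.integer(sub("^.*/", "", rest))
  out <- ipa_triplets(L$res_name,
                      as.matrix(L[, c("x", "y", "z")]),
                      as.matrix(P[, c("x", "y", "z")]),
                      res_name, res_id, ligand_atom)
  ctr_file <- as.matrix(C[, c("x", "y", "z")])
  ctr_true <- as.matrix(out[, c("cx", "cy", "cz")])
  if (any(abs(ctr_file - ctr_true) > 5e-4)) {
    warning("centre IPA(s) not at the ligand/protein midpoint; recomputed")
  }
  out
}

#' Serialise an interaction graph to JSON
#'
#' @param graph an `interaction_graph`.
#' @param path output path; `NULL` returns the JSON string.
#' @return JSON string, invisibly.
#' @export
write_graph_json <- function(graph, path = NULL) {
  obj <- list(labels = graph$labels, weights = graph$weights,
              source = graph$source)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
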