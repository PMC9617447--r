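# Shortest-path graph kernel. A graph is summarised by the multiset of
# (node-label pair, shortest-path length) features over all unordered node
# pairs; two graphs are compared by the dot product (non-normalized, "nn")
# or the cosine (normalized) of their feature-count vectors. Path lengths
# are exact deci-Angstrom integers end to end.

#' All-pairs shortest path lengths of an interaction graph
#'
#' Rounding and the 0.1 A overlap rule can break the triangle inequality, so
#' direct edges are not assumed shortest: true shortest paths are computed
#' (Dijkstra per source via igraph).
#'
#' @param graph an `interaction_graph` from [build_graph()].
#' @return symmetric integer matrix of shortest-path lengths in deci-A.
#' @export
shortest_path_lengths <- function(graph) {
  w <- graph$weights
  n <- nrow(w)
  if (n == 1) return(matrix(0L, 1, 1))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  d <- round(d)
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' Fingerprint a graph by its shortest-path features
#'
#' Each unordered node pair contributes exactly one feature
#' `label_a|label_b|length` with labels in the fixed canonical order, so a
#' graph with n nodes yields counts summing to n(n-1)/2. Self-pairs
#' (distance-0 paths) are excluded.
#'
#' @param graph an `interaction_graph`.
#' @return named integer vector of feature counts, class `path_fingerprint`.
#' @export
sp_fingerprint <- function(graph) {
  sp <- shortest_path_lengths(graph)
  n <- length(graph$labels)
  lv <- node_label_levels()
  li <- match(graph$labels, lv)
  if (anyNA(li)) stop("unknown node label(s)")
  if (n < 2) {
    out <- integer(0)
    class(out) <- "path_fingerprint"
    return(out)
  }
  pairs <- which(upper.tri(sp), arr.ind = TRUE)
  a <- pmin(li[pairs[, 1]], li[pairs[, 2]])
  b <- pmax(li[pairs[, 1]], li[pairs[, 2]])
  keys <- paste(lv[a], lv[b], sp[pairs], sep = "|")
  tab <- table(keys)
  out <- stats::setNames(as.integer(tab), names(tab))
  class(out) <- "path_fingerprint"
  out
}

#' Learn a feature vocabulary from training fingerprints
#'
#' @param fps list of fingerprints from [sp_fingerprint()].
#' @return character vector of feature keys in a stable (sorted) order,
#'   class `sp_vocabulary`.
#' @export
fit_vocabulary <- function(fps) {
  v <- sort(unique(unlist(lapply(fps, names))))
  class(v) <- c("sp_vocabulary", class(v))
  v
}

fp_norm2 <- function(fp) sum(as.numeric(fp)^2)

#' Similarity between two path fingerprints
#'
#' Non-normalized mode is the dot product over shared features; normalized
#' mode is the cosine, each fingerprint's norm taken over its own full
#' feature set (this is exactly the "temporary vocabulary extension" of the
#' kernel: features unseen in one fingerprint contribute only to the other's
#' norm).
#'
#' @param fp1,fp2 fingerprints.
#' @param mode `"normalized"` (cosine) or `"nn"` (dot product).
#' @return numeric similarity; a zero-norm fingerprint in normalized mode
#'   yields 0 with a warning.
#' @export
sp_similarity <- function(fp1, fp2, mode = c("normalized", "nn")) {
  mode <- match.arg(mode)
  common <- intersect(names(fp1), names(fp2))
  nn <- sum(as.numeric(fp1[common]) * as.numeric(fp2[common]))
  if (mode == "nn") return(nn)
  n1 <- fp_norm2(fp1)
  n2 <- fp_norm2(fp2)
  if (n1 == 0 || n2 == 0) {
    warning("zero-norm fingerprint in normalized similarity; returning 0")
    return(0)
  }
  nn / sqrt(n1 * n2)
}

fp_matrix <- function(fps, vocab) {
  i <- unlist(lapply(seq_along(fps), function(k) rep(k, length(fps[[k]]))))
  j <- match(unlist(lapply(fps, names)), vocab)
  x <- as.numeric(unlist(fps, use.names = FALSE))
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                       dims = c(length(fps), length(vocab)))
}

#' Gram matrix over a set of fingerprints
#'
#' @param fps list of fingerprints.
#' @param mode `"normalized"` or `"nn"`.
#' @return symmetric matrix of kernel values with attribute `mode`;
#'   normalized mode has unit diagonal.
#' @export
sp_gram <- function(fps, mode = c("normalized", "nn")) {
  mode <- match.arg(mode)
  vocab <- fit_vocabulary(fps)
  M <- fp_matrix(fps, vocab)
  G <- as.matrix(Matrix::tcrossprod(M))
  if (mode == "normalized") {
    nrm <- sqrt(vapply(fps, fp_norm2, numeric(1)))
    zero <- nrm == 0
    if (any(zero)) {
      warning("zero-norm fingerprint(s) in normalized Gram; rows set to 0")
      nrm[zero] <- 1
    }
    G <- G / outer(nrm, nrm)
    if (any(zero)) G[zero, ] <- G[, zero] <- 0
    diag(G)[!zero] <- 1
  }
  attr(G, "mode") <- mode
  G
}

#' Cross-kernel between training fingerprints and query fingerprints
#'
#' In normalized mode the query norm is computed over the temporarily
#' extended vocabulary (its own full feature set); in nn mode features
#' absent from the training vocabulary are ignored entirely. The stored
#' vocabulary is never modified.
#'
#' @param train_fps list of training fingerprints.
#' @param query_fps one fingerprint or a list of fingerprints.
#' @param mode `"normalized"` or `"nn"`.
#' @return matrix with one row per training fingerprint and one column per
#'   query.
#' @export
sp_cross <- function(train_fps, query_fps, mode = c("normalized", "nn")) {
  mode <- match.arg(mode)
  if (inherits(query_fps, "path_fingerprint")) query_fps <- list(query_fps)
  out <- vapply(query_fps, function(q) {
    vapply(train_fps, sp_similarity, numeric(1), fp2 = q, mode = mode)
  }, numeric(length(train_fps)))
  matrix(out, nrow = length(train_fps))
}
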