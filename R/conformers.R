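# Binding-site definition over a frame series, pairwise binding-site RMSD,
# clustering of receptor conformations, and medoid selection of the
# representative structures used for docking.

#' Define the binding site of a frame series
#'
#' System-specific scope: every protein heavy atom lying strictly closer
#' than `cutoff` to any ligand heavy atom in at least `min_fraction` of the
#' frames. The RMSD equation used downstream has no superposition term, so
#' frames are assumed pre-aligned.
#'
#' @param frames list of [complex_frame()] objects sharing the protein
#'   topology.
#' @param cutoff distance cutoff in Angstroms (strict `<`).
#' @param min_fraction minimal fraction of frames (inclusive `>=`).
#' @return data.frame of class `binding_site` with columns `atom_id`,
#'   `name`, `res_name`, `res_id`, `fraction`.
#' @export
binding_site <- function(frames, cutoff = 4.5, min_fraction = 0.10) {
  stopifnot(length(frames) >= 1)
  pa <- frames[[1]]$protein$atoms
  heavy <- which(!pa$is_hydrogen)
  hits <- matrix(FALSE, length(heavy), length(frames))
  for (f in seq_along(frames)) {
    pf <- frames[[f]]$protein$atoms
    lf <- frames[[f]]$ligand$atoms
    if (nrow(pf) != nrow(pa)) stop("protein topology differs across frames")
    P <- as.matrix(pf[heavy, c("x", "y", "z")])
    L <- as.matrix(lf[!lf$is_hydrogen, c("x", "y", "z")])
    d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
    hits[, f] <- apply(sqrt(pmax(d2, 0)), 1, min) < cutoff
  }
  frac <- rowMeans(hits)
  sel <- heavy[frac >= min_fraction]
  if (!length(sel)) stop("empty binding-site selection")
  out <- data.frame(atom_id = pa$atom_id[sel], name = pa$name[sel],
                    res_name = pa$res_name[sel], res_id = pa$res_id[sel],
                    fraction = frac[frac >= min_fraction])
  class(out) <- c("binding_site", "data.frame")
  out
}

#' Residue-level union of system-specific binding sites
#'
#' The shared scope: all residues containing at least one atom present in
#' any of the supplied system-specific definitions.
#'
#' @param definitions list of [binding_site()] data.frames.
#' @return data.frame with columns `res_name`, `res_id`.
#' @export
shared_binding_site <- function(definitions) {
  res <- unique(do.call(rbind, lapply(definitions, function(d) {
    unique(d[, c("res_name", "res_id")])
  })))
  res <- res[order(res$res_id, res$res_name), ]
  rownames(res) <- NULL
  res
}

selection_coords <- function(frame, selection) {
  pa <- frame$protein$atoms
  i <- match(selection$atom_id, pa$atom_id)
  if (anyNA(i)) stop("selection atoms missing from frame")
  as.matrix(pa[i, c("x", "y", "z")])
}

#' Pairwise binding-site RMSD matrix
#'
#' Plain coordinate RMSD `sqrt(sum((X_i - Y_i)^2) / N)` over the selected
#' atoms, without superposition.
#'
#' @param frames list of [complex_frame()] objects.
#' @param selection a [binding_site()] selection resolvable in every frame.
#' @return symmetric matrix of RMSD values in Angstroms (class `rmsd_matrix`
#'   attribute set).
#' @export
pairwise_rmsd <- function(frames, selection) {
  coords <- lapply(frames, selection_coords, selection = selection)
  N <- nrow(coords[[1]])
  if (!all(vapply(coords, nrow, integer(1)) == N)) {
    stop("selection atom count differs across frames")
  }
  nf <- length(frames)
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    m[i, j] <- m[j, i] <- sqrt(sum((coords[[i]] - coords[[j]])^2) / N)
  }
  attr(m, "frame_index") <- vapply(frames, `[[`, integer(1), "frame_index")
  m
}

cluster_medoids <- function(m, labels) {
  vapply(sort(unique(labels)), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(rowSums(m[idx, idx, drop = FALSE]))]
  }, integer(1))
}

#' Cluster conformations from a distance matrix
#'
#' Agglomerative hierarchical clustering with average linkage, or PAM
#' k-medoids (deterministic BUILD + SWAP, so results do not depend on
#' `seed`; the argument is kept for interface stability). Medoids are always
#' recomputed as the exhaustive row-sum minimiser within each cluster.
#'
#' @param m symmetric distance matrix.
#' @param method `"hierarchical_average"` or `"kmedoids"`.
#' @param k number of clusters, `2 <= k <= nrow(m)`.
#' @param seed unused by the deterministic algorithms; kept in the API.
#' @return list of class `cluster_assignment`: `labels`, `k`, `medoids`.
#' @export
cluster_frames <- function(m, method = c("hierarchical_average", "kmedoids"),
                           k, seed = 1L) {
  method <- match.arg(method)
  n <- nrow(m)
  if (k > n) stop("k exceeds the number of frames")
  if (k < 2) stop("k must be at least 2")
  if (all(m == 0)) {
    warning("zero distance matrix: degenerate, arbitrary split returned")
    labels <- rep(1L, n)
    labels[seq_len(k)] <- seq_len(k)
  } else if (method == "hierarchical_average") {
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    labels <- stats::cutree(hc, k = k)
  } else {
    pm <- cluster::pam(stats::as.dist(m), k = k, diss = TRUE,
                       cluster.only = TRUE)
    labels <- as.integer(pm)
  }
  structure(list(labels = as.integer(labels), k = k,
                 medoids = cluster_medoids(m, labels), method = method),
            class = "cluster_assignment")
}

#' Internal clustering quality indices from a distance matrix
#'
#' Silhouette (mean width), Dunn index (minimum inter-cluster distance over
#' maximum intra-cluster diameter), and Davies-Bouldin index with medoids as
#' cluster centres.
#'
#' @param m symmetric distance matrix.
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @return named numeric vector `(silhouette, dunn, davies_bouldin)`.
#' @export
cluster_quality <- function(m, labels) {
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("need at least 2 clusters")
  if (all(tabulate(match(labels, cls)) == 1)) {
    stop("silhouette undefined for singleton-only clusterings")
  }
  sil <- mean(cluster::silhouette(labels, dmatrix = m)[, "sil_width"])
  inter <- Inf
  for (a in seq_along(cls)) for (b in seq_along(cls)) {
    if (a < b) {
      ia <- labels == cls[a]; ib <- labels == cls[b]
      inter <- min(inter, min(m[ia, ib]))
    }
  }
  diam <- max(vapply(cls, function(cl) {
    idx <- labels == cl
    if (sum(idx) < 2) 0 else max(m[idx, idx])
  }, numeric(1)))
  dunn <- if (diam == 0) Inf else inter / diam
  med <- cluster_medoids(m, labels)
  S <- vapply(seq_along(cls), function(a) {
    mean(m[labels == cls[a], med[a]])
  }, numeric(1))
  db <- mean(vapply(seq_along(cls), function(a) {
    max(vapply(setdiff(seq_along(cls), a), function(b) {
      (S[a] + S[b]) / m[med[a], med[b]]
    }, numeric(1)))
  }, numeric(1)))
  c(silhouette = sil, dunn = dunn, davies_bouldin = db)
}

#' Choose the number of clusters by majority vote of three indices
#'
#' Each index (max silhouette, max Dunn, min Davies-Bouldin) votes for its
#' preferred k in `k_range`; the k with the most votes wins, ties broken
#' toward smaller k.
#'
#' @param m symmetric distance matrix.
#' @param method clustering method passed to [cluster_frames()].
#' @param k_range integer vector of candidate k values.
#' @param seed passed through to [cluster_frames()].
#' @return the selected k.
#' @export
choose_k <- function(m, method = "kmedoids", k_range = 2:10, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= nrow(m) - 1]
  if (!length(k_range)) stop("empty usable k_range")
  q <- t(vapply(k_range, function(k) {
    cluster_quality(m, cluster_frames(m, method, k, seed)$labels)
  }, numeric(3)))
  votes <- c(k_range[which.max(q[, "silhouette"])],
             k_range[which.max(q[, "dunn"])],
             k_range[which.min(q[, "davies_bouldin"])])
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}
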