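# Screening pipeline: pose scoring aggregation to molecule decisions,
# precision/recall/F1 evaluation, the binary interaction-fingerprint (IFP)
# Tanimoto baseline, and the F1-maximising threshold sweep.

#' Aggregate pose predictions into a molecule decision
#'
#' A molecule is classified as an agonist iff at least one of its poses
#' (all stereoisomers pooled, and in ensemble mode all representative
#' receptor structures pooled) is an inlier.
#'
#' @param inlier logical vector of per-pose inlier predictions for one
#'   molecule (or numeric scores, where score >= 0 means inlier).
#' @return `"agonist"` or `"non_agonist"`.
#' @export
classify_molecule <- function(inlier) {
  if (!length(inlier)) {
    warning("molecule with zero poses classified as non_agonist")
    return("non_agonist")
  }
  if (is.numeric(inlier)) inlier <- inlier >= 0
  if (any(inlier)) "agonist" else "non_agonist"
}

#' Molecule decisions from a pose score table
#'
#' @param poses data.frame with columns `molecule_id` and `score` (signed
#'   decision values; >= 0 is an inlier). Rows may span stereoisomers,
#'   poses and receptor structures; the union rule pools them all.
#' @return data.frame (`molecule_id`, `decision`).
#' @export
classify_molecules <- function(poses) {
  ids <- unique(poses$molecule_id)
  dec <- vapply(ids, function(m) {
    classify_molecule(poses$score[poses$molecule_id == m])
  }, character(1))
  data.frame(molecule_id = ids, decision = dec, stringsAsFactors = FALSE)
}

round_half_up2 <- function(x) floor(x * 100 + 0.5) / 100

#' Evaluate molecule decisions against activity labels
#'
#' The positive class is `agonist`; both `antagonist` and `inactive` labels
#' count as non-agonist. Conventions for empty selections: precision 0 when
#' nothing is selected, F1 0 when precision + recall = 0.
#'
#' @param decisions data.frame (`molecule_id`, `decision`) with decisions
#'   `"agonist"`/`"non_agonist"`, e.g. from [classify_molecules()].
#' @param labels data.frame (`molecule_id`, `class`) with classes
#'   `agonist`, `antagonist` or `inactive`.
#' @return list of class `screening_metrics`: `counts` (TP, FP, FN, TN),
#'   `precision`, `recall`, `f1`, `n_selected`, `n_total`.
#' @export
evaluate_screen <- function(decisions, labels) {
  i <- match(decisions$molecule_id, labels$molecule_id)
  if (anyNA(i)) {
    stop("unlabeled molecule(s): ",
         paste(decisions$molecule_id[is.na(i)], collapse = ", "))
  }
  truth <- labels$class[i] == "agonist"
  pred <- decisions$decision == "agonist"
  counts <- c(TP = sum(pred & truth), FP = sum(pred & !truth),
              FN = sum(!pred & truth), TN = sum(!pred & !truth))
  precision <- if (sum(pred) == 0) 0 else counts[["TP"]] / sum(pred)
  recall <- if (sum(truth) == 0) 0 else counts[["TP"]] / sum(truth)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(counts = counts, precision = precision, recall = recall,
                 f1 = f1, n_selected = sum(pred),
                 n_total = nrow(decisions)),
            class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf("precision %.2f  recall %.2f  F1 %.2f  size %d/%d\n",
              round_half_up2(x$precision), round_half_up2(x$recall),
              round_half_up2(x$f1), x$n_selected, x$n_total))
  invisible(x)
}

ifp_bit_names <- function(residue_universe) {
  as.vector(t(outer(residue_universe, ITYPES, paste, sep = "|")))
}

#' Binary interaction fingerprint of one frame/pose
#'
#' One bit per (binding-site residue, interaction type): set iff at least
#' one triplet of that type involves that protein residue.
#'
#' @param triplets an [ipa_triplets()] table.
#' @param residue_universe character vector of residue keys
#'   (`NAME.NUMBER`); must cover every residue in `triplets`.
#' @return named 0/1 integer vector of class `binary_ifp`.
#' @export
compute_ifp <- function(triplets, residue_universe) {
  bits <- stats::setNames(integer(length(residue_universe) * length(ITYPES)),
                          ifp_bit_names(residue_universe))
  if (nrow(triplets)) {
    res <- paste(triplets$res_name, triplets$res_id, sep = ".")
    if (!all(res %in% residue_universe)) {
      stop("residue(s) outside the universe: ",
           paste(unique(res[!res %in% residue_universe]), collapse = ", "))
    }
    bits[unique(paste(res, triplets$itype, sep = "|"))] <- 1L
  }
  class(bits) <- "binary_ifp"
  bits
}

#' Average interaction fingerprint over frames
#'
#' Per-bit frequency over a list of binary IFPs, with a display mask: shown
#' iff observed in at least `min_fraction` of the frames or present in the
#' supplied crystallographic IFP. The mask affects reporting only.
#'
#' @param ifps list of [compute_ifp()] vectors over one universe.
#' @param min_fraction display threshold (default 0.10).
#' @param crystal optional crystallographic `binary_ifp`.
#' @return data.frame (`bit`, `frequency`, `shown`).
#' @export
average_ifp <- function(ifps, min_fraction = 0.10, crystal = NULL) {
  stopifnot(length(ifps) >= 1)
  M <- do.call(rbind, lapply(ifps, as.integer))
  freq <- colMeans(M)
  shown <- freq >= min_fraction
  if (!is.null(crystal)) shown <- shown | as.integer(crystal) == 1L
  data.frame(bit = names(ifps[[1]]), frequency = freq, shown = shown,
             row.names = NULL)
}

#' Tanimoto similarity between two binary IFPs
#'
#' @param a,b [compute_ifp()] vectors over the same universe.
#' @return `|a AND b| / |a OR b|`; 0 with a warning when both are empty.
#' @export
ifp_tanimoto <- function(a, b) {
  if (!identical(names(a), names(b))) stop("IFP universe mismatch")
  a <- as.integer(a); b <- as.integer(b)
  u <- sum(a | b)
  if (u == 0) {
    warning("both IFPs empty; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / u
}

#' F1-maximising score threshold
#'
#' Sweeps thresholds over the midpoints of consecutive sorted unique
#' molecule scores (plus the minimum score itself, i.e. the select-all
#' baseline); a molecule is selected when `score >= threshold`. Among ties
#' the lowest threshold is returned.
#'
#' @param scores named numeric vector of per-molecule scores (names are
#'   molecule ids) or data.frame (`molecule_id`, `score`).
#' @param labels label table as in [evaluate_screen()].
#' @return list (`threshold`, `metrics`).
#' @export
optimal_threshold <- function(scores, labels) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$molecule_id)
  }
  u <- sort(unique(scores))
  if (length(u) == 1) {
    warning("all scores identical; degenerate threshold")
    cands <- u
  } else {
    cands <- c(u[1], (u[-1] + u[-length(u)]) / 2)
  }
  best <- NULL
  for (thr in cands) {
    dec <- data.frame(
      molecule_id = names(scores),
      decision = ifelse(scores >= thr, "agonist", "non_agonist"),
      stringsAsFactors = FALSE
    )
    met <- evaluate_screen(dec, labels)
    if (is.null(best) || met$f1 > best$metrics$f1 + 1e-12) {
      best <- list(threshold = thr, metrics = met)
    }
  }
  best
}
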