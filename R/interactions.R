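# Geometric detection of the seven protein-ligand interaction types and
# their encoding as interaction pseudo-atom (IPA) triplets: one point on the
# ligand atom (or ring centroid), one on the protein atom, one at the exact
# midpoint of the segment they define.

ITYPES <- c("HBA", "HBD", "ION_PPLUS", "ION_PMINUS", "ARO", "HYD", "MET")

#' Geometric thresholds for interaction detection
#'
#' The reference interaction-detection program does not publish its
#' thresholds; these defaults are conventional values and everything is
#' configurable. Distances in Angstroms, angles in degrees. The reference
#' pipeline of the source method widens the aromatic threshold to 5.0
#' (`aro_dist_max = 5.0`).
#'
#' @param hb_dist_max heavy-atom donor-acceptor distance cap for H-bonds.
#' @param hb_angle_min minimum donor-H-acceptor angle; when the donor has no
#'   explicit hydrogen the angle test is skipped with a warning.
#' @param ionic_dist_max cation-anion distance cap.
#' @param aro_dist_max ring centroid-centroid distance cap (the D_Ar knob).
#' @param aro_ftf_angle_max maximum inter-normal angle for face-to-face
#'   stacking.
#' @param aro_etf_angle_min minimum inter-normal angle for edge-to-face
#'   stacking.
#' @param hydrophobic_dist_max hydrophobic heavy-atom contact cap.
#' @param metal_dist_max metal-chelator distance cap.
#' @param hydrophobic_mode "hyd" accepts every C/S heavy atom; "newhyd"
#'   additionally requires a hydrophobic bonded environment
#'   (see [hydrophobic_environment()]).
#' @return list of class `geometry_config`.
#' @export
geometry_config <- function(hb_dist_max = 3.5, hb_angle_min = 120,
                            ionic_dist_max = 4.0, aro_dist_max = 4.0,
                            aro_ftf_angle_max = 30, aro_etf_angle_min = 60,
                            hydrophobic_dist_max = 4.5, metal_dist_max = 2.8,
                            hydrophobic_mode = c("hyd", "newhyd")) {
  hydrophobic_mode <- match.arg(hydrophobic_mode)
  cfg <- list(hb_dist_max = hb_dist_max, hb_angle_min = hb_angle_min,
              ionic_dist_max = ionic_dist_max, aro_dist_max = aro_dist_max,
              aro_ftf_angle_max = aro_ftf_angle_max,
              aro_etf_angle_min = aro_etf_angle_min,
              hydrophobic_dist_max = hydrophobic_dist_max,
              metal_dist_max = metal_dist_max,
              hydrophobic_mode = hydrophobic_mode)
  dists <- unlist(cfg[grepl("dist", names(cfg))])
  if (any(dists <= 0)) stop("distance thresholds must be positive")
  angs <- c(hb_angle_min, aro_ftf_angle_max, aro_etf_angle_min)
  if (any(angs < 0 | angs > 180)) stop("angles must lie in [0, 180]")
  class(cfg) <- "geometry_config"
  cfg
}

#' Build an IPA triplet table
#'
#' @param itype character vector of interaction types (subset of
#'   `HBA, HBD, ION_PPLUS, ION_PMINUS, ARO, HYD, MET`).
#' @param lig,prot numeric matrices (n x 3) of ligand- and protein-side IPA
#'   coordinates.
#' @param res_name,res_id protein residue annotation.
#' @param ligand_atom ligand atom id (ring index for ARO).
#' @return data.frame of class `ipa_triplets`; centre points are computed as
#'   exact midpoints.
#' @export
ipa_triplets <- function(itype, lig, prot, res_name = "UNK", res_id = 0L,
                         ligand_atom = 0L) {
  lig <- matrix(as.numeric(lig), ncol = 3)
  prot <- matrix(as.numeric(prot), ncol = 3)
  stopifnot(length(itype) == nrow(lig), nrow(lig) == nrow(prot),
            all(itype %in% ITYPES))
  ctr <- (lig + prot) / 2
  out <- data.frame(
    itype = as.character(itype),
    lx = lig[, 1], ly = lig[, 2], lz = lig[, 3],
    px = prot[, 1], py = prot[, 2], pz = prot[, 3],
    cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
    res_name = rep_len(as.character(res_name), length(itype)),
    res_id = rep_len(as.integer(res_id), length(itype)),
    ligand_atom = rep_len(as.integer(ligand_atom), length(itype)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ipa_triplets", "data.frame")
  out
}

empty_triplets <- function() {
  ipa_triplets(character(), matrix(numeric(), ncol = 3),
               matrix(numeric(), ncol = 3), character(), integer(), integer())
}

rbind_triplets <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(parts)) return(empty_triplets())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("ipa_triplets", "data.frame")
  rownames(out) <- NULL
  out
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Is an atom in a hydrophobic bonded environment?
#'
#' Operationalisation of the stricter ("newhyd") hydrophobic-contact
#' eligibility: a C or S heavy atom qualifies iff none of its bonded heavy
#' neighbours is nitrogen, oxygen, or a charged atom. An atom with no heavy
#' neighbours qualifies vacuously. This approximates an unpublished rule of
#' the reference program.
#'
#' @param atom_id atom id within `structure`.
#' @param structure a [mol2_structure()].
#' @param flags optional perception flags (from [perceive_chemistry()]) used
#'   to identify charged neighbours.
#' @return logical.
#' @export
hydrophobic_environment <- function(atom_id, structure, flags = NULL) {
  a <- structure$atoms
  nb <- bonded_ids(structure, atom_id)
  nb <- nb[!a$is_hydrogen[match(nb, a$atom_id)]]
  if (!length(nb)) return(TRUE)
  i <- match(nb, a$atom_id)
  bad <- a$element[i] %in% c("N", "O")
  if (!is.null(flags)) {
    j <- match(nb, flags$atom_id)
    bad <- bad | flags$cation[j] | flags$anion[j]
  }
  !any(bad)
}

hb_pairs <- function(donor_struct, donor_flags, acceptor_struct,
                     acceptor_flags, cfg) {
  da <- donor_struct$atoms
  aa <- acceptor_struct$atoms
  don <- donor_flags$atom_id[donor_flags$hbond_donor]
  acc <- acceptor_flags$atom_id[acceptor_flags$hbond_acceptor]
  if (!length(don) || !length(acc)) return(NULL)
  out <- list()
  warned <- FALSE
  for (d in don) {
    di <- match(d, da$atom_id)
    dxyz <- as.numeric(da[di, c("x", "y", "z")])
    hs <- bonded_ids(donor_struct, d)
    hs <- hs[da$is_hydrogen[match(hs, da$atom_id)]]
    for (ac in acc) {
      ai <- match(ac, aa$atom_id)
      axyz <- as.numeric(aa[ai, c("x", "y", "z")])
      if (sqrt(sum((dxyz - axyz)^2)) > cfg$hb_dist_max) next
      if (length(hs)) {
        angles <- vapply(hs, function(h) {
          hxyz <- as.numeric(da[match(h, da$atom_id), c("x", "y", "z")])
          vec_angle(dxyz - hxyz, axyz - hxyz)
        }, numeric(1))
        if (max(angles) < cfg$hb_angle_min) next
      } else if (!warned) {
        warning("donor without explicit hydrogen: distance-only H-bond test")
        warned <- TRUE
      }
      out[[length(out) + 1L]] <- list(donor = d, acceptor = ac,
                                      dxyz = dxyz, axyz = axyz)
    }
  }
  out
}

#' Detect protein-ligand interactions in a frame
#'
#' Emits one IPA triplet per qualifying pair: hydrogen bonds split by
#' direction (`HBA` protein acceptor, `HBD` protein donor), ionic contacts
#' split by the protein charge sign (`ION_PPLUS` protein cation,
#' `ION_PMINUS` protein anion), aromatic stacking between ring centroids
#' (face-to-face or edge-to-face by inter-normal angle), hydrophobic
#' heavy-atom contacts (mode-dependent eligibility), and metal chelation.
#' An interaction that satisfies both the ionic and the H-bond geometry is
#' emitted as both.
#'
#' @param frame a [complex_frame()].
#' @param config a [geometry_config()].
#' @param ann_p,ann_l optional precomputed [perceive_chemistry()] annotations
#'   for the protein and the ligand.
#' @return an [ipa_triplets()] table.
#' @export
detect_interactions <- function(frame, config = geometry_config(),
                                ann_p = NULL, ann_l = NULL) {
  p <- frame$protein
  l <- frame$ligand
  if (is.null(ann_p)) ann_p <- perceive_chemistry(p)
  if (is.null(ann_l)) ann_l <- perceive_chemistry(l)
  fp <- ann_p$flags
  fl <- ann_l$flags
  pa <- p$atoms
  la <- l$atoms
  res_of <- function(atom_id) {
    i <- match(atom_id, pa$atom_id)
    list(name = pa$res_name[i], id = pa$res_id[i])
  }
  parts <- list()

  # hydrogen bonds, protein acceptor (HBA): ligand donates
  for (hb in hb_pairs(l, fl, p, fp, config) %||% list()) {
    r <- res_of(hb$acceptor)
    parts[[length(parts) + 1L]] <- ipa_triplets(
      "HBA", hb$dxyz, hb$axyz, r$name, r$id, hb$donor)
  }
  # hydrogen bonds, protein donor (HBD)
  for (hb in hb_pairs(p, fp, l, fl, config) %||% list()) {
    r <- res_of(hb$donor)
    parts[[length(parts) + 1L]] <- ipa_triplets(
      "HBD", hb$axyz, hb$dxyz, r$name, r$id, hb$acceptor)
  }

  ion_pairs <- function(p_ids, l_ids, itype, dmax) {
    for (pi in p_ids) for (li in l_ids) {
      pxyz <- as.numeric(pa[match(pi, pa$atom_id), c("x", "y", "z")])
      lxyz <- as.numeric(la[match(li, la$atom_id), c("x", "y", "z")])
      if (sqrt(sum((pxyz - lxyz)^2)) <= dmax) {
        r <- res_of(pi)
        parts[[length(parts) + 1L]] <<- ipa_triplets(
          itype, lxyz, pxyz, r$name, r$id, li)
      }
    }
  }
  ion_pairs(fp$atom_id[fp$cation & !fp$metal], fl$atom_id[fl$anion],
            "ION_PPLUS", config$ionic_dist_max)
  ion_pairs(fp$atom_id[fp$anion], fl$atom_id[fl$cation & !fl$metal],
            "ION_PMINUS", config$ionic_dist_max)

  # aromatic stacking between ring centroids
  if (length(ann_p$rings) && length(ann_l$rings)) {
    for (ri in seq_along(ann_l$rings)) {
      lr <- ann_l$rings[[ri]]
      for (pr in ann_p$rings) {
        d <- sqrt(sum((lr$centroid - pr$centroid)^2))
        if (d > config$aro_dist_max) next
        ang <- vec_angle(lr$normal, pr$normal)
        ang <- min(ang, 180 - ang)  # normals are sign-ambiguous
        if (ang <= config$aro_ftf_angle_max ||
            ang >= config$aro_etf_angle_min) {
          r <- res_of(pr$members[1])
          parts[[length(parts) + 1L]] <- ipa_triplets(
            "ARO", lr$centroid, pr$centroid, r$name, r$id, ri)
        }
      }
    }
  }

  # hydrophobic contacts
  ph <- fp$atom_id[fp$hydrophobic]
  lh <- fl$atom_id[fl$hydrophobic]
  if (config$hydrophobic_mode == "newhyd") {
    ph <- ph[vapply(ph, hydrophobic_environment, logical(1),
                    structure = p, flags = fp)]
    lh <- lh[vapply(lh, hydrophobic_environment, logical(1),
                    structure = l, flags = fl)]
  }
  for (pi in ph) for (li in lh) {
    pxyz <- as.numeric(pa[match(pi, pa$atom_id), c("x", "y", "z")])
    lxyz <- as.numeric(la[match(li, la$atom_id), c("x", "y", "z")])
    if (sqrt(sum((pxyz - lxyz)^2)) <= config$hydrophobic_dist_max) {
      r <- res_of(pi)
      parts[[length(parts) + 1L]] <- ipa_triplets(
        "HYD", lxyz, pxyz, r$name, r$id, li)
    }
  }

  # metal chelation (either side may carry the metal)
  met_pairs <- function(met_ids, che_ids, met_on_protein) {
    for (mi in met_ids) for (ci in che_ids) {
      if (met_on_protein) {
        pxyz <- as.numeric(pa[match(mi, pa$atom_id), c("x", "y", "z")])
        lxyz <- as.numeric(la[match(ci, la$atom_id), c("x", "y", "z")])
        rid <- mi; lid <- ci
      } else {
        pxyz <- as.numeric(pa[match(ci, pa$atom_id), c("x", "y", "z")])
        lxyz <- as.numeric(la[match(mi, la$atom_id), c("x", "y", "z")])
        rid <- ci; lid <- mi
      }
      if (sqrt(sum((pxyz - lxyz)^2)) <= config$metal_dist_max) {
        r <- res_of(rid)
        parts[[length(parts) + 1L]] <<- ipa_triplets(
          "MET", lxyz, pxyz, r$name, r$id, lid)
      }
    }
  }
  chel_l <- fl$atom_id[(fl$hbond_acceptor | fl$anion) & !fl$metal]
  chel_p <- fp$atom_id[(fp$hbond_acceptor | fp$anion) & !fp$metal]
  met_pairs(fp$atom_id[fp$metal], chel_l, TRUE)
  met_pairs(fl$atom_id[fl$metal], chel_p, FALSE)

  do.call(rbind_triplets, parts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count interactions by type
#'
#' @param triplets an [ipa_triplets()] table.
#' @return named integer vector over all seven types (zeros included), with
#'   attribute `n_ipa` = 3 x total interactions.
#' @export
count_by_type <- function(triplets) {
  counts <- table(factor(triplets$itype, levels = ITYPES))
  out <- stats::setNames(as.integer(counts), ITYPES)
  attr(out, "n_ipa") <- 3L * sum(out)
  out
}
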