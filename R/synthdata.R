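# Synthetic test data: a conserved-interaction binding-mode template
# (emulating the statistical structure of an agonist-receptor MD ensemble,
# where the key interactions are the best conserved), simulated trajectories
# of IPA triplet frames, decoy poses, and geometric micro-fixtures for the
# interaction-detection thresholds. Residue names reuse ADRB2-style labels
# purely as readable identifiers.

#' Default binding-mode template
#'
#' An ADRB2-agonist-like template: ionic and hydrogen-bond anchors to
#' "Asp113" (always present), hydrogen bonds to "Asn312" (p = 0.9) and
#' "Ser207" (p = 0.8), three hydrophobic contacts (p = 0.6-0.8) and one
#' aromatic stacking (p = 0.5), with anchor coordinates spanning roughly
#' 10 Angstroms.
#'
#' @return data.frame of class `binding_mode_template` with columns `itype`,
#'   `lx..lz`, `px..pz`, `res_name`, `res_id`, `p`.
#' @export
default_template <- function() {
  tpl <- data.frame(
    itype = c("ION_PMINUS", "HBD", "HBA", "HBD", "HBA",
              "HYD", "HYD", "HYD", "ARO"),
    lx = c(0.0, 0.5, 1.5, 2.0, 7.5, 4.0, 5.0, 6.5, 6.3),
    ly = c(0.0, 0.3, -0.5, 0.5, 0.5, 0.0, 1.0, -1.0, 0.0),
    lz = c(0.0, 0.5, 1.0, -0.8, 0.0, 0.5, -0.5, 0.8, 0.0),
    px = c(0.0, 0.2, 1.8, 2.4, 8.5, 4.2, 5.5, 7.0, 6.5),
    py = c(3.5, 3.4, -3.2, 3.0, 3.2, -3.5, 3.6, -3.8, 0.5),
    pz = c(0.0, 0.8, 1.5, -1.5, 0.5, 1.0, -1.2, 1.2, 3.8),
    res_name = c("ASP", "ASP", "ASN", "ASN", "SER", "VAL", "PHE", "PHE",
                 "PHE"),
    res_id = c(113L, 113L, 312L, 312L, 207L, 114L, 290L, 193L, 290L),
    p = c(1.0, 1.0, 0.9, 0.9, 0.8, 0.8, 0.7, 0.6, 0.5),
    stringsAsFactors = FALSE
  )
  class(tpl) <- c("binding_mode_template", "data.frame")
  tpl
}

#' Simulation configuration
#'
#' @param n_frames number of frames (>= 1).
#' @param jitter_sigma isotropic Gaussian positional noise (Angstroms)
#'   applied independently to each included IPA endpoint coordinate.
#' @param spurious_rate Poisson mean of extra random interactions per frame.
#' @param seed RNG seed; a fixed seed makes output bit-reproducible.
#' @param displace_mag protein-anchor displacement magnitude used by
#'   displacement decoys (must be >= 3).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_frames = 100L, jitter_sigma = 0.5,
                       spurious_rate = 0.5, seed = 1L, displace_mag = 5) {
  stopifnot(n_frames >= 1, jitter_sigma >= 0, spurious_rate >= 0)
  structure(list(n_frames = as.integer(n_frames),
                 jitter_sigma = jitter_sigma,
                 spurious_rate = spurious_rate, seed = as.integer(seed),
                 displace_mag = displace_mag),
            class = "sim_config")
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

template_frame <- function(template, include, sigma, spurious_rate) {
  t_inc <- template[include, , drop = FALSE]
  n <- nrow(t_inc)
  lig <- as.matrix(t_inc[, c("lx", "ly", "lz")]) +
    matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3)
  prot <- as.matrix(t_inc[, c("px", "py", "pz")]) +
    matrix(stats::rnorm(3 * n, sd = sigma), ncol = 3)
  out <- ipa_triplets(t_inc$itype, lig, prot, t_inc$res_name, t_inc$res_id,
                      seq_len(nrow(template))[include])
  n_spu <- stats::rpois(1, spurious_rate)
  if (n_spu > 0) {
    centroid <- colMeans(as.matrix(template[, c("lx", "ly", "lz")]))
    spu <- lapply(seq_len(n_spu), function(i) {
      lp <- centroid + random_unit() * stats::runif(1, 0, 8)
      pp <- lp + random_unit() * stats::runif(1, 2.5, 4.5)
      ipa_triplets(sample(ITYPES, 1), lp, pp, "SPU",
                   900L + sample.int(50L, 1), 99L)
    })
    out <- do.call(rbind_triplets, c(list(out), spu))
  }
  out
}

#' Simulate a trajectory of IPA triplet frames
#'
#' Per frame each template interaction is included independently with its
#' conservation probability p, included endpoints are jittered with
#' isotropic Gaussian noise, centres are recomputed as exact midpoints, and
#' Poisson-many spurious interactions of random type are added within 8
#' Angstroms of the template centroid (so they pollute the same graph
#' scale). Fully seeded and reproducible.
#'
#' @param template a [default_template()]-style data.frame.
#' @param config a [sim_config()].
#' @return list of [ipa_triplets()] tables, one per frame.
#' @export
simulate_trajectory <- function(template, config = sim_config()) {
  set.seed(config$seed)
  lapply(seq_len(config$n_frames), function(f) {
    include <- stats::runif(nrow(template)) < template$p
    if (!any(include)) include[which.max(template$p)] <- TRUE
    template_frame(template, include, config$jitter_sigma,
                   config$spurious_rate)
  })
}

#' Generate decoy poses from a template
#'
#' Three decoy mechanisms emulating non-agonist docking poses:
#' `type_swap` permutes the interaction types among the template positions,
#' `displace` translates every protein-side anchor by a random direction of
#' fixed magnitude (>= 3 Angstroms), and `subset` keeps only the least
#' conserved half of the interactions (preferentially dropping the p >= 0.8
#' anchors). All modes then apply the usual conservation/jitter sampling.
#'
#' @param template a [default_template()]-style data.frame.
#' @param n number of decoy poses.
#' @param mode `"type_swap"`, `"displace"`, or `"subset"`.
#' @param config a [sim_config()].
#' @return list of [ipa_triplets()] tables.
#' @export
make_decoys <- function(template, n,
                        mode = c("type_swap", "displace", "subset"),
                        config = sim_config()) {
  mode <- match.arg(mode)
  if (mode == "displace" && config$displace_mag < 3) {
    stop("displacement decoys require displace_mag >= 3")
  }
  set.seed(config$seed)
  lapply(seq_len(n), function(i) {
    tpl <- template
    if (mode == "type_swap") {
      repeat {
        perm <- sample.int(nrow(tpl))
        if (any(perm != seq_len(nrow(tpl)))) break
      }
      tpl$itype <- tpl$itype[perm]
    } else if (mode == "displace") {
      shift <- random_unit() * config$displace_mag
      tpl$px <- tpl$px + shift[1]
      tpl$py <- tpl$py + shift[2]
      tpl$pz <- tpl$pz + shift[3]
    } else {
      # drop the strongly conserved anchors (p >= 0.8) first, and never
      # keep more than half of the interactions
      keep <- which(tpl$p < 0.8)
      cap <- max(1L, floor(nrow(tpl) / 2))
      if (length(keep) > cap) keep <- keep[order(tpl$p[keep])][seq_len(cap)]
      if (!length(keep)) keep <- which.min(tpl$p)
      tpl <- tpl[sort(keep), , drop = FALSE]
    }
    include <- stats::runif(nrow(tpl)) < tpl$p
    if (!any(include)) include[which.max(tpl$p)] <- TRUE
    template_frame(tpl, include, config$jitter_sigma, config$spurious_rate)
  })
}

hexagon <- function(centre, radius = 1.4, tilt_deg = 0) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  xyz <- cbind(radius * cos(ang), radius * sin(ang), 0)
  if (tilt_deg != 0) {
    th <- tilt_deg * pi / 180
    R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
    xyz <- xyz %*% t(R)
  }
  sweep(xyz, 2, centre, "+")
}

ring_structure <- function(centre, mol_name, res_name, tilt_deg = 0,
                           id0 = 0L) {
  xyz <- hexagon(centre, tilt_deg = tilt_deg)
  atoms <- data.frame(atom_id = id0 + 1:6, name = paste0("C", 1:6),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      sybyl_type = "C.ar", res_id = 1L, res_name = res_name)
  bonds <- data.frame(a1 = id0 + 1:6, a2 = id0 + c(2:6, 1), order = "ar")
  mol2_structure(atoms, bonds, mol_name)
}

#' Minimal geometric fixture for interaction detection
#'
#' Builds a tiny protein/ligand pair presenting exactly one candidate
#' interaction of the requested kind at the requested geometry.
#'
#' @param kind `"hbond"` (ligand donor, protein acceptor; `angle` is the
#'   donor-H-acceptor angle), `"ionic"` (protein carboxylate, ligand
#'   ammonium), `"aromatic"` (two rings, centroid distance `distance`,
#'   inter-normal angle `angle`), `"hydrophobic"` (two aliphatic carbons),
#'   or `"metal"` (protein zinc, ligand hydroxyl oxygen).
#' @param distance heavy-atom (or centroid) separation in Angstroms.
#' @param angle interaction angle in degrees where applicable.
#' @param ligand_env for `"hydrophobic"`: `"apolar"` keeps the ligand carbon
#'   unsubstituted; `"polar"` bonds it to an oxygen so the stricter
#'   environment rule rejects it.
#' @return a [complex_frame()].
#' @export
geometry_fixture <- function(kind = c("hbond", "ionic", "aromatic",
                                      "hydrophobic", "metal"),
                             distance, angle = 180,
                             ligand_env = c("apolar", "polar")) {
  kind <- match.arg(kind)
  ligand_env <- match.arg(ligand_env)
  if (distance <= 0) stop("impossible geometry: non-positive distance")
  prot_atoms <- function(...) data.frame(..., res_id = 1L, res_name = "RES")
  lig_atoms <- function(...) data.frame(..., res_id = 1L, res_name = "LIG")
  if (kind == "hbond") {
    # acceptor O at origin, donor N at (distance, 0, 0); H on the donor
    # positioned so the N-H..O angle equals `angle`
    hb_angle <- function(phi) {
      H <- c(distance + cos(phi), sin(phi), 0)
      vec_angle(c(distance, 0, 0) - H, c(0, 0, 0) - H)
    }
    lo <- hb_angle(pi / 2 + 1e-6)
    if (angle > 180 || angle < lo) {
      stop(sprintf("impossible geometry: H-bond angle %.1f not in [%.1f, 180]",
                   angle, lo))
    }
    phi <- if (angle >= 180 - 1e-9) pi else {
      stats::uniroot(function(x) hb_angle(x) - angle,
                     c(pi / 2 + 1e-6, pi), tol = 1e-12)$root
    }
    H <- c(distance + cos(phi), sin(phi), 0)
    protein <- mol2_structure(prot_atoms(
      atom_id = 1:2, name = c("O", "C"),
      x = c(0, 0), y = c(0, -1.23), z = c(0, 0),
      sybyl_type = c("O.2", "C.2")),
      data.frame(a1 = 1, a2 = 2, order = "2"), "prot")
    ligand <- mol2_structure(lig_atoms(
      atom_id = 1:3, name = c("N", "H", "C"),
      x = c(distance, H[1], distance + 1.0), y = c(0, H[2], 1.2),
      z = c(0, H[3], 0), sybyl_type = c("N.3", "H", "C.3")),
      data.frame(a1 = c(1, 1), a2 = c(2, 3), order = "1"), "lig")
  } else if (kind == "ionic") {
    protein <- mol2_structure(prot_atoms(
      atom_id = 1:2, name = c("OD1", "CG"),
      x = c(0, 0), y = c(0, -1.3), z = c(0, 0),
      sybyl_type = c("O.co2", "C.2")),
      data.frame(a1 = 1, a2 = 2, order = "ar"), "prot")
    ligand <- mol2_structure(lig_atoms(
      atom_id = 1L, name = "N", x = distance, y = 0, z = 0,
      sybyl_type = "N.4"), NULL, "lig")
  } else if (kind == "aromatic") {
    protein <- ring_structure(c(0, 0, 0), "prot", "RES")
    ligand <- ring_structure(c(0, 0, distance), "lig", "LIG",
                             tilt_deg = angle)
  } else if (kind == "hydrophobic") {
    protein <- mol2_structure(prot_atoms(
      atom_id = 1L, name = "CB", x = 0, y = 0, z = 0, sybyl_type = "C.3"),
      NULL, "prot")
    if (ligand_env == "apolar") {
      ligand <- mol2_structure(lig_atoms(
        atom_id = 1L, name = "C1", x = distance, y = 0, z = 0,
        sybyl_type = "C.3"), NULL, "lig")
    } else {
      ligand <- mol2_structure(lig_atoms(
        atom_id = 1:2, name = c("C1", "O1"),
        x = c(distance, distance + 1.4), y = c(0, 0), z = c(0, 0),
        sybyl_type = c("C.3", "O.3")),
        data.frame(a1 = 1, a2 = 2, order = "1"), "lig")
    }
  } else {
    protein <- mol2_structure(prot_atoms(
      atom_id = 1L, name = "ZN", x = 0, y = 0, z = 0, sybyl_type = "Zn"),
      NULL, "prot")
    ligand <- mol2_structure(lig_atoms(
      atom_id = 1:2, name = c("O1", "C1"),
      x = c(distance, distance + 1.4), y = c(0, 0), z = c(0, 0),
      sybyl_type = c("O.3", "C.3")),
      data.frame(a1 = 1, a2 = 2, order = "1"), "lig")
  }
  complex_frame(protein, ligand)
}
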