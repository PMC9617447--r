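# TRIPOS MOL2 input/output and chemical feature perception.
#
# Structures are plain lists: $atoms is a data.frame (one row per atom,
# file order preserved), $bonds a data.frame of (a1, a2, order), $mol_name
# a string. Coordinates are Cartesian Angstroms throughout; no unit
# conversion happens anywhere in the package.

TWO_LETTER_ELEMENTS <- c(
  "Cl", "Br", "Li", "Na", "Mg", "Al", "Si", "Ca", "Cr", "Mn", "Fe", "Co",
  "Cu", "Zn", "Se", "Mo", "Sn", "Du"
)

sybyl_element <- function(sybyl_type) {
  base <- sub("\\..*$", "", sybyl_type)
  ifelse(base %in% TWO_LETTER_ELEMENTS, base, substr(base, 1, 1))
}

#' Construct a molecular structure
#'
#' Lightweight container used by every structure-handling function in the
#' package. Atom ids must be unique and bond endpoints must refer to existing
#' atoms.
#'
#' @param atoms data.frame with columns `atom_id`, `name`, `sybyl_type`,
#'   `x`, `y`, `z`, `charge`, `res_name`, `res_id`. Missing `charge`,
#'   `res_name`, `res_id` are filled with defaults.
#' @param bonds data.frame with columns `a1`, `a2`, `order`
#'   (order one of "1", "2", "3", "ar", "am"); may have zero rows.
#' @param mol_name molecule name string.
#' @return object of class `mol2_structure`.
#' @export
mol2_structure <- function(atoms, bonds = NULL, mol_name = "MOL") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$charge)) atoms$charge <- rep(0, nrow(atoms))
  if (is.null(atoms$res_name)) atoms$res_name <- rep("UNK", nrow(atoms))
  if (is.null(atoms$res_id)) atoms$res_id <- rep(1L, nrow(atoms))
  if (is.null(atoms$name)) atoms$name <- atoms$sybyl_type
  atoms$atom_id <- as.integer(atoms$atom_id)
  atoms$element <- sybyl_element(atoms$sybyl_type)
  atoms$is_hydrogen <- atoms$element == "H"
  if (anyDuplicated(atoms$atom_id)) stop("duplicate atom ids")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates")
  }
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- data.frame(a1 = integer(), a2 = integer(),
                        order = character(), stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    bonds$a1 <- as.integer(bonds$a1)
    bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.character(bonds$order)
    ok <- bonds$a1 %in% atoms$atom_id & bonds$a2 %in% atoms$atom_id
    if (!all(ok)) stop("bond endpoints refer to missing atoms")
  }
  structure(list(atoms = atoms, bonds = bonds, mol_name = mol_name),
            class = "mol2_structure")
}

#' @export
print.mol2_structure <- function(x, ...) {
  cat(sprintf("<mol2_structure> %s: %d atoms (%d heavy), %d bonds\n",
              x$mol_name, nrow(x$atoms), sum(!x$atoms$is_hydrogen),
              nrow(x$bonds)))
  invisible(x)
}

#' Read a TRIPOS MOL2 file
#'
#' Parses the MOLECULE, ATOM and BOND sections of the first molecule in the
#' file. Partial charges are read when present (ninth atom field), otherwise
#' set to 0. SUBSTRUCTURE records are ignored beyond the per-atom residue
#' bookkeeping carried by the atom records themselves.
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character vector of MOL2 lines (overrides `path`).
#' @return a [mol2_structure()].
#' @export
read_mol2 <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  sec_idx <- grep("^@<TRIPOS>", lines)
  if (!length(sec_idx)) stop("not a MOL2 stream: no @<TRIPOS> records")
  sec_name <- sub("^@<TRIPOS>", "", lines[sec_idx])
  section <- function(name) {
    i <- which(sec_name == name)[1]
    if (is.na(i)) return(NULL)
    from <- sec_idx[i] + 1L
    to <- if (i < length(sec_idx)) sec_idx[i + 1L] - 1L else length(lines)
    if (to < from) return(list(lines = character(), lineno = integer()))
    body <- lines[from:to]
    keep <- !grepl("^\\s*(#|$)", body)
    list(lines = body[keep], lineno = (from:to)[keep])
  }
  mol <- section("MOLECULE")
  if (is.null(mol)) stop("missing @<TRIPOS>MOLECULE section")
  mol_name <- if (length(mol$lines)) trimws(mol$lines[1]) else "MOL"

  at <- section("ATOM")
  if (is.null(at)) stop("missing @<TRIPOS>ATOM section")
  parse_atom <- function(line, lineno) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < 6) {
      stop(sprintf("malformed ATOM record at line %d: '%s'", lineno, line))
    }
    xyz <- suppressWarnings(as.numeric(f[3:5]))
    if (anyNA(xyz)) {
      stop(sprintf("non-numeric coordinates at line %d", lineno))
    }
    data.frame(
      atom_id = as.integer(f[1]), name = f[2],
      x = xyz[1], y = xyz[2], z = xyz[3], sybyl_type = f[6],
      res_id = if (length(f) >= 7) suppressWarnings(as.integer(f[7])) else 1L,
      res_name = if (length(f) >= 8) f[8] else "UNK",
      charge = if (length(f) >= 9) suppressWarnings(as.numeric(f[9])) else 0,
      status = if (length(f) >= 10) f[10] else NA_character_,
      stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, Map(parse_atom, at$lines, at$lineno))
  rownames(atoms) <- NULL
  atoms$charge[is.na(atoms$charge)] <- 0
  atoms$res_id[is.na(atoms$res_id)] <- 1L

  bo <- section("BOND")
  if (is.null(bo)) {
    warning("MOL2 stream has no @<TRIPOS>BOND section; empty bond list")
    bonds <- NULL
  } else if (!length(bo$lines)) {
    bonds <- NULL
  } else {
    parse_bond <- function(line, lineno) {
      f <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(f) < 4) {
        stop(sprintf("malformed BOND record at line %d: '%s'", lineno, line))
      }
      data.frame(a1 = as.integer(f[2]), a2 = as.integer(f[3]), order = f[4],
                 stringsAsFactors = FALSE)
    }
    bonds <- do.call(rbind, Map(parse_bond, bo$lines, bo$lineno))
    rownames(bonds) <- NULL
  }
  st <- mol2_structure(atoms[setdiff(names(atoms), "status")], bonds, mol_name)
  st$atoms$status <- atoms$status
  st
}

#' Write a TRIPOS MOL2 file
#'
#' @param structure a [mol2_structure()].
#' @param path output path; when `NULL` the lines are returned invisibly
#'   without writing.
#' @return character vector of MOL2 lines, invisibly.
#' @export
write_mol2 <- function(structure, path = NULL) {
  a <- structure$atoms
  b <- structure$bonds
  lines <- c(
    "@<TRIPOS>MOLECULE",
    structure$mol_name,
    sprintf("%5d %5d %5d", nrow(a), nrow(b),
            if (nrow(a)) length(unique(a$res_id)) else 0L),
    "SMALL",
    "USER_CHARGES",
    "@<TRIPOS>ATOM"
  )
  if (nrow(a)) {
    status <- if (!is.null(a$status)) ifelse(is.na(a$status), "", a$status)
              else rep("", nrow(a))
    lines <- c(lines, sprintf(
      "%7d %-8s %10.4f %10.4f %10.4f %-8s %4d %-8s %9.4f %s",
      a$atom_id, a$name, a$x, a$y, a$z, a$sybyl_type,
      a$res_id, a$res_name, a$charge, status))
  }
  lines <- c(lines, "@<TRIPOS>BOND")
  if (nrow(b)) {
    lines <- c(lines, sprintf("%6d %5d %5d %s", seq_len(nrow(b)),
                              b$a1, b$a2, b$order))
  }
  lines <- trimws(lines, which = "right")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' SYBYL atom-type feature rules
#'
#' The frozen rule table mapping SYBYL atom types to chemical feature
#' candidacies. The reference interaction-detection program does not publish
#' its typing rules, so this table is a documented approximation; tests pin
#' its behaviour.
#'
#' @return data.frame with columns `sybyl_type`, `donor_candidate`,
#'   `acceptor`, `cation`, `anion`, `metal`.
#' @export
sybyl_rules <- function() {
  path <- system.file("extdata", "sybyl_feature_rules.tsv",
                      package = "igocsvm", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

bonded_ids <- function(structure, atom_id) {
  b <- structure$bonds
  c(b$a2[b$a1 == atom_id], b$a1[b$a2 == atom_id])
}

#' Perceive donors, acceptors, charges, hydrophobes and aromatic rings
#'
#' Deterministic rule-table perception driven only by SYBYL types and bonds
#' (never by coordinates): donors are N/O heavy atoms carrying an explicit
#' hydrogen (quaternary N.4 is a donor regardless), acceptors are the
#' lone-pair N/O types of the table, cations are N.4, nitrogens bonded to a
#' C.cat carbon, and metal ions, anions are carboxylate O.co2 plus
#' phosphate/sulfate oxygens, and every C or S heavy atom is flagged
#' hydrophobic (environment filtering happens at interaction detection).
#' Protonation is taken as given in the file.
#'
#' @param structure a [mol2_structure()].
#' @return list with `flags` (data.frame keyed by `atom_id` with logical
#'   columns `hbond_donor`, `hbond_acceptor`, `cation`, `anion`,
#'   `hydrophobic`, `metal` and integer `n_donor_h`) and `rings`
#'   (see [find_aromatic_rings()]).
#' @export
perceive_chemistry <- function(structure) {
  a <- structure$atoms
  rules <- sybyl_rules()
  known <- a$sybyl_type %in% rules$sybyl_type | a$is_hydrogen
  if (!all(known)) {
    warning("unknown SYBYL types, no flags assigned: ",
            paste(unique(a$sybyl_type[!known]), collapse = ", "))
  }
  ri <- match(a$sybyl_type, rules$sybyl_type)
  getrule <- function(col) {
    v <- rules[[col]][ri]
    v[is.na(v)] <- FALSE
    as.logical(v)
  }
  heavy <- !a$is_hydrogen
  n_donor_h <- vapply(seq_len(nrow(a)), function(i) {
    if (!heavy[i]) return(0L)
    nb <- bonded_ids(structure, a$atom_id[i])
    sum(a$is_hydrogen[match(nb, a$atom_id)])
  }, integer(1))

  donor <- heavy & getrule("donor_candidate") &
    (n_donor_h > 0L | a$sybyl_type == "N.4")
  acceptor <- heavy & getrule("acceptor")
  cation <- heavy & getrule("cation")
  anion <- heavy & getrule("anion")
  metal <- heavy & getrule("metal")
  hydrophobic <- heavy & a$element %in% c("C", "S")

  # topology-dependent charge rules: guanidinium/amidinium N, oxyanion O
  for (i in seq_len(nrow(a))) {
    if (!heavy[i]) next
    nb <- match(bonded_ids(structure, a$atom_id[i]), a$atom_id)
    nb_types <- a$sybyl_type[nb]
    if (a$element[i] == "N" && any(nb_types == "C.cat")) cation[i] <- TRUE
    if (a$element[i] == "O" && any(nb_types %in% c("P.3", "S.o2"))) {
      anion[i] <- TRUE
      acceptor[i] <- TRUE
    }
  }

  flags <- data.frame(
    atom_id = a$atom_id, hbond_donor = donor, hbond_acceptor = acceptor,
    cation = cation, anion = anion, hydrophobic = hydrophobic,
    metal = metal, n_donor_h = n_donor_h
  )
  list(flags = flags, rings = find_aromatic_rings(structure))
}

#' Find aromatic rings
#'
#' Enumerates 5- and 6-membered cycles whose members are all aromatic-typed
#' (SYBYL type ending ".ar"). Each ring is reported once with its centroid
#' (mean of member coordinates) and unit normal (principal axis orthogonal
#' to the best-fit plane).
#'
#' @param structure a [mol2_structure()].
#' @return list of rings, each `list(members, centroid, normal)`.
#' @export
find_aromatic_rings <- function(structure) {
  a <- structure$atoms
  aro <- a$atom_id[grepl("\\.ar$", a$sybyl_type)]
  if (length(aro) < 5) return(list())
  b <- structure$bonds
  keep <- b$a1 %in% aro & b$a2 %in% aro
  if (!any(keep)) return(list())
  adj <- lapply(stats::setNames(aro, aro), function(id) {
    nb <- c(b$a2[keep & b$a1 == id], b$a1[keep & b$a2 == id])
    unique(nb)
  })
  found <- new.env(parent = emptyenv())
  rings <- list()
  dfs <- function(path) {
    last <- path[length(path)]
    for (nxt in adj[[as.character(last)]]) {
      if (nxt == path[1] && length(path) >= 5) {
        key <- paste(sort(path), collapse = "-")
        if (is.null(found[[key]])) {
          assign(key, TRUE, envir = found)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(nxt %in% path) && length(path) < 6 && nxt > path[1]) {
        dfs(c(path, nxt))
      }
    }
  }
  for (start in sort(aro)) dfs(start)
  lapply(rings, function(members) {
    xyz <- as.matrix(a[match(members, a$atom_id), c("x", "y", "z")])
    centroid <- colMeans(xyz)
    centered <- sweep(xyz, 2, centroid)
    normal <- svd(centered)$v[, 3]
    normal <- normal / sqrt(sum(normal^2))
    list(members = sort(members), centroid = unname(centroid),
         normal = unname(normal))
  })
}

#' Bundle a protein and a ligand structure into one frame
#'
#' @param protein,ligand [mol2_structure()] objects.
#' @param frame_index non-negative integer frame identifier.
#' @return object of class `complex_frame`.
#' @export
complex_frame <- function(protein, ligand, frame_index = 0L) {
  stopifnot(inherits(protein, "mol2_structure"),
            inherits(ligand, "mol2_structure"), frame_index >= 0)
  if (!any(!ligand$atoms$is_hydrogen)) stop("ligand has no heavy atom")
  structure(list(protein = protein, ligand = ligand,
                 frame_index = as.integer(frame_index)),
            class = "complex_frame")
}
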