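# Internal molecular-graph representation.
#
# A `mf_mol` is a list with two tibbles:
#   atoms: element (chr, "*" for a bonding-site dummy), charge (int),
#          isotope (int, 0 = natural), x/y/z (dbl, NA when no geometry)
#   bonds: a1, a2 (int row indices into atoms), order (int, 1/2/3)
# Hydrogens are always explicit. OpenBabel (ChemmineOB) supplies parsing,
# canonical SMILES and 3D embedding; the V2000 block is the interchange
# format between the two worlds.

new_mol <- function(atoms, bonds) {
  atoms <- tibble::as_tibble(atoms)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$isotope)) atoms$isotope <- 0L
  if (is.null(atoms$x)) atoms$x <- NA_real_
  if (is.null(atoms$y)) atoms$y <- NA_real_
  if (is.null(atoms$z)) atoms$z <- NA_real_
  core_cols <- c("element", "charge", "isotope", "x", "y", "z")
  atoms <- atoms[, c(core_cols, setdiff(names(atoms), core_cols))]
  atoms$charge <- as.integer(atoms$charge)
  atoms$isotope <- as.integer(atoms$isotope)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
  }
  bonds <- tibble::as_tibble(bonds)[, c("a1", "a2", "order")]
  bonds$a1 <- as.integer(bonds$a1)
  bonds$a2 <- as.integer(bonds$a2)
  bonds$order <- as.integer(bonds$order)
  structure(list(atoms = atoms, bonds = bonds), class = "mf_mol")
}

is_mol <- function(x) inherits(x, "mf_mol")

n_atoms <- function(mol) nrow(mol$atoms)

mol_has_geometry <- function(mol) {
  nrow(mol$atoms) > 0L && !anyNA(mol$atoms$x) && !anyNA(mol$atoms$y) && !anyNA(mol$atoms$z)
}

mol_coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

mol_set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

dummy_idx <- function(mol) which(mol$atoms$element == "*")

heavy_count <- function(mol) sum(!mol$atoms$element %in% c("H", "*"))

#' @noRd
mol_neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

# --- V2000 molblock codec -------------------------------------------------

mol_to_molblock <- function(mol, name = "mol") {
  na <- nrow(mol$atoms)
  nb <- nrow(mol$bonds)
  xyz <- mol_coords(mol)
  xyz[is.na(xyz)] <- 0
  header <- c(name, " mopforge", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)
  # old-style charge code (0 none, 1..3 = +3..+1, 5..7 = -1..-3) alongside
  # M CHG: some SDF consumers read only one of the two
  chg_code <- ifelse(mol$atoms$charge == 0L, 0L,
              ifelse(mol$atoms$charge > 0L, 4L - mol$atoms$charge,
                     4L - mol$atoms$charge))
  chg_code[chg_code < 0L | chg_code > 7L] <- 0L
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0%3d  0  0  0  0  0  0  0  0  0  0",
                   xyz[, 1], xyz[, 2], xyz[, 3], mol$atoms$element, chg_code)
  bonds <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1, mol$bonds$a2, mol$bonds$order)
  } else character()
  props <- character()
  chg <- which(mol$atoms$charge != 0L)
  # M CHG/ISO lines carry at most 8 entries each
  emit_prop <- function(tag, idx, val) {
    out <- character()
    while (length(idx) > 0) {
      k <- seq_len(min(8L, length(idx)))
      out <- c(out, paste0(sprintf("M  %s%3d", tag, length(k)),
                           paste(sprintf("%4d%4d", idx[k], val[k]), collapse = "")))
      idx <- idx[-k]; val <- val[-k]
    }
    out
  }
  if (length(chg)) props <- c(props, emit_prop("CHG", chg, mol$atoms$charge[chg]))
  iso <- which(mol$atoms$isotope != 0L)
  if (length(iso)) props <- c(props, emit_prop("ISO", iso, mol$atoms$isotope[iso]))
  paste(c(header, counts, atoms, bonds, props, "M  END"), collapse = "\n")
}

mol_to_sdf <- function(mols, names = NULL) {
  if (is_mol(mols)) mols <- list(mols)
  if (is.null(names)) names <- paste0("mol", seq_along(mols))
  paste0(paste(vapply(seq_along(mols), function(i) {
    mol_to_molblock(mols[[i]], names[i])
  }, character(1)), collapse = "\n$$$$\n"), "\n$$$$\n")
}

parse_molblock <- function(lines) {
  na <- as.integer(substr(lines[4], 1, 3))
  nb <- as.integer(substr(lines[4], 4, 6))
  al <- lines[4 + seq_len(na)]
  atoms <- tibble::tibble(
    element = trimws(substr(al, 32, 34)),
    charge = 0L,
    isotope = 0L,
    x = as.numeric(substr(al, 1, 10)),
    y = as.numeric(substr(al, 11, 20)),
    z = as.numeric(substr(al, 21, 30))
  )
  bonds <- if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    tibble::tibble(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else NULL
  for (ln in grep("^M  (CHG|ISO)", lines, value = TRUE)) {
    tag <- substr(ln, 4, 6)
    n <- as.integer(substr(ln, 7, 9))
    rest <- substring(ln, 10)
    vals <- as.integer(strsplit(trimws(gsub("(.{4})", "\\1 ", rest)), "\\s+")[[1]])
    idx <- vals[seq(1, 2 * n, by = 2)]
    v <- vals[seq(2, 2 * n, by = 2)]
    if (tag == "CHG") atoms$charge[idx] <- v else atoms$isotope[idx] <- v
  }
  new_mol(atoms, bonds)
}

parse_sdf_text <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines) + 1L
  start <- 1L
  out <- list()
  for (e in ends) {
    block <- lines[start:(e - 1L)]
    block <- block[cumsum(block != "") > 0 | seq_along(block) <= 4]
    if (any(grepl("V2000", block))) out[[length(out) + 1L]] <- parse_molblock(block)
    start <- e + 1L
  }
  out
}

# --- OpenBabel bridge -----------------------------------------------------

ob_convert <- function(from, to, source, options = NULL) {
  if (is.null(options)) {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source))
  } else {
    suppressWarnings(ChemmineOB::convertFormat(from, to, source, options = options))
  }
}

#' Parse SMILES into internal molecular graphs
#'
#' Hydrogens are added explicitly; optionally a 3D geometry is embedded
#' with OpenBabel's builder + force-field cleanup.
#' @noRd
mol_from_smiles <- function(smiles, gen3d = FALSE) {
  stopifnot(length(smiles) == 1L)
  opts <- if (gen3d) data.frame(names = "gen3d", args = "") else
    data.frame(names = "h", args = "")
  src <- paste0(smiles, " m\n")
  sdf <- ob_convert("SMI", "SDF", src, options = opts)
  mols <- parse_sdf_text(sdf)
  if (length(mols) != 1L || n_atoms(mols[[1]]) == 0L) {
    stop("could not parse SMILES: ", smiles, call. = FALSE)
  }
  mol <- mols[[1]]
  if (!gen3d) {
    mol$atoms$x <- NA_real_; mol$atoms$y <- NA_real_; mol$atoms$z <- NA_real_
  }
  mol
}

#' Canonical SMILES for a batch of SMILES strings
#'
#' Vectorized through a single OpenBabel call; unparseable entries error.
#' @param smiles character vector
#' @return character vector of canonical SMILES
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character())
  ids <- paste0("q", seq_along(smiles))
  src <- paste0(paste(smiles, ids, collapse = "\n"), "\n")
  out <- ob_convert("SMI", "CAN", src)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) p[[2]], character(1))
  res <- stats::setNames(vapply(parts, function(p) p[[1]], character(1)), got)
  if (!all(ids %in% got)) {
    bad <- smiles[!(ids %in% got)]
    stop("unparseable SMILES: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(res[ids])
}

#' Constitutional canonical SMILES: stereo markers stripped, then
#' re-canonicalized. Product identity at the SMILES level is
#' stereo-agnostic (the graph joiner does not track bond stereo).
#' @param smiles character vector
#' @return character vector of stereo-free canonical SMILES
#' @export
canonical_constitution <- function(smiles) {
  bare <- gsub("@", "", gsub("[/\\\\]", "", smiles))
  canonical_smiles(bare)
}

#' Canonical SMILES of an internal molecule (dummies preserved)
#' @noRd
mol_to_smiles <- function(mol) {
  out <- ob_convert("SDF", "CAN", mol_to_sdf(mol))
  smi <- strsplit(strsplit(out, "\n", fixed = TRUE)[[1]][1], "\t", fixed = TRUE)[[1]][1]
  if (is.na(smi) || !nzchar(smi)) stop("could not canonicalize molecule", call. = FALSE)
  smi
}

# Batched canonical SMILES for a list of mols (one OpenBabel call per chunk).
mols_to_smiles <- function(mols, chunk = 200L) {
  if (length(mols) == 0) return(character())
  out <- character(length(mols))
  for (s in seq(1, length(mols), by = chunk)) {
    idx <- s:min(s + chunk - 1L, length(mols))
    sdf <- mol_to_sdf(mols[idx], names = paste0("m", idx))
    res <- ob_convert("SDF", "CAN", sdf)
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ids <- as.integer(sub("^m", "", vapply(parts, `[[`, character(1), 2)))
    out[ids] <- vapply(parts, `[[`, character(1), 1)
  }
  if (any(!nzchar(out))) stop("canonicalization failed for some molecules", call. = FALSE)
  out
}

# --- graph utilities ------------------------------------------------------

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = mol$bonds[, c("a1", "a2")],
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms)))
  )
}

mol_is_connected <- function(mol) {
  if (nrow(mol$atoms) <= 1L) return(TRUE)
  igraph::is_connected(mol_igraph(mol))
}

# Logical vector over bonds: TRUE when the bond is part of some ring
# (equivalently, the edge is not a bridge of the molecular graph).
ring_bond_mask <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(logical(0))
  g <- mol_igraph(mol)
  br <- igraph::bridges(g)
  mask <- rep(TRUE, nrow(mol$bonds))
  mask[as.integer(br)] <- FALSE
  mask
}

# Induced sub-molecule on atom indices `keep` (bonds among them only).
mol_subset <- function(mol, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- integer(nrow(mol$atoms))
  map[keep] <- seq_along(keep)
  b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
  b$a1 <- map[b$a1]; b$a2 <- map[b$a2]
  list(mol = new_mol(mol$atoms[keep, , drop = FALSE], b), map = map)
}

# Append atoms/bonds of `molB` to `molA`; returns combined mol and the
# index offset applied to B.
mol_bind <- function(molA, molB) {
  off <- nrow(molA$atoms)
  b <- molB$bonds
  b$a1 <- b$a1 + off; b$a2 <- b$a2 + off
  list(mol = new_mol(dplyr::bind_rows(molA$atoms, molB$atoms),
                     dplyr::bind_rows(molA$bonds, b)),
       offset = off)
}

# Remove atoms by index, dropping incident bonds and reindexing.
mol_drop_atoms <- function(mol, drop) {
  keep <- setdiff(seq_len(nrow(mol$atoms)), as.integer(drop))
  mol_subset(mol, keep)$mol
}

# Substructure match count via OpenBabel SMARTS.
smarts_match_count <- function(mol, smarts) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(mol_to_sdf(mol), tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  unname(ChemmineR::smartsSearchOB(sdfset, smarts, uniqueMatches = TRUE))
}
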