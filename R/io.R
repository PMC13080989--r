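# File input/output: SMILES lists, XYZ, SDF, fragment-library JSON.

#' Write a SMILES list (.smi)
#'
#' One record per line: SMILES, tab, name.
#' @param smiles character vector
#' @param path output file
#' @param names optional record names
#' @export
write_smi <- function(smiles, path, names = NULL) {
  if (is.null(names)) names <- paste0("cbu", seq_along(smiles))
  writeLines(paste(smiles, names, sep = "\t"), path)
  invisible(path)
}

#' Read a SMILES list (.smi)
#' @param path input file
#' @return tibble with columns `smiles`, `name`
#' @export
read_smi <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  tibble::tibble(
    smiles = vapply(parts, `[[`, character(1), 1),
    name = vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_,
                  character(1))
  )
}

#' Write coordinates to an XYZ file
#'
#' Dummy atoms are written with the symbol `X` and restored on read.
#' @param x an internal mol, an `mf_cbu`, an `mf_mop`, or a tibble with
#'   element/x/y/z columns
#' @param path output file
#' @param comment second-line comment (provenance)
#' @export
write_xyz <- function(x, path, comment = "") {
  at <- if (is_mol(x)) x$atoms
  else if (is_cbu(x)) x$mol$atoms
  else if (inherits(x, "mf_mop")) x$atoms
  else x
  el <- ifelse(at$element == "*", "X", at$element)
  lines <- c(
    as.character(nrow(at)),
    comment,
    sprintf("%-3s %14.8f %14.8f %14.8f", el, at$x, at$y, at$z)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ file
#' @param path input file
#' @return tibble with `element`, `x`, `y`, `z` (symbol `X` becomes `*`)
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || length(lines) < n + 2) {
    stop("malformed XYZ file: ", path, call. = FALSE)
  }
  rec <- strsplit(trimws(lines[2 + seq_len(n)]), "\\s+")
  bad <- vapply(rec, length, integer(1)) < 4
  if (any(bad)) stop("malformed XYZ atom line in ", path, call. = FALSE)
  el <- vapply(rec, `[[`, character(1), 1)
  tibble::tibble(
    element = ifelse(el == "X", "*", el),
    x = as.numeric(vapply(rec, `[[`, character(1), 2)),
    y = as.numeric(vapply(rec, `[[`, character(1), 3)),
    z = as.numeric(vapply(rec, `[[`, character(1), 4))
  )
}

#' Read molecules from an SDF file
#' @param path SDF/MOL file
#' @return list of internal mols (with coordinates and charges)
#' @export
read_sdf <- function(path) {
  # ChemmineR validates the container; the V2000 blocks are decoded by the
  # internal codec, which keeps formal charges and dummy atoms
  invisible(suppressWarnings(ChemmineR::read.SDFset(path)))
  parse_sdf_text(paste(readLines(path), collapse = "\n"))
}

#' Write molecules to an SDF file
#' @param mols internal mol or list of mols (e.g. `cbu$mol`)
#' @param path output file
#' @param names record names
#' @export
write_sdf <- function(mols, path, names = NULL) {
  writeLines(mol_to_sdf(mols, names = names), path)
  invisible(path)
}

#' Write a fragment library to JSON (+ XYZ geometries)
#'
#' The JSON carries canonical SMILES, type, category, flags and provenance
#' counts, ordered by canonical key; each fragment's geometry is written as
#' an XYZ file next to it, named by its index.
#' @param library fragment library tibble
#' @param path JSON path; XYZ files go into `<path>_xyz/`
#' @export
write_fragment_library <- function(library, path) {
  library <- dplyr::arrange(library, .data$key)
  xyz_dir <- paste0(sub("\\.json$", "", path), "_xyz")
  dir.create(xyz_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(seq_len(nrow(library)), function(i) {
    f <- library[i, ]
    xyz_file <- file.path(xyz_dir, sprintf("frag_%03d.xyz", i))
    write_xyz(f$mol[[1]], xyz_file, comment = f$key)
    list(key = f$key, smiles = f$smiles, frag_type = f$frag_type,
         category = if ("category" %in% names(f)) f$category else NA,
         n_sites = f$n_sites,
         cyclic = f$cyclic, linear = f$linear, symmetric = f$symmetric,
         n_side_chains = f$n_side_chains, xyz = basename(xyz_file))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a fragment library written by [write_fragment_library()]
#' @param path JSON path
#' @return fragment library tibble
#' @export
read_fragment_library <- function(path) {
  recs <- jsonlite::read_json(path)
  xyz_dir <- paste0(sub("\\.json$", "", path), "_xyz")
  out <- lapply(recs, function(r) {
    mol <- mol_from_smiles(r$smiles)
    xyz_file <- file.path(xyz_dir, r$xyz)
    if (file.exists(xyz_file)) {
      coords <- read_xyz(xyz_file)
      if (nrow(coords) == nrow(mol$atoms) &&
          identical(coords$element, mol$atoms$element)) {
        mol <- mol_set_coords(mol, as.matrix(coords[, c("x", "y", "z")]))
      } else {
        # atom order is only guaranteed for files this package wrote
        stop("XYZ/SMILES atom mismatch for ", r$key, call. = FALSE)
      }
    }
    f <- fragment_from_mol(mol, frag_type = r$frag_type)
    f$n_side_chains <- as.integer(r$n_side_chains)
    f$category <- if (is.null(r$category)) NA_character_ else r$category
    f
  })
  dplyr::bind_rows(out)
}
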