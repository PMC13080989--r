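# Fragmentation of organic chemical building units (CBUs) into typed
# fragments. A CBU is cleaved at every exocyclic, non-hydrogen single bond;
# each fragmentation point receives a dummy atom ("*") on both sides, placed
# at the position of the removed neighbor so that rejoining reproduces the
# original bond length. Fragments are typed by bonding-site count
# (1 = side chain, 2 = linker, >= 3 = node), except fragments matching a
# configured binding-group pattern, which are always typed binding_group.
# Side-chain attachment points on their parent fragments are reverted to
# hydrogen, so parents stay valid standalone molecules.

.mf_cache <- new.env(parent = emptyenv())

# 3D embedding memoised by (dummy-preserving) canonical SMILES: OpenBabel's
# conformer generation is stochastic, caching keeps a session's geometries
# for one species identical everywhere it is used.
geometry_for_smiles <- function(smiles) {
  key <- paste0("g3d:", smiles)
  hit <- get0(key, envir = .mf_cache)
  if (!is.null(hit)) return(hit)
  mol <- mol_from_smiles(smiles, gen3d = TRUE)
  mol <- normalize_dummy_lengths(mol)
  assign(key, mol, envir = .mf_cache)
  mol
}

# OpenBabel embeds dummy atoms almost on top of their anchor; stretch each
# dummy to the anchor's covalent radius plus a carbon radius, the typical
# length of the single bond the site will form. (Fragments extracted by
# fragment_cbu() keep the true removed-neighbor position instead.)
normalize_dummy_lengths <- function(mol) {
  if (!mol_has_geometry(mol)) return(mol)
  for (d in dummy_idx(mol)) {
    a <- mol_neighbors(mol, d)[1]
    ap <- as.numeric(mol$atoms[a, c("x", "y", "z")])
    dp <- as.numeric(mol$atoms[d, c("x", "y", "z")])
    len <- covalent_radius(mol$atoms$element[a]) + covalent_radius("C")
    np <- ap + unit_vec(dp - ap) * len
    mol$atoms$x[d] <- np[1]; mol$atoms$y[d] <- np[2]; mol$atoms$z[d] <- np[3]
  }
  mol
}

#' Default binding-group patterns
#'
#' Carboxylate and pyrazolate, the two metal-coordinating groups this
#' design space terminates its organic building units with. Both are kept
#' anionic throughout. Patterns are dummy-marked fragment SMILES; the
#' pattern core (dummies removed) is matched as a colored subgraph, so
#' bonds inside a match are never cleaved and fragments containing a match
#' are typed `binding_group`.
#' @return named character vector of dummy-marked SMILES
#' @export
binding_group_patterns <- function() {
  c(carboxylate = "*C(=O)[O-]",
    pyrazolate = "*c1c[n-]nc1")
}

# Pattern core: parse a dummy-marked SMILES and strip the dummies.
pattern_core <- function(pattern) {
  key <- paste0("pat:", pattern)
  hit <- get0(key, envir = .mf_cache)
  if (!is.null(hit)) return(hit)
  mol <- mol_from_smiles(pattern)
  core <- mol_drop_atoms(mol, dummy_idx(mol))
  assign(key, core, envir = .mf_cache)
  core
}

# Colored graph for VF2 matching: vertices colored by (element, charge),
# edges colored 0 for ring bonds (kekulization-independent) and by bond
# order otherwise.
match_graph <- function(mol, vertex_levels) {
  g <- mol_igraph(mol)
  vcol <- match(paste(mol$atoms$element, mol$atoms$charge), vertex_levels)
  vcol[is.na(vcol)] <- length(vertex_levels) + 1L
  igraph::V(g)$color <- vcol
  ring <- ring_bond_mask(mol)
  igraph::E(g)$color <- ifelse(ring, 0L, mol$bonds$order)
  g
}

# All induced matches of a pattern core inside `mol`; returns a list of
# integer vectors of mol atom indices (possibly overlapping).
mol_match_atoms <- function(mol, core) {
  lv <- unique(paste(core$atoms$element, core$atoms$charge))
  gp <- match_graph(core, lv)
  gt <- match_graph(mol, lv)
  maps <- igraph::subgraph_isomorphisms(pattern = gp, target = gt, method = "vf2")
  unique(lapply(maps, function(m) sort(as.integer(m))))
}

mol_matches_pattern <- function(mol, pattern) {
  core <- pattern_core(pattern)
  if (nrow(core$atoms) > nrow(mol$atoms)) return(FALSE)
  length(mol_match_atoms(mol, core)) > 0
}

fragment_types <- function() {
  c("binding_group", "linker", "node", "side_chain", "untyped")
}

# Build one fragment row from an internal mol carrying dummy sites.
fragment_from_mol <- function(mol, frag_type = NULL) {
  dmy <- dummy_idx(mol)
  n_sites <- length(dmy)
  key <- canonical_key(mol)
  cyc <- any(ring_bond_mask(mol))
  lin <- fragment_is_linear(mol)
  sym <- fragment_is_symmetric(mol, key)
  if (is.null(frag_type)) {
    frag_type <- switch(as.character(min(n_sites, 3L)),
                        "0" = "untyped", "1" = "side_chain",
                        "2" = "linker", "3" = "node")
  }
  tibble::tibble(
    key = key, smiles = key, frag_type = frag_type, n_sites = n_sites,
    cyclic = cyc, linear = lin, symmetric = sym,
    n_side_chains = 0L, mol = list(mol)
  )
}

#' Build a fragment record from SMILES
#'
#' The SMILES must mark each bonding site with a dummy atom `*`. A 3D
#' geometry is embedded (and cached) unless `gen3d = FALSE`.
#' @param smiles character scalar with `*` bonding sites
#' @param frag_type optional type override; inferred from site count if NULL
#' @param gen3d embed a 3D geometry via OpenBabel
#' @return one-row fragment tibble
#' @export
fragment_from_smiles <- function(smiles, frag_type = NULL, gen3d = TRUE) {
  mol <- if (gen3d) geometry_for_smiles(canonical_smiles(smiles)) else
    mol_from_smiles(smiles)
  fragment_from_mol(mol, frag_type = frag_type)
}

#' Canonical key of a fragment
#'
#' Equal molecular graphs (including dummy placement, charges) map to equal
#' keys; the key is the OpenBabel canonical SMILES with isotope labels
#' cleared.
#' @param frag a fragment row (tibble), an internal mol, or a SMILES string
#' @return character scalar
#' @export
canonical_key <- function(frag) {
  if (is_mol(frag)) {
    frag$atoms$isotope <- 0L
    return(mol_to_smiles(frag))
  }
  if (is.data.frame(frag)) {
    stopifnot(nrow(frag) == 1L)
    return(canonical_key(frag$mol[[1]]))
  }
  if (is.character(frag)) return(canonical_smiles(frag))
  stop("cannot compute a canonical key for this object", call. = FALSE)
}

# Site table of a fragment: one row per dummy with its anchor atom.
fragment_sites <- function(mol) {
  dmy <- dummy_idx(mol)
  anchors <- vapply(dmy, function(d) {
    nb <- mol_neighbors(mol, d)
    if (length(nb) != 1L) stop("dummy atom must have exactly one neighbor", call. = FALSE)
    nb
  }, integer(1))
  tibble::tibble(site = seq_along(dmy), dummy = dmy, anchor = anchors)
}

# A two-site fragment is linear when its two anchor->dummy vectors are
# within `tol_deg` of antiparallel. NA without geometry or for other
# site counts.
fragment_is_linear <- function(mol, tol_deg = 15) {
  sites <- fragment_sites(mol)
  if (nrow(sites) != 2L || !mol_has_geometry(mol)) return(NA)
  xyz <- mol_coords(mol)
  v1 <- unit_vec(xyz[sites$dummy[1], ] - xyz[sites$anchor[1], ])
  v2 <- unit_vec(xyz[sites$dummy[2], ] - xyz[sites$anchor[2], ])
  ang <- acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
  ang >= 180 - tol_deg
}

# A two-site fragment is symmetric iff exchanging its two dummies yields
# the same canonical SMILES (tested with isotope labels 1/2 swapped).
# Fragments with fewer or more sites are treated as symmetric: orientation
# choices only exist for two-site linkers.
fragment_is_symmetric <- function(mol, key = NULL) {
  sites <- fragment_sites(mol)
  if (nrow(sites) != 2L) return(TRUE)
  m1 <- mol
  m1$atoms$isotope[sites$dummy] <- c(1L, 2L)
  m2 <- mol
  m2$atoms$isotope[sites$dummy] <- c(2L, 1L)
  mol_to_smiles(m1) == mol_to_smiles(m2)
}

#' Fragment an organic CBU into typed fragments
#'
#' Cleaves every exocyclic, non-hydrogen single bond and replaces each
#' fragmentation point with dummy atoms at either end. Fragments matching a
#' binding-group pattern are typed `binding_group` regardless of site
#' count; remaining one-site fragments are typed `side_chain` and their
#' attachment point on the parent fragment is reverted to hydrogen; the
#' rest are typed by site count (2 = linker, >= 3 = node).
#'
#' @param cbu a SMILES string or an internal mol with explicit hydrogens
#' @param patterns named character vector of binding-group SMARTS
#' @param gen3d embed 3D coordinates first when `cbu` is a SMILES string
#' @return tibble of fragments, one row per fragment instance (not
#'   deduplicated; see [fragment_library()])
#' @export
fragment_cbu <- function(cbu, patterns = binding_group_patterns(), gen3d = TRUE) {
  mol <- if (is.character(cbu)) {
    if (gen3d) geometry_for_smiles(canonical_smiles(cbu)) else mol_from_smiles(cbu)
  } else cbu
  stopifnot(is_mol(mol))
  if (!mol_is_connected(mol)) {
    stop("fragment_cbu() requires a single-component molecule", call. = FALSE)
  }
  elem <- mol$atoms$element
  ring <- ring_bond_mask(mol)
  # bonds whose two atoms lie inside one binding-group match are protected
  protected <- rep(FALSE, nrow(mol$bonds))
  for (p in patterns) {
    core <- pattern_core(p)
    if (nrow(core$atoms) > nrow(mol$atoms)) next
    for (mset in mol_match_atoms(mol, core)) {
      protected <- protected |
        (mol$bonds$a1 %in% mset & mol$bonds$a2 %in% mset)
    }
  }
  cleave <- which(mol$bonds$order == 1L & !ring &
                    elem[mol$bonds$a1] != "H" & elem[mol$bonds$a2] != "H" &
                    elem[mol$bonds$a1] != "*" & elem[mol$bonds$a2] != "*" &
                    !protected)
  if (length(cleave) == 0L) {
    frag <- fragment_from_mol(mol, frag_type = "untyped")
    return(frag)
  }

  kept <- mol$bonds[-cleave, , drop = FALSE]
  g <- igraph::graph_from_data_frame(kept[, c("a1", "a2")], directed = FALSE,
                                     vertices = data.frame(name = seq_len(nrow(mol$atoms))))
  comp <- igraph::components(g)$membership

  has_geom <- mol_has_geometry(mol)
  xyz <- mol_coords(mol)

  # per-component fragment mol with dummies appended; remember which
  # component each dummy points at so side chains can be reverted
  comps <- sort(unique(comp))
  frag_mols <- list()
  dummy_partner <- list() # per comp: integer vector, partner comp per dummy
  for (ci in comps) {
    idx <- which(comp == ci)
    sub <- mol_subset(mol, idx)
    fmol <- sub$mol
    partners <- integer(0)
    for (b in cleave) {
      i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
      for (ord in list(c(i, j), c(j, i))) {
        if (comp[ord[1]] == ci) {
          fmol$atoms <- dplyr::bind_rows(fmol$atoms, tibble::tibble(
            element = "*", charge = 0L, isotope = 0L,
            x = if (has_geom) xyz[ord[2], 1] else NA_real_,
            y = if (has_geom) xyz[ord[2], 2] else NA_real_,
            z = if (has_geom) xyz[ord[2], 3] else NA_real_
          ))
          fmol$bonds <- dplyr::bind_rows(fmol$bonds, tibble::tibble(
            a1 = sub$map[ord[1]], a2 = nrow(fmol$atoms), order = 1L
          ))
          partners <- c(partners, comp[ord[2]])
        }
      }
    }
    frag_mols[[ci]] <- fmol
    dummy_partner[[ci]] <- partners
  }

  # pass 1: binding groups (pattern match), then provisional side chains
  is_bg <- vapply(frag_mols, function(m) {
    any(vapply(patterns, function(p) mol_matches_pattern(m, p), logical(1)))
  }, logical(1))
  n_sites0 <- vapply(frag_mols, function(m) length(dummy_idx(m)), integer(1))
  is_sc <- !is_bg & n_sites0 == 1L

  # pass 2: revert side-chain attachment points to hydrogen on parents
  for (ci in comps[!is_bg & !is_sc]) {
    fmol <- frag_mols[[ci]]
    dmy <- dummy_idx(fmol)
    to_sc <- which(is_sc[dummy_partner[[ci]]])
    for (k in to_sc) {
      d <- dmy[k]
      anchor <- mol_neighbors(fmol, d)
      fmol$atoms$element[d] <- "H"
      if (mol_has_geometry(fmol)) {
        a <- as.numeric(fmol$atoms[anchor, c("x", "y", "z")])
        p <- as.numeric(fmol$atoms[d, c("x", "y", "z")])
        newp <- a + unit_vec(p - a) * xh_bond_length(fmol$atoms$element[anchor])
        fmol$atoms$x[d] <- newp[1]; fmol$atoms$y[d] <- newp[2]; fmol$atoms$z[d] <- newp[3]
      }
    }
    frag_mols[[ci]] <- fmol
  }

  # pass 3: final typing from remaining site counts
  out <- lapply(comps, function(ci) {
    ftype <- if (is_bg[ci]) "binding_group"
    else if (is_sc[ci]) "side_chain"
    else {
      ns <- length(dummy_idx(frag_mols[[ci]]))
      if (ns == 0L) "untyped" else if (ns == 1L) "side_chain"
      else if (ns == 2L) "linker" else "node"
    }
    fragment_from_mol(frag_mols[[ci]], frag_type = ftype)
  })
  dplyr::bind_rows(out)
}

#' Deduplicate fragments into a library
#'
#' Fragments are keyed by canonical SMILES; the first occurrence of each
#' key is kept and rows are ordered deterministically by key.
#' @param fragments fragment tibble (possibly with repeated keys)
#' @return fragment library tibble
#' @export
fragment_library <- function(fragments) {
  lib <- fragments |>
    dplyr::distinct(.data$key, .keep_all = TRUE) |>
    dplyr::arrange(.data$key)
  lib
}

#' Fragment counts by type
#' @param library fragment library tibble
#' @return tibble with columns `frag_type`, `n`
#' @export
library_counts <- function(library) {
  library |>
    dplyr::count(frag_type = factor(.data$frag_type, levels = fragment_types()),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(frag_type = as.character(.data$frag_type))
}
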