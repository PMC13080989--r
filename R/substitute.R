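# Controlled side-chain substitution: graft a one-site side-chain fragment
# onto each symmetry-distinct C-H position of a two-site linker, producing
# asymmetric linker variants.

#' Substitute a side chain onto every distinct C-H position of a linker
#'
#' Each hydrogen bound to carbon is treated as a bonding site: the side
#' chain's dummy is mapped onto the carbon, the hydrogen onto the side
#' chain's anchor, and the pair is joined with the same bonding-site join
#' used in geometric CBU assembly (including the torsion scan on clash).
#' Products are deduplicated by canonical key, so symmetry-equivalent ring
#' positions collapse to one product.
#'
#' @param linker one-row fragment tibble with exactly 2 bonding sites
#' @param side_chain one-row fragment tibble with exactly 1 bonding site
#' @param torsion_step torsion-scan increment in degrees
#' @param clash_factor clash threshold as fraction of the vdW-radius sum
#' @return fragment tibble of unique substituted linkers (possibly empty
#'   when the linker has no substitutable C-H)
#' @export
substitute_linker <- function(linker, side_chain, torsion_step = 10,
                              clash_factor = mf_clash_factor()) {
  stopifnot(nrow(linker) == 1L, nrow(side_chain) == 1L)
  if (linker$n_sites != 2L) {
    stop("linker must have exactly 2 bonding sites", call. = FALSE)
  }
  if (side_chain$n_sites != 1L) {
    stop("side chain must have exactly 1 bonding site", call. = FALSE)
  }
  sc_mol <- fragment_instance_mol(side_chain, geometry = TRUE)
  if (sum(!sc_mol$atoms$element %in% c("H", "*")) == 0L) {
    stop("degenerate side chain (hydrogen-equivalent substituent)", call. = FALSE)
  }
  lk_mol <- fragment_instance_mol(linker, geometry = TRUE)

  host <- tag_mol(lk_mol, "lk")
  guest0 <- tag_mol(sc_mol, "sc")
  gsite <- instance_sites(guest0)[[1]]

  # candidate positions: hydrogens bound to carbon
  hs <- which(host$atoms$element == "H")
  hs <- hs[vapply(hs, function(h) {
    nb <- mol_neighbors(host, h)
    length(nb) == 1L && host$atoms$element[nb] == "C"
  }, logical(1))]
  if (length(hs) == 0L) return(linker[0, ])

  prods <- list()
  for (h in hs) {
    anchor <- mol_neighbors(host, h)
    hsite <- list(anchor = host$atoms$uid[anchor], dummy = host$atoms$uid[h])
    res <- tryCatch(
      join_fragments(host, hsite, guest0, gsite, geometry = TRUE,
                     torsion_step = torsion_step, clash_factor = clash_factor),
      mopforge_assembly_failure = function(e) NULL
    )
    if (is.null(res)) next
    frag <- fragment_from_mol(res$mol, frag_type = "linker")
    frag$n_side_chains <- linker$n_side_chains + side_chain$n_side_chains + 1L
    prods[[length(prods) + 1L]] <- frag
  }
  if (length(prods) == 0L) return(linker[0, ])
  fragment_library(dplyr::bind_rows(prods))
}

#' Generate asymmetric linker variants from a library
#'
#' Applies [substitute_linker()] for one base linker against a set of side
#' chains (single substitution each) and deduplicates the union.
#' @param linker one-row fragment tibble (2 sites)
#' @param side_chains fragment tibble of one-site fragments
#' @return fragment tibble of unique substituted linkers
#' @export
substituted_linker_set <- function(linker, side_chains) {
  out <- lapply(seq_len(nrow(side_chains)), function(i) {
    substitute_linker(linker, side_chains[i, ])
  })
  fragment_library(dplyr::bind_rows(out))
}
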