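# Synthetic fragment library and synthetic metal units.
#
# The generator reproduces the category structure of the study's curated
# fragment set - two binding groups (carboxylate, pyrazolate), two
# three-site nodes, five nonlinear acyclic linkers, 24 side chains, 20
# linear cyclic linkers and 18 linear acyclic linkers (71 fragments in
# total) - from a hand-written pool of simple, chemically valid motifs.
# It does not reproduce any published fragment set.

fixture_pools <- function() {
  list(
    binding_group = c("*C(=O)[O-]", "*c1c[n-]nc1"),
    node = c("*c1cc(*)cc(*)c1", "*c1nc(*)nc(*)n1"),
    nonlinear_acyclic_linker = c(
      "*C*", "*O*", "*N*", "*C(=O)*", "*S(=O)(=O)*", "*S*", "*C(F)(F)*", "*OC*"
    ),
    linear_cyclic_linker = c(
      "*c1ccc(*)cc1", "*c1ccc(*)nc1", "*c1cnc(*)cn1", "*c1ncc(*)cn1",
      "*c1nnc(*)cc1", "*c1nnc(*)cn1", "*c1nnc(*)nn1",
      "*c1ccc2cc(*)ccc2c1", "*c1c2ccccc2c(*)c2ccccc12",
      "*c1cc2ccc3cc(*)cc4ccc(c1)c2c34",
      "*c1ccc2nc(*)ccc2c1", "*c1ccc2cc(*)cnc2c1", "*c1ccc2cc(*)ncc2c1",
      "*c1cnc2cc(*)cnc2c1", "*c1ncc2cc(*)cnc2c1", "*c1ncc2cc(*)ncc2c1",
      "*c1nnc2cc(*)ccc2c1", "*c1cnc2cc(*)ncc2n1", "*c1nnc2cc(*)cnc2c1",
      "*c1nnc2cc(*)ncc2c1", "*c1nc2ccc(*)cc2cn1",
      "*C1CCC(*)CC1", "*C12CC(*)(C1)C2"
    ),
    linear_acyclic_linker = c(
      "*C#C*", "*C#CC#C*", "*C#CC#CC#C*", "*C#CC#CC#CC#C*",
      "*/C=C/*", "*/C=C/C=C/*", "*/C=C/C=C/C=C/*",
      "*C=C=C=C*", "*/N=N/*", "*/C=N/*", "*/N=C/C=N/*",
      "*C#C/C=C/C#C*", "*C#CN=NC#C*", "*/C=C/N=N/C=C/*",
      "*C#C/C=N/C#C*", "*/C=C/C#CC#C/C=C/*", "*C#CC=C*", "*CC*",
      "*C#CC#C/C=C/*", "*/N=N/C#C*"
    ),
    side_chain = c(
      "*F", "*Cl", "*Br", "*I", "*C", "*CC", "*OC", "*O", "*N",
      "*[N+](=O)[O-]", "*C#N", "*C(F)(F)F", "*C=O", "*C(C)=O", "*C(=O)OC",
      "*C(N)=O", "*S", "*SC", "*OC(F)(F)F", "*C#C", "*C=C", "*C(C)C",
      "*C(C)(C)C", "*N(C)C", "*OCC"
    )
  )
}

fixture_categories <- function() names(fixture_pools())

# category membership test on a computed fragment row
category_ok <- function(frag, category) {
  switch(category,
    binding_group = TRUE,
    node = frag$frag_type == "node",
    side_chain = frag$n_sites == 1L,
    nonlinear_acyclic_linker =
      frag$n_sites == 2L && !frag$cyclic && identical(frag$linear, FALSE),
    linear_cyclic_linker =
      frag$n_sites == 2L && frag$cyclic && identical(frag$linear, TRUE),
    linear_acyclic_linker =
      frag$n_sites == 2L && !frag$cyclic && identical(frag$linear, TRUE)
  )
}

run_with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Default fixture category counts
#'
#' Two binding groups, two nodes, five nonlinear acyclic linkers, 24 side
#' chains, 20 linear cyclic linkers and 18 linear acyclic linkers
#' (71 fragments).
#' @return named integer vector
#' @export
fixture_counts <- function() {
  c(binding_group = 2L, node = 2L, nonlinear_acyclic_linker = 5L,
    side_chain = 24L, linear_cyclic_linker = 20L, linear_acyclic_linker = 18L)
}

#' Generate the synthetic fixture fragment library
#'
#' Draws `counts` fragments per category from the built-in motif pool.
#' Every candidate is parsed, embedded in 3D and checked against its
#' category's flag signature (site count, cyclicity, linearity) before
#' selection; the draw within each validated pool is seeded, so equal
#' seeds give identical libraries.
#'
#' @param counts named integer vector over the categories of
#'   [fixture_counts()]
#' @param seed integer seed controlling the within-pool selection
#' @return fragment library tibble with a `category` column
#' @export
generate_fixture_library <- function(counts = fixture_counts(), seed = 1L) {
  pools <- fixture_pools()
  bad <- setdiff(names(counts), names(pools))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- list()
  for (cat in fixture_categories()) {
    n <- if (cat %in% names(counts)) counts[[cat]] else 0L
    if (n == 0L) next
    frags <- dplyr::bind_rows(lapply(pools[[cat]], function(s) {
      f <- fragment_from_smiles(s)
      if (!category_ok(f, cat)) return(NULL)
      f
    }))
    frags <- fragment_library(frags)
    if (nrow(frags) < n) {
      stop("requested ", n, " ", cat, " fragments but only ", nrow(frags),
           " validated pool entries exist", call. = FALSE)
    }
    pick <- run_with_seed(seed + match(cat, fixture_categories()),
                          sort(sample.int(nrow(frags), n)))
    sel <- frags[pick, ]
    sel$frag_type <- switch(cat,
      binding_group = "binding_group",
      node = "node",
      side_chain = "side_chain",
      "linker")
    sel$category <- cat
    out[[cat]] <- sel
  }
  lib <- dplyr::bind_rows(out)
  if (nrow(lib) == 0L) {
    lib <- fragment_from_smiles("*C")[0, ]
    lib$category <- character()
    return(lib)
  }
  if (anyDuplicated(lib$key)) {
    stop("internal: fixture library has duplicate canonical keys", call. = FALSE)
  }
  lib |> dplyr::arrange(.data$category, .data$key)
}

#' Synthetic 3-pyramidal metal building unit
#'
#' A parametric trioxo-metal cluster (labelled synthetic: it is a geometric
#' stand-in, not an experimentally derived cluster) exposing three binding
#' sites arranged pyramidally, suitable as the vertex unit of the built-in
#' assembly models. `size` scales all dimensions, mimicking small/medium/
#' large metal CBUs.
#'
#' @param size `"small"`, `"medium"` or `"large"`
#' @return an `mf_cbu`-like metal unit with 3 binding sites
#' @export
synthetic_metal_cbu <- function(size = c("small", "medium", "large")) {
  size <- match.arg(size)
  f <- switch(size, small = 1.0, medium = 1.25, large = 1.6)
  ang <- 2 * pi * (0:2) / 3
  atoms <- tibble::tibble(
    element = c("O", rep("Zn", 3), rep("O", 3)),
    charge = 0L, isotope = 0L,
    x = c(0, 1.35 * f * cos(ang), 1.05 * f * cos(ang + pi / 3)),
    y = c(0, 1.35 * f * sin(ang), 1.05 * f * sin(ang + pi / 3)),
    z = c(0.9 * f, rep(0.15 * f, 3), rep(-0.45 * f, 3))
  )
  mol <- new_mol(atoms, NULL)
  ctr <- colMeans(mol_coords(mol))
  sites <- dplyr::bind_rows(lapply(1:3, function(k) {
    pt <- c(2.15 * f * cos(ang[k]), 2.15 * f * sin(ang[k]), -0.6 * f)
    tibble::tibble(bg_id = paste0("m", k), junction = NA_integer_,
                   atoms = list(integer(0)), donors = list(integer(0)),
                   point = list(pt), outward = list(unit_vec(pt - ctr)))
  }))
  structure(list(
    mol = mol,
    smiles = paste0("synthetic-M3O-", size),
    template_name = NA_character_,
    arrangement = "three_pyramidal",
    fragment_keys = character(),
    orientation = integer(),
    n_side_chains = 0L,
    binding_sites = sites,
    torsions = numeric()
  ), class = "mf_cbu")
}
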