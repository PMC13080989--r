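# Shared fixtures. Fragment geometries are memoised inside the package, so
# repeated construction across test files is cheap.

frag_carbox <- function() fragment_from_smiles("*C(=O)[O-]", frag_type = "binding_group")
frag_pyraz <- function() fragment_from_smiles("*c1c[n-]nc1", frag_type = "binding_group")
frag_phen <- function() fragment_from_smiles("*c1ccc(*)cc1")
frag_node <- function() fragment_from_smiles("*c1cc(*)cc(*)c1")
frag_ch2 <- function() fragment_from_smiles("*C*")
frag_yne <- function() fragment_from_smiles("*C#C*")
frag_fluorophen <- function() fragment_from_smiles("*c1ccc(*)cc1F")

tpl <- function(name) shipped_templates()[[name]]

# terephthalate-style assignment on the 1-linker linear template
assign_linear1 <- function(linker = frag_phen(), bg = frag_carbox()) {
  list("0" = bg, "1" = linker, "2" = bg)
}

# Independent enumeration oracle: naive nested loops in R over every
# fragment tuple and every full orientation bit vector; products joined
# and canonicalized by RDKit (molzip) through the system python, entirely
# outside the package's assembly code.
oracle_enumerate_count <- function(template, per_slot_smiles, arrangement) {
  tuples <- expand.grid(rev(lapply(per_slot_smiles, seq_along)),
                        KEEP.OUT.ATTRS = FALSE)
  tuples <- tuples[, rev(seq_along(per_slot_smiles)), drop = FALSE]
  # single binding-group species: drop tuples mixing BG fragments
  bg_slots <- which(template$slots$accepts == "binding_group")
  if (length(bg_slots) > 1) {
    same <- apply(tuples, 1, function(tu) {
      length(unique(vapply(bg_slots, function(s) {
        per_slot_smiles[[s]][tu[s]]
      }, character(1)))) == 1
    })
    tuples <- tuples[same, , drop = FALSE]
  }
  n_link <- length(per_slot_smiles) - 2L
  bitsets <- if (n_link > 0) {
    as.matrix(expand.grid(rep(list(0:1), n_link)))
  } else {
    matrix(integer(), nrow = 1, ncol = 0)
  }
  cands <- list()
  for (i in seq_len(nrow(tuples))) {
    frags <- vapply(seq_along(per_slot_smiles), function(s) {
      per_slot_smiles[[s]][tuples[i, s]]
    }, character(1))
    for (b in seq_len(nrow(bitsets))) {
      cands[[length(cands) + 1L]] <- list(
        fragments = as.list(frags),
        bits = as.list(as.integer(bitsets[b, ])),
        arrangement = arrangement
      )
    }
  }
  payload <- jsonlite::toJSON(cands, auto_unbox = TRUE)
  script <- testthat::test_path("oracle_enumerate.py")
  out <- system2("python", script, input = as.character(payload), stdout = TRUE)
  res <- jsonlite::fromJSON(out[length(out)])
  length(unique(res))
}

# random small library drawn from the fixture pools for oracle comparisons
random_toy_library <- function(n_bg = 1, n_linker = 3, seed = 1) {
  pools <- mopforge:::fixture_pools()
  lib <- generate_fixture_library(seed = 1)
  linkers <- dplyr::filter(lib, .data$frag_type == "linker")
  bgs <- dplyr::filter(lib, .data$frag_type == "binding_group")
  set.seed(seed)
  pick_l <- linkers[sample.int(nrow(linkers), n_linker), ]
  # mix in an asymmetric substituted linker half of the time
  if (seed %% 2 == 0) {
    sc <- dplyr::filter(lib, .data$frag_type == "side_chain")
    sub <- substitute_linker(frag_phen(), sc[1 + seed %% nrow(sc), ])
    if (nrow(sub) > 0) pick_l <- dplyr::bind_rows(pick_l[-1, ], sub[1, ])
  }
  dplyr::bind_rows(bgs[seq_len(n_bg), ], pick_l)
}

# Brute-force 2D grid oracle for ring-window fixtures: largest probe disk
# that fits in the ring plane without touching any atom disk.
ring_window_oracle <- function(ring_xyz, r_atom, grid_step = 0.02) {
  gx <- seq(-2.5, 2.5, by = grid_step)
  best <- 0
  for (px in gx) {
    for (py in gx) {
      d <- sqrt((ring_xyz[, 1] - px)^2 + (ring_xyz[, 2] - py)^2)
      clear <- min(d) - r_atom
      if (clear > best) best <- clear
    }
  }
  2 * best
}

expect_no_clash <- function(mol, factor = mopforge:::mf_clash_factor()) {
  expect_gte(mopforge:::mol_clash_margin(mol, factor), 0)
}
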