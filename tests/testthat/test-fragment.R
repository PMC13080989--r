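# Fragmentation: cleavage rules, typing, side-chain reversion, dedup,
# substitution.

test_that("terephthalate fragments into carboxylate binding groups and a phenylene linker", {
  fr <- fragment_cbu("[O-]C(=O)c1ccc(cc1)C(=O)[O-]")
  expect_identical(nrow(fr), 3L)
  expect_setequal(fr$frag_type, c("binding_group", "linker"))
  bg <- fr[fr$frag_type == "binding_group", ]
  expect_identical(unique(bg$key), canonical_smiles("*C(=O)[O-]"))
  expect_true(all(bg$n_sites == 1L))
  lk <- fr[fr$frag_type == "linker", ]
  expect_identical(lk$key, canonical_smiles("*c1ccc(*)cc1"))
  expect_identical(lk$n_sites, 2L)
})

test_that("side chains are split off and reverted to H on the parent", {
  fr <- fragment_cbu("Cc1cc(ccc1C(=O)[O-])C(=O)[O-]")
  expect_identical(sum(fr$frag_type == "side_chain"), 1L)
  expect_identical(fr$key[fr$frag_type == "side_chain"], canonical_smiles("*C"))
  # parent linker reverted: plain 1,4-phenylene, not the methyl variant
  expect_identical(fr$key[fr$frag_type == "linker"], canonical_smiles("*c1ccc(*)cc1"))
})

test_that("a molecule with no cleavable bond is one untyped 0-site fragment", {
  fr <- fragment_cbu("c1ccccc1")
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$frag_type, "untyped")
  expect_identical(fr$n_sites, 0L)
  expect_identical(fr$key, canonical_smiles("c1ccccc1"))
})

test_that("pyrazolate binding groups are protected and detected", {
  fr <- fragment_cbu("c1cc(ccc1c1cn[n-]c1)c1cn[n-]c1")
  expect_identical(sum(fr$frag_type == "binding_group"), 2L)
  expect_identical(unique(fr$key[fr$frag_type == "binding_group"]),
                   canonical_smiles("*c1c[n-]nc1"))
})

test_that("disconnected input is rejected", {
  expect_error(fragment_cbu("CCO.CCN"), "single-component")
})

test_that("fragment typing is a partition and dedup is idempotent", {
  cbus <- c("[O-]C(=O)c1ccc(cc1)C(=O)[O-]",
            "Cc1cc(ccc1C(=O)[O-])C(=O)[O-]",
            "[O-]C(=O)C#Cc1ccc(cc1)C(=O)[O-]")
  fr <- dplyr::bind_rows(lapply(cbus, fragment_cbu))
  expect_true(all(fr$frag_type %in% mopforge:::fragment_types()))
  lib1 <- fragment_library(fr)
  libN <- fragment_library(dplyr::bind_rows(fr, fr, fr))
  expect_identical(lib1$key, libN$key)
  counts <- library_counts(lib1)
  expect_identical(sum(counts$n), nrow(lib1))
})

test_that("canonical keys separate distinct graphs and are idempotent", {
  k14 <- canonical_key(frag_phen())
  k13 <- canonical_key(fragment_from_smiles("*c1cccc(*)c1"))
  expect_false(k14 == k13)
  expect_identical(canonical_key(fragment_from_smiles(k14)), k14)
})

test_that("round trip: assembly then fragmentation returns the input keys", {
  cbu <- assemble_geometry(tpl("linear_1"), assign_linear1())
  fr <- fragment_cbu(cbu$mol)
  expect_setequal(unique(fr$key), c(frag_carbox()$key, frag_phen()$key))
  expect_identical(sum(fr$key == frag_carbox()$key), 2L)

  # two-linker chain with a cyclic and an acyclic linker
  a2 <- list("0" = frag_carbox(), "1" = frag_phen(), "2" = frag_yne(),
             "3" = frag_carbox())
  cbu2 <- assemble_geometry(tpl("linear_2"), a2)
  fr2 <- fragment_cbu(cbu2$mol)
  expect_setequal(unique(fr2$key),
                  c(frag_carbox()$key, frag_phen()$key, frag_yne()$key))
})

test_that("substitution enumerates symmetry-distinct C-H positions", {
  p <- substitute_linker(frag_phen(), fragment_from_smiles("*C"))
  expect_identical(nrow(p), 1L) # all four ring positions are equivalent
  expect_identical(p$n_sites, 2L)
  expect_false(p$symmetric)
  expect_identical(p$n_side_chains, 1L)
  # meta-substituted linker has two distinct positions relative to nothing:
  # pyridine-2,5-diyl has three inequivalent ring C-H positions
  p2 <- substitute_linker(fragment_from_smiles("*c1ccc(*)nc1"),
                          fragment_from_smiles("*C"))
  expect_identical(nrow(p2), 3L)
})

test_that("substitution rejects degenerate side chains and non-C-H linkers", {
  expect_error(substitute_linker(frag_phen(), fragment_from_smiles("*[H]")),
               "degenerate")
  ether <- fragment_from_smiles("*O*")
  out <- substitute_linker(ether, fragment_from_smiles("*C"))
  expect_identical(nrow(out), 0L)
})

test_that("24 fixture side chains give 24 unique asymmetric benzene linkers", {
  lib <- generate_fixture_library(seed = 1)
  side <- lib[lib$category == "side_chain", ]
  expect_identical(nrow(side), 24L)
  out <- substituted_linker_set(frag_phen(), side)
  expect_identical(nrow(out), 24L)
  expect_true(all(!out$symmetric))
  expect_true(all(out$n_sites == 2L))
})
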