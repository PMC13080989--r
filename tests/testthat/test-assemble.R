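# CBU assembly: SMILES level, geometry level, torsion handling.

test_that("SMILES assembly reproduces hand-drawn products", {
  s <- assemble_smiles(tpl("linear_1"), assign_linear1(), 0L)
  expect_identical(s, canonical_smiles("[O-]C(=O)c1ccc(cc1)C(=O)[O-]"))
  s2 <- assemble_smiles(tpl("planar_0"),
                        list("0" = frag_carbox(), "1" = frag_node()),
                        integer(0))
  expect_identical(s2, canonical_smiles("[O-]C(=O)c1cc(cc(c1)C(=O)[O-])C(=O)[O-]"))
})

test_that("orientation bits of a symmetric linker do not change the product", {
  a <- assign_linear1()
  expect_identical(assemble_smiles(tpl("linear_1"), a, 0L),
                   assemble_smiles(tpl("linear_1"), a, 1L))
})

test_that("geometry assembly yields dummy-free, clash-free structures", {
  fixtures <- list(
    assemble_geometry(tpl("linear_1"), assign_linear1()),
    assemble_geometry(tpl("linear_1"), assign_linear1(bg = frag_pyraz())),
    assemble_geometry(tpl("bent_1"),
                      list("0" = frag_carbox(), "1" = frag_ch2(),
                           "2" = frag_carbox())),
    assemble_geometry(tpl("planar_0"),
                      list("0" = frag_carbox(), "1" = frag_node())),
    assemble_geometry(tpl("linear_2"),
                      list("0" = frag_carbox(), "1" = frag_phen(),
                           "2" = frag_yne(), "3" = frag_carbox()))
  )
  for (cbu in fixtures) {
    expect_length(mopforge:::dummy_idx(cbu$mol), 0L)
    expect_no_clash(cbu$mol)
    expect_identical(nrow(cbu$binding_sites),
                     if (cbu$arrangement == "three_planar") 3L else 2L)
  }
})

test_that("SMILES- and geometry-level assembly agree on composition", {
  cases <- list(
    list(tpl("linear_1"), assign_linear1(), 0L),
    list(tpl("linear_1"), assign_linear1(linker = frag_fluorophen()), 1L),
    list(tpl("planar_0"), list("0" = frag_carbox(), "1" = frag_node()),
         integer(0))
  )
  for (cs in cases) {
    expect_identical(assemble_geometry(cs[[1]], cs[[2]], cs[[3]])$smiles,
                     assemble_smiles(cs[[1]], cs[[2]], cs[[3]]))
  }
})

test_that("junction bond length equals the mapped site length", {
  cbu <- assemble_geometry(tpl("linear_1"), assign_linear1())
  mol <- cbu$mol
  xyz <- mopforge:::mol_coords(mol)
  # junction bonds connect atoms of different slots
  slots <- mol$atoms$slot
  jb <- mol$bonds[slots[mol$bonds$a1] != slots[mol$bonds$a2], ]
  lens <- sqrt(rowSums((xyz[jb$a1, , drop = FALSE] - xyz[jb$a2, , drop = FALSE])^2))
  # sites were normalized to covalent C-C length at embedding
  expect_true(all(abs(lens - 1.50) < 0.05))
})

# Synthetic torsion fixtures built from placed coordinates. Each fragment
# is an anchor carbon with a dummy along +x, an arm atom, and blocker
# atoms two bonds from the anchor (so blocker/blocker pairs across the
# junction are 1-6 and subject to the clash check while 1-4 pairs are
# excluded by construction).
make_blocked_site <- function(blockers) {
  atoms <- dplyr::bind_rows(
    tibble::tibble(element = "C", charge = 0L, isotope = 0L, x = 0, y = 0, z = 0),
    tibble::tibble(element = "*", charge = 0L, isotope = 0L, x = 1.5, y = 0, z = 0),
    tibble::tibble(element = "C", charge = 0L, isotope = 0L, x = 0, y = 1.4, z = 0),
    blockers
  )
  bonds <- dplyr::bind_rows(
    tibble::tibble(a1 = 1L, a2 = 2L, order = 1L),
    tibble::tibble(a1 = 1L, a2 = 3L, order = 1L),
    tibble::tibble(a1 = 3L, a2 = 3L + seq_len(nrow(blockers)), order = 1L)
  )
  mopforge:::new_mol(atoms, bonds)
}

test_that("the torsion scan resolves a constructed eclipsing clash", {
  one_cl <- tibble::tibble(element = "Cl", charge = 0L, isotope = 0L,
                           x = 1.5, y = 2.0, z = 0)
  one_br <- dplyr::mutate(one_cl, element = "Br")
  host <- mopforge:::tag_mol(make_blocked_site(one_cl), "h")
  guest <- mopforge:::tag_mol(make_blocked_site(one_br), "g")
  res <- mopforge:::join_fragments(host, mopforge:::instance_sites(host)[[1]],
                                   guest, mopforge:::instance_sites(guest)[[1]],
                                   geometry = TRUE)
  # the aligned starting pose eclipses Cl and Br; a rotation clears it
  expect_gt(res$torsion_used, 0)
  expect_no_clash(res$mol)
})

test_that("a site blocked at every torsion fails assembly", {
  ang <- 2 * pi * (0:11) / 12
  ring <- tibble::tibble(element = "Cl", charge = 0L, isotope = 0L,
                         x = 1.5, y = 2 * cos(ang), z = 2 * sin(ang))
  one_br <- tibble::tibble(element = "Br", charge = 0L, isotope = 0L,
                           x = 1.5, y = 2.0, z = 0)
  host <- mopforge:::tag_mol(make_blocked_site(ring), "h")
  guest <- mopforge:::tag_mol(make_blocked_site(one_br), "g")
  err <- tryCatch(
    mopforge:::join_fragments(host, mopforge:::instance_sites(host)[[1]],
                              guest, mopforge:::instance_sites(guest)[[1]],
                              geometry = TRUE),
    mopforge_assembly_failure = function(e) e
  )
  expect_true(is_assembly_failure(err))
})

test_that("a valence-violating junction raises a structured error", {
  # carbon already carrying four explicit bonds plus the dummy
  atoms <- tibble::tibble(
    element = c("C", "*", "F", "F", "F", "F"), charge = 0L, isotope = 0L,
    x = c(0, 1.5, -0.7, -0.7, -0.7, 0.5), y = c(0, 0, 1, -1, 0, 1.2),
    z = c(0, 0, 0.5, 0.5, -1, 0.8)
  )
  bonds <- tibble::tibble(a1 = 1L, a2 = 2:6, order = 1L)
  bad <- mopforge:::tag_mol(mopforge:::new_mol(atoms, bonds), "b")
  ok <- mopforge:::tag_mol(frag_carbox()$mol[[1]], "c")
  err <- tryCatch(
    mopforge:::join_fragments(bad, mopforge:::instance_sites(bad)[[1]],
                              ok, mopforge:::instance_sites(ok)[[1]],
                              geometry = FALSE),
    mopforge_assembly_failure = function(e) e
  )
  expect_true(is_assembly_failure(err))
  expect_match(conditionMessage(err), "valence")
})
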