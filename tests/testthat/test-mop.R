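# Geometric MOP assembly.

# Point-like toy units whose binding cones exactly match the reference
# polyhedron, so docking is exact up to numerical precision.
toy_metal_for <- function(model, reach = 2) {
  U <- do.call(rbind, model$sites$u)
  i <- which(model$sites$class == "3-pyramidal")[1]
  partners <- model$edges$organic[model$edges$metal == i]
  dirs <- t(vapply(partners, function(j) {
    mopforge:::unit_vec(U[j, ] - U[i, ])
  }, numeric(3)))
  atoms <- tibble::tibble(element = "Zn", charge = 0L, isotope = 0L,
                          x = 0, y = 0, z = 0)
  sites <- dplyr::bind_rows(lapply(seq_len(nrow(dirs)), function(k) {
    tibble::tibble(bg_id = paste0("m", k), junction = NA_integer_,
                   atoms = list(integer(0)), donors = list(integer(0)),
                   point = list(reach * dirs[k, ]),
                   outward = list(dirs[k, ]))
  }))
  structure(list(mol = mopforge:::new_mol(atoms, NULL), smiles = "toy-metal",
                 arrangement = "three_pyramidal", n_side_chains = 0L,
                 binding_sites = sites), class = "mf_cbu")
}

toy_organic_for <- function(model, reach = 3) {
  U <- do.call(rbind, model$sites$u)
  i <- which(model$sites$class != "3-pyramidal")[1]
  partners <- model$edges$metal[model$edges$organic == i]
  dirs <- t(vapply(partners, function(j) {
    mopforge:::unit_vec(U[j, ] - U[i, ])
  }, numeric(3)))
  atoms <- tibble::tibble(element = "C", charge = 0L, isotope = 0L,
                          x = 0, y = 0, z = 0)
  sites <- dplyr::bind_rows(lapply(seq_len(nrow(dirs)), function(k) {
    tibble::tibble(bg_id = paste0("o", k), junction = NA_integer_,
                   atoms = list(integer(0)), donors = list(integer(0)),
                   point = list(reach * dirs[k, ]),
                   outward = list(dirs[k, ]))
  }))
  arr <- mopforge:::model_organic_arrangement(model)
  structure(list(mol = mopforge:::new_mol(atoms, NULL), smiles = "toy-organic",
                 arrangement = arr, n_side_chains = 0L,
                 binding_sites = sites), class = "mf_cbu")
}

test_that("point-like units land on the scaled polyhedron sites", {
  model <- assembly_model("(3-pyramidal)4(2-linear)6")
  met <- toy_metal_for(model, reach = 2)
  org <- toy_organic_for(model, reach = 3)
  mop <- assemble_mop(model, met, org)
  U <- do.call(rbind, model$sites$u)
  d <- sqrt(sum((U[1, ] - U[5, ])^2)) # uniform metal-organic separation
  s_expect <- (2 + 3) / d
  expect_equal(mop$scale, s_expect, tolerance = 1e-9)
  # one atom per unit: centroids are the atom positions
  for (i in seq_len(nrow(model$sites))) {
    at <- mop$atoms[mop$atoms$unit == i, ]
    expect_equal(as.numeric(at[1, c("x", "y", "z")]),
                 s_expect * U[i, ], tolerance = 1e-6)
  }
})

test_that("stoichiometry follows the model name", {
  met <- synthetic_metal_cbu("small")
  cbu <- assemble_geometry(tpl("linear_1"), assign_linear1())
  m23 <- assembly_model("(3-pyramidal)2(2-linear)3")
  mop <- assemble_mop(m23, met, cbu)
  units <- mop$atoms[!duplicated(mop$atoms$unit), ]
  expect_identical(sum(units$gbu_class == "3-pyramidal"), 2L)
  expect_identical(sum(units$gbu_class == "2-linear"), 3L)

  m46 <- assembly_model("(3-pyramidal)4(2-linear)6")
  mop2 <- assemble_mop(m46, met, cbu)
  units2 <- mop2$atoms[!duplicated(mop2$atoms$unit), ]
  expect_identical(sum(units2$gbu_class == "3-pyramidal"), 4L)
  expect_identical(sum(units2$gbu_class == "2-linear"), 6L)
  # total atom count = sum over units
  expect_identical(nrow(mop2$atoms),
                   4L * nrow(met$mol$atoms) + 6L * nrow(cbu$mol$atoms))
})

test_that("assembly is deterministic and rigid-motion invariant", {
  met <- synthetic_metal_cbu("small")
  cbu <- assemble_geometry(tpl("linear_1"), assign_linear1())
  model <- assembly_model("(3-pyramidal)2(2-linear)3")
  mop1 <- assemble_mop(model, met, cbu)
  mop2 <- assemble_mop(model, met, cbu)
  expect_identical(mop1$atoms, mop2$atoms)

  # rotate + translate the organic CBU input
  R <- mopforge:::rotation_about_axis(c(1, 2, 3), 0.83)
  t_vec <- c(5, -3, 2)
  cbu_rot <- cbu
  cbu_rot$mol <- mopforge:::mol_set_coords(
    cbu$mol, mopforge:::apply_rigid(mopforge:::mol_coords(cbu$mol), R, t_vec))
  cbu_rot$binding_sites <- mopforge:::cbu_binding_sites(cbu_rot$mol)
  mop3 <- assemble_mop(model, met, cbu_rot)
  x1 <- as.matrix(mop1$atoms[, c("x", "y", "z")])
  x3 <- as.matrix(mop3$atoms[, c("x", "y", "z")])
  fit <- mopforge:::kabsch(x3, x1)
  rmsd <- sqrt(mean(rowSums((mopforge:::apply_rigid(x3, fit$R, fit$t) - x1)^2)))
  expect_lt(rmsd, 1e-6)
})

test_that("a longer linker strictly increases the fitted scale", {
  met <- synthetic_metal_cbu("small")
  model <- assembly_model("(3-pyramidal)2(2-linear)3")
  short <- assemble_geometry(tpl("linear_1"), assign_linear1())
  long <- assemble_geometry(
    tpl("linear_2"),
    list("0" = frag_carbox(), "1" = frag_phen(), "2" = frag_yne(),
         "3" = frag_carbox()))
  s1 <- assemble_mop(model, met, short)$scale
  s2 <- assemble_mop(model, met, long)$scale
  expect_gt(s2, s1)
})

test_that("narrow geometry raises an assembly failure with the unit pair", {
  met <- synthetic_metal_cbu("small")
  # anthracene-9,10 linker: wide flanks on the narrow trigonal lantern
  wide <- assemble_geometry(
    tpl("linear_1"),
    assign_linear1(linker = fragment_from_smiles("*c1c2ccccc2c(*)c2ccccc12")))
  err <- tryCatch(
    assemble_mop(assembly_model("(3-pyramidal)2(2-linear)3"), met, wide),
    mopforge_assembly_failure = function(e) e
  )
  expect_true(is_assembly_failure(err))
  expect_length(err$pair, 2L)
})

test_that("arity mismatches are rejected up front", {
  met <- synthetic_metal_cbu("small")
  cbu <- assemble_geometry(tpl("linear_1"), assign_linear1())
  expect_error(assemble_mop(assembly_model("(3-pyramidal)2(2-bent)3"),
                            met, cbu), "arrangement")
  bad_metal <- met
  bad_metal$binding_sites <- met$binding_sites[1:2, ]
  expect_error(assemble_mop(assembly_model("(3-pyramidal)2(2-linear)3"),
                            bad_metal, cbu), "3 binding sites")
})
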