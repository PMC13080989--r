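# Cavity descriptors and synthesizability metrics.

test_that("inner sphere matches the closed form on shell fixtures", {
  shell <- tibble::tibble(element = "C",
                          x = c(10, -10, 0, 0), y = c(0, 0, 10, -10), z = 0)
  inn <- inner_sphere(shell, vdw = c(C = 1.5))
  expect_equal(inn$diameter, 17.0, tolerance = 1e-12)
  expect_equal(inn$volume, pi / 6 * 17^3, tolerance = 1e-9)
  # atom at the centroid clamps to zero
  inn0 <- inner_sphere(dplyr::bind_rows(shell,
                                        tibble::tibble(element = "C", x = 0, y = 0, z = 0)))
  expect_identical(inn0$diameter, 0)
  # volume/diameter consistency as typed
  expect_equal(pi / 6 * 2^3, 4.18879, tolerance = 1e-5)
})

test_that("inner sphere is invariant under rigid motion", {
  set.seed(3)
  cloud <- tibble::tibble(element = sample(c("C", "N", "O"), 30, TRUE),
                          x = rnorm(30, sd = 6), y = rnorm(30, sd = 6),
                          z = rnorm(30, sd = 6))
  R <- mopforge:::rotation_about_axis(c(1, 1, 0), 1.1)
  moved <- cloud
  xyz <- mopforge:::apply_rigid(as.matrix(cloud[, c("x", "y", "z")]), R, c(3, -2, 7))
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  expect_equal(inner_sphere(cloud)$diameter, inner_sphere(moved)$diameter,
               tolerance = 1e-9)
})

test_that("window diameter matches the brute-force grid oracle on a ring", {
  ang <- 2 * pi * (0:5) / 6
  ring <- tibble::tibble(element = "C", x = 5 * cos(ang), y = 5 * sin(ang), z = 0)
  oracle <- ring_window_oracle(as.matrix(ring[, c("x", "y", "z")]), 1.7)
  got <- window_diameter(ring, n_rays = 2000, vdw = c(C = 1.7))
  expect_equal(got$diameter, oracle, tolerance = 0.05)
})

test_that("removing obstructing atoms strictly widens a cage window", {
  dirs <- mopforge:::fibonacci_sphere(400)
  shell <- tibble::tibble(element = "C", x = 4 * dirs[, 1],
                          y = 4 * dirs[, 2], z = 4 * dirs[, 3])
  hole <- function(deg) shell[dirs[, 3] < cos(deg * pi / 180), ]
  w_small <- window_diameter(hole(30), n_rays = 1200)$diameter
  w_large <- window_diameter(hole(45), n_rays = 1200)$diameter
  expect_gt(w_small, 0)
  expect_gt(w_large, w_small)
})

test_that("a fully enclosed cage has no window", {
  dirs <- mopforge:::fibonacci_sphere(400)
  dense <- tibble::tibble(element = "C", x = 4 * dirs[, 1],
                          y = 4 * dirs[, 2], z = 4 * dirs[, 3])
  got <- window_diameter(dense, n_rays = 600)
  expect_identical(got$diameter, 0)
  expect_identical(got$n_windows, 0L)
})

test_that("inner sphere of the toy tetrahedral cage matches its construction", {
  # single-atom units of zero vdW contribution: radius = organic site radius
  model <- assembly_model("(3-pyramidal)4(2-linear)6")
  U <- do.call(rbind, model$sites$u)
  s <- 12
  atoms <- tibble::tibble(element = "C",
                          x = s * U[, 1], y = s * U[, 2], z = s * U[, 3])
  inn <- inner_sphere(atoms, vdw = c(C = 1.7))
  r_org <- s * sqrt(sum(U[5, ]^2)) # edge-midpoint radius < vertex radius
  expect_equal(inn$diameter, 2 * (r_org - 1.7), tolerance = 1e-9)
})

test_that("SAscore behaves like the fragment-contribution reference", {
  vals <- sa_score(c("c1ccccc1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O"))
  expect_true(all(vals >= 1 & vals <= 10))
  expect_equal(vals[1], 1.0, tolerance = 1e-6) # benzene is the floor
  # atom-order invariance
  expect_equal(sa_score("C1=CC=CC=C1CCO"), sa_score("OCCc1ccccc1"),
               tolerance = 1e-9)
  # added stereocentres and a macrocycle increase the score
  simple <- sa_score("CCCCCC(=O)NCC")
  complex_mol <- sa_score("C[C@H]1CCC[C@@H](N1)C2CCCCCCCCCC2")
  expect_gt(complex_mol, simple)
  expect_error(sa_score("*C(=O)[O-]"), "dummy")
})

test_that("side-chain counts come from provenance and survive re-canonicalization", {
  cbu0 <- assemble_geometry(tpl("linear_1"), assign_linear1())
  expect_identical(side_chain_count(cbu0), 0L)

  sub <- substitute_linker(frag_phen(), fragment_from_smiles("*C"))
  # one substituted linker used in each of the three node arms
  a <- list("0" = frag_carbox(), "1" = sub, "2" = frag_node())
  cbu3 <- assemble_geometry(tpl("planar_1"), a)
  expect_identical(side_chain_count(cbu3), 3L)
  # invariant under re-canonicalization of the CBU smiles
  expect_identical(canonical_smiles(cbu3$smiles), cbu3$smiles)
  expect_identical(side_chain_count(cbu3), 3L)
})
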