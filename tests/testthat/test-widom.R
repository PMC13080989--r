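# Widom insertion: accessibility statistics, limiting cases, oracle
# agreement.

single_atom_host <- function() tibble::tibble(element = "C", x = 0, y = 0, z = 0)

test_that("the zero-potential backend gives exactly zero mean energy", {
  res <- widom_average(single_atom_host(), backend_zero(),
                       n_insertions = 500, seed = 1)
  expect_identical(res$mean_U_int, 0)
  expect_lte(res$n_accessible, res$n_insertions)
})

test_that("an empty region makes every pose accessible", {
  # probe far larger margin than host extent, zero-size host radius
  res <- widom_average(single_atom_host(), backend_zero(),
                       n_insertions = 300, seed = 4, probe = point_probe(),
                       clash_factor = 0)
  expect_identical(res$n_accessible, 300L)
})

test_that("accessible fraction matches the analytic excluded volume", {
  host <- single_atom_host()
  probe <- point_probe(element = "Ar")
  n <- 1e5
  res <- widom_average(host, backend_zero(), n_insertions = n, seed = 9,
                       probe = probe, margin = 5)
  r_hc <- mopforge:::mf_clash_factor() * (vdw_radii("C") + vdw_radii("Ar"))
  p_acc <- 1 - (4 / 3) * pi * r_hc^3 / 10^3
  se <- sqrt(p_acc * (1 - p_acc) / n)
  expect_lt(abs(res$n_accessible / n - p_acc), 3 * se)
})

test_that("Widom mean matches a deterministic grid quadrature for one LJ atom", {
  host <- single_atom_host()
  probe <- point_probe()
  backend <- backend_lj(cutoff = 14)
  res <- widom_average(host, backend, n_insertions = 1e5, seed = 21,
                       probe = probe, margin = 5)

  # midpoint-rule quadrature of the same integrand over the same box,
  # restricted to the accessible region
  r_hc <- mopforge:::mf_clash_factor() * (vdw_radii("C") + vdw_radii("Ar"))
  g <- seq(-5 + 0.05, 5 - 0.05, by = 0.1)
  grid <- expand.grid(x = g, y = g, z = g)
  r <- sqrt(grid$x^2 + grid$y^2 + grid$z^2)
  acc <- r >= r_hc
  host_lj <- mopforge:::uff_lj("C")
  sig <- (host_lj$sigma + probe$sigma) / 2
  eps <- sqrt(host_lj$epsilon * probe$epsilon)
  sr6 <- (sig / r[acc])^6
  u <- 4 * eps * (sr6^2 - sr6)
  u[r[acc] > 14] <- 0
  expected <- mean(u)
  expect_lt(abs(res$mean_U_int - expected), 3 * res$std_error)
})

test_that("a far-separated probe has exactly zero interaction energy", {
  host_tab <- mopforge:::host_atom_table(matrix(0, 1, 3), "C")
  probe <- point_probe()
  backend <- backend_lj(cutoff = 14)
  far_pose <- matrix(c(40, 0, 0), 1, 3) # > 2x cutoff away
  br <- energy_breakdown(host_tab, far_pose, probe, backend)
  expect_identical(br$U_int, br$U_complex - br$U_host - br$U_probe)
  expect_identical(br$U_int, 0)
})

test_that("CO2 near a host is attractive at vdW contact and repulsive inside", {
  host_tab <- mopforge:::host_atom_table(matrix(0, 1, 3), "C")
  probe <- co2_probe()
  backend <- backend_lj()
  near <- energy_breakdown(host_tab, sweep(as.matrix(probe[, c("x", "y", "z")]),
                                           2, c(0, 3.7, 0), `+`),
                           probe, backend)
  inside <- energy_breakdown(host_tab, sweep(as.matrix(probe[, c("x", "y", "z")]),
                                             2, c(0, 2.0, 0), `+`),
                             probe, backend)
  expect_lt(near$U_int, 0)
  expect_gt(inside$U_int, 0)
})

test_that("standard error shrinks like one over root n", {
  host <- single_atom_host()
  se_n <- se_2n <- numeric()
  for (seed in 1:12) {
    se_n <- c(se_n, widom_average(host, backend_lj(), n_insertions = 600,
                                  seed = seed, probe = point_probe())$std_error)
    se_2n <- c(se_2n, widom_average(host, backend_lj(), n_insertions = 1200,
                                    seed = 100 + seed,
                                    probe = point_probe())$std_error)
  }
  ratio <- mean(se_2n) / mean(se_n)
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.15)
})

test_that("rigid rotation of the host leaves the energy distribution unchanged", {
  set.seed(5)
  host <- tibble::tibble(element = c("C", "O", "N"),
                         x = c(0, 2.5, -1.5), y = c(0, 0.5, 1.2),
                         z = c(0, -0.8, 0.3))
  R <- mopforge:::rotation_about_axis(c(0, 0, 1), pi / 2)
  xyz <- mopforge:::apply_rigid(as.matrix(host[, c("x", "y", "z")]), R, c(0, 0, 0))
  host_rot <- host
  host_rot$x <- xyz[, 1]; host_rot$y <- xyz[, 2]; host_rot$z <- xyz[, 3]
  # a z-axis rotation maps the axis-aligned sampling box onto itself, so
  # matched seeds give statistically indistinguishable estimates
  a <- widom_average(host, backend_lj(), n_insertions = 20000, seed = 31,
                     probe = point_probe())
  b <- widom_average(host_rot, backend_lj(), n_insertions = 20000, seed = 77,
                     probe = point_probe())
  expect_lt(abs(a$mean_U_int - b$mean_U_int),
            3 * sqrt(a$std_error^2 + b$std_error^2))
})
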