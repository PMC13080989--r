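# Widom insertion: Monte Carlo estimation of the ensemble-average
# host-guest interaction energy <U_int> of a rigid, isolated cage with a
# rigid CO2 probe, U_int = U(host+probe) - U(host) - U(probe).
#
# Energies come from a pluggable backend that evaluates the total energy
# of an arbitrary atom configuration; the packaged default is classical
# LJ + point charges (TraPPE CO2 probe, UFF host parameters,
# Lorentz-Berthelot mixing). Machine-learned potentials can be supplied
# through the same contract but are not packaged.

KB_EV <- 8.617333262e-5      # Boltzmann constant, eV/K
K_TO_EV <- 8.617333262e-5    # energy in Kelvin units (eps/k) -> eV
KCAL_TO_EV <- 0.0433641      # kcal/mol -> eV per molecule
COULOMB_EV_A <- 14.399645    # e^2/(4 pi eps0), eV * Angstrom

#' Rigid 3-site CO2 probe (TraPPE)
#'
#' C-O bond 1.16 A, linear; LJ eps/k 27.0 K (C), 79.0 K (O); sigma 2.80 A
#' (C), 3.05 A (O); charges +0.70 (C), -0.35 (O).
#' @return tibble with element, x, y, z, sigma (A), epsilon (eV), charge (e)
#' @export
co2_probe <- function() {
  tibble::tibble(
    element = c("C", "O", "O"),
    x = c(0, 1.16, -1.16), y = 0, z = 0,
    sigma = c(2.80, 3.05, 3.05),
    epsilon = c(27.0, 79.0, 79.0) * K_TO_EV,
    charge = c(0.70, -0.35, -0.35)
  )
}

#' Single-site probe (for oracle checks and custom guests)
#' @param sigma LJ sigma in A
#' @param epsilon LJ epsilon in eV
#' @param element element label
#' @return probe tibble as in [co2_probe()]
#' @export
point_probe <- function(sigma = 3.0, epsilon = 100 * K_TO_EV, element = "Ar") {
  tibble::tibble(element = element, x = 0, y = 0, z = 0,
                 sigma = sigma, epsilon = epsilon, charge = 0)
}

# UFF Lennard-Jones parameters: x_i (A, minimum position) and D_i
# (kcal/mol); sigma = x / 2^(1/6).
uff_lj <- function(elements) {
  x <- c(H = 2.886, B = 4.083, C = 3.851, N = 3.660, O = 3.500, F = 3.364,
         Si = 4.295, P = 4.147, S = 4.035, Cl = 3.947, Br = 4.189, I = 4.50,
         Zn = 2.763, Cu = 3.495, V = 3.144, Zr = 3.124)
  d <- c(H = 0.044, B = 0.180, C = 0.105, N = 0.069, O = 0.060, F = 0.050,
         Si = 0.402, P = 0.305, S = 0.274, Cl = 0.227, Br = 0.251, I = 0.339,
         Zn = 0.124, Cu = 0.005, V = 0.016, Zr = 0.069)
  xi <- x[elements]; di <- d[elements]
  xi[is.na(xi)] <- 3.5; di[is.na(di)] <- 0.06
  tibble::tibble(sigma = unname(xi) / 2^(1 / 6),
                 epsilon = unname(di) * KCAL_TO_EV)
}

# Atom configuration table: element, x/y/z, sigma, epsilon, charge.
# Host atoms get per-element parameters; probe rows carry their own.
host_atom_table <- function(xyz, elements, host_params = NULL,
                            host_charges = NULL) {
  par <- if (is.null(host_params)) uff_lj(elements) else {
    i <- match(elements, host_params$element)
    tibble::tibble(sigma = host_params$sigma[i], epsilon = host_params$epsilon[i])
  }
  tibble::tibble(element = elements, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 sigma = par$sigma, epsilon = par$epsilon,
                 charge = host_charges %||% 0)
}

probe_atom_table <- function(pose, probe) {
  tibble::tibble(element = probe$element, x = pose[, 1], y = pose[, 2],
                 z = pose[, 3], sigma = probe$sigma, epsilon = probe$epsilon,
                 charge = probe$charge)
}

#' Lennard-Jones + Coulomb energy backend
#'
#' The backend contract: `evaluate(config)` takes an atom-configuration
#' tibble (element, x, y, z, sigma, epsilon, charge) and returns the total
#' pairwise energy (eV) over all pairs within `cutoff`. Deterministic and
#' size-consistent: far-separated groups contribute no cross terms, so
#' `U_int -> 0`.
#'
#' @param cutoff interaction cutoff in A
#' @return energy backend: list with `evaluate` and `cutoff`
#' @export
backend_lj <- function(cutoff = 14) {
  force(cutoff)
  list(
    name = "lj", cutoff = cutoff,
    evaluate = function(config) {
      n <- nrow(config)
      if (n < 2) return(0)
      xyz <- cbind(config$x, config$y, config$z)
      d <- as.matrix(stats::dist(xyz))
      d[d < 1e-9] <- 1e-9
      sig <- outer(config$sigma, config$sigma, `+`) / 2
      eps <- sqrt(outer(config$epsilon, config$epsilon))
      sr6 <- (sig / d)^6
      e <- 4 * eps * (sr6^2 - sr6) + COULOMB_EV_A * outer(config$charge, config$charge) / d
      e[d > cutoff] <- 0
      diag(e) <- 0
      sum(e) / 2
    }
  )
}

#' Zero-interaction backend (for limiting-case checks)
#' @return an energy backend whose energies vanish identically
#' @export
backend_zero <- function() {
  list(name = "zero", cutoff = 10, evaluate = function(config) 0)
}

#' Energy breakdown of one probe pose
#'
#' Forms `U_int = U_complex - U_host - U_probe` explicitly from three
#' backend evaluations.
#' @param host_tab host atom-configuration tibble (see internals of
#'   [widom_average()]); any tibble with the backend's columns works
#' @param pose 3-column matrix of probe site positions
#' @param probe probe definition tibble (see [co2_probe()])
#' @param backend energy backend (see [backend_lj()])
#' @param u_host optional precomputed host energy
#' @param u_probe optional precomputed probe self-energy
#' @return list with U_complex, U_host, U_probe, U_int (eV)
#' @export
energy_breakdown <- function(host_tab, pose, probe, backend = backend_lj(),
                             u_host = NULL, u_probe = NULL) {
  probe_tab <- probe_atom_table(pose, probe)
  if (is.null(u_host)) u_host <- backend$evaluate(host_tab)
  if (is.null(u_probe)) u_probe <- backend$evaluate(probe_tab)
  u_complex <- backend$evaluate(dplyr::bind_rows(host_tab, probe_tab))
  list(U_complex = u_complex, U_host = u_host, U_probe = u_probe,
       U_int = u_complex - u_host - u_probe)
}

# Sample one probe pose: position uniform in the box, orientation uniform
# over rotations (driven by R's RNG).
sample_pose <- function(box_lo, box_hi, probe) {
  pos <- box_lo + stats::runif(3) * (box_hi - box_lo)
  R <- random_rotation()
  sites <- as.matrix(probe[, c("x", "y", "z")])
  sweep(sites %*% t(R), 2, pos, `+`)
}

pose_accessible <- function(pose, host_xyz, host_r, probe_elements,
                            factor = mf_clash_factor()) {
  pr <- vdw_radii(probe_elements)
  d2 <- outer(rowSums(host_xyz^2), rowSums(pose^2), `+`) - 2 * host_xyz %*% t(pose)
  lim <- factor * outer(host_r, pr, `+`)
  all(d2 >= lim^2)
}

#' Widom insertion estimate of the mean interaction energy
#'
#' Inserts `n_insertions` random rigid probe poses uniformly into the
#' host's bounding box (+ `margin` A) with uniform random orientation;
#' poses with any probe atom inside the hard-core distance
#' (`clash_factor` x vdW sum) of a host atom are inaccessible and skipped.
#' `<U_int>` is the unweighted arithmetic mean over accessible poses;
#' `boltzmann = TRUE` instead weights poses by `exp(-U/kT)`.
#'
#' @param mop host structure (`mf_mop`, `mf_cbu`, or element/x/y/z tibble)
#' @param backend energy backend (see [backend_lj()])
#' @param n_insertions number of trial insertions
#' @param seed integer seed (mandatory; results are reproducible)
#' @param probe probe definition (default rigid CO2)
#' @param margin bounding-box margin in A
#' @param boltzmann Boltzmann-weighted average instead of unweighted
#' @param temp temperature (K) for Boltzmann weighting
#' @param clash_factor hard-core accessibility factor
#' @param host_params,host_charges optional host parameter overrides
#' @return list: mean_U_int (eV), n_insertions, n_accessible, std_error
#'   (eV), seed
#' @export
widom_average <- function(mop, backend = backend_lj(), n_insertions = 10000,
                          seed, probe = co2_probe(), margin = 5,
                          boltzmann = FALSE, temp = 298,
                          clash_factor = mf_clash_factor(),
                          host_params = NULL, host_charges = NULL) {
  stopifnot(n_insertions >= 1)
  if (missing(seed)) stop("a seed is required for Widom sampling", call. = FALSE)
  co <- mop_coordinates(mop)
  host_tab <- host_atom_table(co$xyz, co$elements, host_params, host_charges)
  host_r <- vdw_radii(co$elements)
  box_lo <- apply(co$xyz, 2, min) - margin
  box_hi <- apply(co$xyz, 2, max) + margin
  u_host <- backend$evaluate(host_tab)
  u_probe <- backend$evaluate(probe_atom_table(as.matrix(probe[, c("x", "y", "z")]), probe))

  # the complex configuration is built once; per insertion only the probe
  # coordinates change, so each U_int is still the backend-evaluated
  # difference U(complex) - U(host) - U(probe)
  complex_tab <- dplyr::bind_rows(
    host_tab,
    probe_atom_table(as.matrix(probe[, c("x", "y", "z")]), probe))
  probe_rows <- nrow(host_tab) + seq_len(nrow(probe))

  u <- run_with_seed(seed, {
    vals <- rep(NA_real_, n_insertions)
    for (i in seq_len(n_insertions)) {
      pose <- sample_pose(box_lo, box_hi, probe)
      if (!pose_accessible(pose, co$xyz, host_r, probe$element, clash_factor)) next
      complex_tab$x[probe_rows] <- pose[, 1]
      complex_tab$y[probe_rows] <- pose[, 2]
      complex_tab$z[probe_rows] <- pose[, 3]
      vals[i] <- backend$evaluate(complex_tab) - u_host - u_probe
    }
    vals
  })
  acc <- u[!is.na(u)]
  if (length(acc) == 0) {
    stop("no accessible insertions; increase margin or n_insertions",
         call. = FALSE)
  }
  m <- if (boltzmann) {
    w <- exp(-acc / (KB_EV * temp))
    sum(w * acc) / sum(w)
  } else {
    mean(acc)
  }
  se <- if (length(acc) > 1) stats::sd(acc) / sqrt(length(acc)) else 0
  list(mean_U_int = m, n_insertions = as.integer(n_insertions),
       n_accessible = length(acc), std_error = se, seed = seed)
}
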