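# Cavity and synthesizability descriptors.

mop_coordinates <- function(mop) {
  if (inherits(mop, "mf_mop")) {
    list(xyz = as.matrix(mop$atoms[, c("x", "y", "z")]),
         elements = mop$atoms$element)
  } else if (is_cbu(mop)) {
    list(xyz = mol_coords(mop$mol), elements = mop$mol$atoms$element)
  } else if (is.data.frame(mop)) {
    list(xyz = as.matrix(mop[, c("x", "y", "z")]), elements = mop$element)
  } else {
    stop("cannot extract coordinates from this object", call. = FALSE)
  }
}

#' Inner-sphere diameter and volume of a cage
#'
#' The largest sphere centred at the cage centroid (unweighted mean of all
#' atom positions) that touches no atom's van der Waals surface:
#' `d = 2 * max(0, min_i(|r_i - c| - vdw_i))`, with the spherical volume
#' `V = pi/6 d^3`.
#'
#' @param mop an `mf_mop`, `mf_cbu`, or tibble with element/x/y/z
#' @param vdw optional named radius overrides (Angstrom)
#' @return list with `diameter` (A), `volume` (A^3), `centroid`
#' @export
inner_sphere <- function(mop, vdw = NULL) {
  co <- mop_coordinates(mop)
  stopifnot(nrow(co$xyz) > 0)
  ctr <- colMeans(co$xyz)
  r <- sqrt(rowSums(sweep(co$xyz, 2, ctr)^2)) - vdw_radii(co$elements, vdw)
  d <- 2 * max(0, min(r))
  list(diameter = d, volume = pi / 6 * d^3, centroid = ctr)
}

#' Largest window diameter of a cage
#'
#' Casts rays from the cage centroid along a Fibonacci-sphere set of
#' directions; a ray escapes when its clearance (minimum over atoms of the
#' distance to the half-line minus the vdW radius) is positive. Escaping
#' directions are clustered by angular adjacency; each cluster is one
#' window whose diameter is twice the best clearance in the cluster. The
#' maximum over windows is returned (0 when no ray escapes).
#'
#' @inheritParams inner_sphere
#' @param n_rays number of ray directions
#' @return list with `diameter` (A) and `n_windows`
#' @export
window_diameter <- function(mop, n_rays = 500, vdw = NULL) {
  co <- mop_coordinates(mop)
  ctr <- colMeans(co$xyz)
  pos <- sweep(co$xyz, 2, ctr)
  rad <- vdw_radii(co$elements, vdw)
  dirs <- fibonacci_sphere(n_rays)
  clearance <- vapply(seq_len(n_rays), function(k) {
    u <- dirs[k, ]
    # distance from each atom to the half-line {c + t u, t >= 0}
    t_i <- pmax(as.vector(pos %*% u), 0)
    d_i <- sqrt(rowSums((pos - t_i %*% t(u))^2))
    min(d_i - rad)
  }, numeric(1))
  esc <- which(clearance > 0)
  if (length(esc) == 0) return(list(diameter = 0, n_windows = 0L))
  # angular adjacency graph: mean Fibonacci spacing ~ 2/sqrt(n), connect
  # directions within 2.5x that angle
  cos_lim <- cos(2.5 * 2 / sqrt(n_rays))
  dsub <- dirs[esc, , drop = FALSE]
  adj <- (dsub %*% t(dsub)) >= cos_lim
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  # per-cluster refinement: from the best ray, let the escape path shift
  # laterally (origin offset in the plane perpendicular to the direction)
  # and maximize the bottleneck clearance
  ray_clearance <- function(origin, u) {
    rel <- sweep(pos, 2, origin)
    t_i <- pmax(as.vector(rel %*% u), 0)
    min(sqrt(rowSums((rel - t_i %*% t(u))^2)) - rad)
  }
  best <- vapply(seq_len(max(comp)), function(ci) {
    rays <- esc[comp == ci]
    k <- rays[which.max(clearance[rays])]
    u <- dirs[k, ]
    B <- build_frame(u)[, 2:3]
    opt <- stats::optim(c(0, 0), function(ab) {
      -ray_clearance(as.vector(B %*% ab), u)
    }, method = "Nelder-Mead")
    max(clearance[k], -opt$value)
  }, numeric(1))
  list(diameter = 2 * max(best), n_windows = max(comp))
}

#' Cavity report for a MOP
#'
#' @inheritParams window_diameter
#' @return tibble with inner-sphere diameter/volume, window diameter and
#'   window count
#' @export
cavity_report <- function(mop, n_rays = 500, vdw = NULL) {
  inn <- inner_sphere(mop, vdw = vdw)
  win <- window_diameter(mop, n_rays = n_rays, vdw = vdw)
  tibble::tibble(
    inner_sphere_diameter = inn$diameter,
    inner_sphere_volume = inn$volume,
    window_diameter = win$diameter,
    n_windows = win$n_windows
  )
}

#' Synthetic accessibility score (SAscore)
#'
#' Ertl-Schuffenhauer fragment-contribution score on [1, 10] (1 = easy to
#' make). Computed through the RDKit reference implementation invoked via
#' the system `python`; molecules with dummy atoms are rejected.
#'
#' @param smiles character vector of SMILES
#' @return numeric vector of scores
#' @export
sa_score <- function(smiles) {
  if (length(smiles) == 0) return(numeric())
  if (any(grepl("*", smiles, fixed = TRUE))) {
    stop("sa_score() is defined for complete molecules, not fragments with dummy atoms",
         call. = FALSE)
  }
  script <- paste(
    "import sys, json",
    "from rdkit import Chem, RDLogger",
    "from rdkit.Chem import RDConfig",
    "import os", "RDLogger.DisableLog('rdApp.*')",
    "sys.path.append(os.path.join(RDConfig.RDContribDir, 'SA_Score'))",
    "import sascorer",
    "out = []",
    "for line in sys.stdin:",
    "    line = line.strip()",
    "    if not line: continue",
    "    m = Chem.MolFromSmiles(line)",
    "    out.append(None if m is None else sascorer.calculateScore(m))",
    "print(json.dumps(out))",
    sep = "\n")
  res <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), input = smiles,
            stdout = TRUE, stderr = FALSE)
  )
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("SAscore backend failed", call. = FALSE)
  }
  vals <- jsonlite::fromJSON(res[length(res)])
  if (any(vapply(vals, is.null, logical(1)))) {
    stop("unparseable SMILES passed to sa_score()", call. = FALSE)
  }
  as.numeric(vals)
}

#' Number of side-chain fragments in a CBU
#'
#' Read from fragment provenance: the sum over slots of side-chain
#' substitutions carried by each assigned fragment (node-template arms
#' count once per arm).
#'
#' @param cbu an `mf_cbu`
#' @return integer
#' @export
side_chain_count <- function(cbu) {
  stopifnot(is_cbu(cbu))
  if (is.null(cbu$n_side_chains)) {
    stop("CBU carries no fragment provenance", call. = FALSE)
  }
  as.integer(cbu$n_side_chains)
}

#' Molecular weight of a CBU or mol (g/mol)
#' @param x `mf_cbu` or internal mol
#' @return numeric
#' @export
mol_weight <- function(x) {
  mol <- if (is_cbu(x)) x$mol else x
  masses <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
              F = 18.998, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
              Br = 79.904, I = 126.904, Zn = 65.38, `*` = 0)
  m <- masses[mol$atoms$element]
  m[is.na(m)] <- 0
  sum(m)
}
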