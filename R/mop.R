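# Geometric MOP assembly: position a metal CBU on every 3-pyramidal site
# and an organic CBU on every 2- or 3-class site of a reference polyhedron,
# after uniformly scaling the polyhedron so that paired binding-site
# separations match the sum of the units' binding reaches.

#' Built-in assembly models
#'
#' Four reference topologies:
#' * `(3-pyramidal)4(2-linear)6` - regular tetrahedron, metals at vertices,
#'   linear linkers on edges;
#' * `(3-pyramidal)4(3-planar)4` - tetrahedron vertices plus face centers;
#' * `(3-pyramidal)2(2-bent)3` and `(3-pyramidal)2(2-linear)3` - trigonal
#'   lantern: metals on the +/-z axis, three organics spaced 120 degrees
#'   about the equator.
#' @return character vector of model names
#' @export
assembly_model_names <- function() {
  c("(3-pyramidal)4(2-linear)6", "(3-pyramidal)4(3-planar)4",
    "(3-pyramidal)2(2-bent)3", "(3-pyramidal)2(2-linear)3")
}

#' Construct an assembly model by name
#'
#' @param name one of [assembly_model_names()]
#' @return `mf_assembly_model`: sites (unit positions on the reference
#'   polyhedron with gbu class), connectivity edges, stoichiometry
#' @export
assembly_model <- function(name) {
  name <- match.arg(name, assembly_model_names())
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  if (name == "(3-pyramidal)4(2-linear)6") {
    pairs <- utils::combn(4, 2)
    org <- t(apply(pairs, 2, function(p) (tet[p[1], ] + tet[p[2], ]) / 2))
    sites <- rbind(tet, org)
    class <- c(rep("3-pyramidal", 4), rep("2-linear", 6))
    edges <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      cbind(metal = pairs[, k], organic = 4L + k)
    }))
  } else if (name == "(3-pyramidal)4(3-planar)4") {
    faces <- utils::combn(4, 3)
    org <- t(apply(faces, 2, function(f) colMeans(tet[f, ])))
    sites <- rbind(tet, org)
    class <- c(rep("3-pyramidal", 4), rep("3-planar", 4))
    edges <- do.call(rbind, lapply(seq_len(ncol(faces)), function(k) {
      cbind(metal = faces[, k], organic = 4L + k)
    }))
  } else {
    r0 <- 0.5
    ang <- 2 * pi * (0:2) / 3
    org <- cbind(r0 * cos(ang), r0 * sin(ang), 0)
    sites <- rbind(c(0, 0, 1), c(0, 0, -1), org)
    oc <- if (grepl("2-bent", name)) "2-bent" else "2-linear"
    class <- c(rep("3-pyramidal", 2), rep(oc, 3))
    edges <- rbind(cbind(metal = 1L, organic = 3:5), cbind(metal = 2L, organic = 3:5))
  }
  stoich <- table(class)
  structure(list(
    name = name,
    sites = tibble::tibble(site = seq_len(nrow(sites)), class = class,
                           u = lapply(seq_len(nrow(sites)), function(i) sites[i, ])),
    edges = tibble::as_tibble(as.data.frame(edges)),
    stoichiometry = stats::setNames(as.integer(stoich), names(stoich))
  ), class = "mf_assembly_model")
}

#' @export
print.mf_assembly_model <- function(x, ...) {
  cat("<mf_assembly_model>", x$name, "\n")
  print(x$stoichiometry)
  invisible(x)
}

# organic gbu class -> CBU template arrangement
model_organic_arrangement <- function(model) {
  cls <- setdiff(unique(model$sites$class), "3-pyramidal")
  switch(cls, "2-linear" = "two_linear", "2-bent" = "two_bent",
         "3-planar" = "three_planar")
}

cbu_reach <- function(cbu) {
  ctr <- colMeans(mol_coords(cbu$mol))
  mean(vapply(cbu$binding_sites$point, function(p) sqrt(sum((p - ctr)^2)),
              numeric(1)))
}

# Dock one unit onto its site: least-squares superposition of the unit's
# [centroid, contact points, contact + outward pseudo-atoms] onto the
# site's targets, trying site-to-partner pairings in every permutation and
# keeping the best fit (first on ties - deterministic).
dock_unit <- function(cbu, p, partner_dirs, reach) {
  xyz <- mol_coords(cbu$mol)
  ctr <- colMeans(xyz)
  contacts <- do.call(rbind, cbu$binding_sites$point)
  outward <- do.call(rbind, cbu$binding_sites$outward)
  k <- nrow(contacts)
  stopifnot(k == nrow(partner_dirs))
  targets_for <- function(perm) {
    dirs <- partner_dirs[perm, , drop = FALSE]
    tc <- sweep(reach * dirs, 2, p, `+`)
    rbind(p, tc, tc + dirs)
  }
  src <- rbind(ctr, contacts, contacts + outward)
  perms <- perm_matrix(k)
  best <- NULL
  for (i in seq_len(nrow(perms))) {
    perm <- perms[i, ]
    ref <- targets_for(perm)
    fit <- kabsch(src, ref)
    rss <- sum((apply_rigid(src, fit$R, fit$t) - ref)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss, perm = perm)
    }
  }
  mol <- mol_set_coords(cbu$mol, apply_rigid(xyz, best$fit$R, best$fit$t))
  list(mol = mol, perm = best$perm,
       bg_atoms = cbu$binding_sites$atoms)
}

perm_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}

#' Assemble a MOP from a metal CBU, an organic CBU and an assembly model
#'
#' The reference polyhedron is uniformly scaled so that metal-organic site
#' separations equal the sum of the two units' binding reaches, every unit
#' is rigidly docked onto its site by least-squares superposition of its
#' binding contacts and outward vectors, and inter-unit steric clashes are
#' checked. Clashing organic units are spun about their site axis in
#' `spin_step` degree increments; if any clash survives, an assembly
#' failure condition (class `mopforge_assembly_failure`) is raised carrying
#' the offending unit pair.
#'
#' @param model `mf_assembly_model`
#' @param metal metal CBU (3 binding sites), e.g. [synthetic_metal_cbu()]
#' @param organic assembled organic CBU from [assemble_geometry()]
#' @param spin_step axial spin increment in degrees for clash escape
#' @param clash_factor clash threshold as fraction of vdW-radius sum
#' @return `mf_mop`: atom tibble with unit provenance, model name, scale
#' @export
assemble_mop <- function(model, metal, organic, spin_step = 15,
                         clash_factor = mf_clash_factor()) {
  stopifnot(inherits(model, "mf_assembly_model"))
  if (nrow(metal$binding_sites) != 3L) {
    stop("metal CBU must expose 3 binding sites (3-pyramidal)", call. = FALSE)
  }
  want <- model_organic_arrangement(model)
  if (!identical(organic$arrangement, want)) {
    stop("organic CBU arrangement ", organic$arrangement,
         " does not match model class ", want, call. = FALSE)
  }
  deg <- template_degree(list(arrangement = want))
  if (nrow(organic$binding_sites) != deg) {
    stop("organic CBU must expose ", deg, " binding sites", call. = FALSE)
  }

  r_met <- cbu_reach(metal)
  r_org <- cbu_reach(organic)
  U <- do.call(rbind, model$sites$u)
  d <- sqrt(rowSums((U[model$edges$metal, , drop = FALSE] -
                       U[model$edges$organic, , drop = FALSE])^2))
  L <- r_met + r_org
  s <- sum(d * L) / sum(d * d)
  P <- U * s

  units <- vector("list", nrow(model$sites))
  for (i in seq_len(nrow(model$sites))) {
    cls <- model$sites$class[i]
    partners <- if (cls == "3-pyramidal") {
      model$edges$organic[model$edges$metal == i]
    } else {
      model$edges$metal[model$edges$organic == i]
    }
    dirs <- t(vapply(partners, function(j) unit_vec(P[j, ] - P[i, ]), numeric(3)))
    cbu <- if (cls == "3-pyramidal") metal else organic
    reach <- if (cls == "3-pyramidal") r_met else r_org
    docked <- dock_unit(cbu, P[i, ], dirs, reach)
    units[[i]] <- c(docked, list(class = cls, partners = partners))
  }

  # clash resolution: spin clashing organic units about their site axis
  organic_sites <- which(model$sites$class != "3-pyramidal")
  spin_angles <- seq(0, 360 - spin_step, by = spin_step)
  for (pass in 1:2) {
    clash <- mop_clash_pairs(units, model, clash_factor)
    if (is.null(clash)) break
    progress <- FALSE
    for (i in organic_sites) {
      if (!unit_in_clash(i, units, model, clash_factor)) next
      axis_pts <- P[units[[i]]$partners, , drop = FALSE]
      axis <- if (nrow(axis_pts) >= 2) axis_pts[1, ] - axis_pts[2, ] else
        cross3(P[i, ], axis_pts[1, ] - P[i, ])
      for (ang in spin_angles[-1]) {
        cand <- units[[i]]
        xyz <- mol_coords(cand$mol)
        R <- rotation_about_axis(axis, ang * pi / 180)
        cand$mol <- mol_set_coords(cand$mol,
                                   sweep(sweep(xyz, 2, P[i, ]) %*% t(R), 2, P[i, ], `+`))
        trial <- units
        trial[[i]] <- cand
        if (!unit_in_clash(i, trial, model, clash_factor)) {
          units <- trial
          progress <- TRUE
          break
        }
      }
    }
    if (!progress) break
  }
  clash <- mop_clash_pairs(units, model, clash_factor)
  if (!is.null(clash)) {
    assembly_failure(sprintf("inter-unit clash between units %d and %d",
                             clash[1], clash[2]), pair = clash)
  }

  atoms <- dplyr::bind_rows(lapply(seq_along(units), function(i) {
    m <- units[[i]]$mol
    tibble::tibble(element = m$atoms$element,
                   x = m$atoms$x, y = m$atoms$y, z = m$atoms$z,
                   unit = i, gbu_class = units[[i]]$class,
                   cbu_id = if (units[[i]]$class == "3-pyramidal")
                     metal$smiles %||% "metal" else organic$smiles)
  }))
  structure(list(atoms = atoms, model_name = model$name, scale = s,
                 stoichiometry = model$stoichiometry),
            class = "mf_mop")
}

#' @export
print.mf_mop <- function(x, ...) {
  cat("<mf_mop>", x$model_name, " atoms:", nrow(x$atoms),
      " scale:", round(x$scale, 3), "A\n")
  invisible(x)
}

# Pairwise inter-unit clash test. Atoms of an organic unit's binding group
# are exempt against the connected metal unit (they coordinate it by
# construction).
unit_pair_clash <- function(ui, uj, i, j, model, factor) {
  connected <- any((model$edges$metal == i & model$edges$organic == j) |
                     (model$edges$metal == j & model$edges$organic == i))
  xi <- mol_coords(ui$mol); xj <- mol_coords(uj$mol)
  ei <- ui$mol$atoms$element; ej <- uj$mol$atoms$element
  if (connected) {
    # an organic unit's binding-group atoms coordinate the connected metal
    # cluster; their contacts with it are bonding, not steric
    if (ui$class == "3-pyramidal") {
      keep <- setdiff(seq_len(nrow(xj)), unlist(uj$bg_atoms))
      xj <- xj[keep, , drop = FALSE]; ej <- ej[keep]
    } else {
      keep <- setdiff(seq_len(nrow(xi)), unlist(ui$bg_atoms))
      xi <- xi[keep, , drop = FALSE]; ei <- ei[keep]
    }
  } else if (ui$class != "3-pyramidal" && uj$class != "3-pyramidal" &&
             length(intersect(model$edges$metal[model$edges$organic == i],
                              model$edges$metal[model$edges$organic == j]))) {
    # two organics chelating the same metal cluster: how their donor groups
    # interleave around it is cluster chemistry the purely geometric
    # protocol does not model, so binding-group/binding-group contacts
    # between them are exempt (backbone contacts still count)
    di <- unlist(ui$bg_atoms)
    dj <- unlist(uj$bg_atoms)
    keep_i <- setdiff(seq_len(nrow(xi)), di)
    bb <- clash_score(xi[keep_i, , drop = FALSE], ei[keep_i], xj, ej,
                      factor = factor) < 0
    keep_j <- setdiff(seq_len(nrow(xj)), dj)
    return(bb || clash_score(xi, ei, xj[keep_j, , drop = FALSE], ej[keep_j],
                             factor = factor) < 0)
  }
  clash_score(xi, ei, xj, ej, factor = factor) < 0
}

mop_clash_pairs <- function(units, model, factor) {
  n <- length(units)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (unit_pair_clash(units[[i]], units[[j]], i, j, model, factor)) {
        return(c(i, j))
      }
    }
  }
  NULL
}

unit_in_clash <- function(i, units, model, factor) {
  for (j in setdiff(seq_along(units), i)) {
    if (unit_pair_clash(units[[i]], units[[j]], i, j, model, factor)) return(TRUE)
  }
  FALSE
}

#' Coordinates of a MOP as a tibble
#' @param mop `mf_mop`
#' @return tibble with element, x, y, z and unit provenance
#' @export
mop_atoms <- function(mop) mop$atoms
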