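# Geometry-level CBU assembly and the assembled-CBU result object.

#' Assembled chemical building unit
#'
#' `mf_cbu` bundles the dummy-free molecular graph (with 3D coordinates for
#' geometry-level assembly), the canonical SMILES, provenance (template,
#' fragment key per slot, orientation bits) and the derived binding sites:
#' one row per binding-group instance with its junction atom, donor-centroid
#' contact point and outward unit vector.
#'
#' @param x object to test
#' @return `is_cbu` returns a logical
#' @export
is_cbu <- function(x) inherits(x, "mf_cbu")

new_cbu <- function(mol, smiles, template, fragment_keys, orientation,
                    n_side_chains, torsions = numeric()) {
  structure(list(
    mol = mol,
    smiles = smiles,
    template_name = template$name,
    arrangement = template$arrangement,
    fragment_keys = fragment_keys,
    orientation = orientation,
    n_side_chains = n_side_chains,
    binding_sites = if (mol_has_geometry(mol)) cbu_binding_sites(mol) else NULL,
    torsions = torsions
  ), class = "mf_cbu")
}

#' @export
print.mf_cbu <- function(x, ...) {
  cat("<mf_cbu>", x$template_name, "\n  ", x$smiles, "\n")
  cat("  atoms:", nrow(x$mol$atoms),
      " side chains:", x$n_side_chains,
      " geometry:", mol_has_geometry(x$mol), "\n")
  invisible(x)
}

# Binding sites from bg-tagged atoms: contact point = centroid of the
# binding group's donor atoms (O/N), outward vector from the junction atom
# through that centroid.
cbu_binding_sites <- function(mol) {
  bgs <- unique(stats::na.omit(mol$atoms$bg))
  xyz <- mol_coords(mol)
  rows <- lapply(sort(bgs), function(b) {
    idx <- which(mol$atoms$bg == b & !is.na(mol$atoms$bg))
    junction <- idx[which(mol$atoms$bg_anchor[idx])[1]]
    donors <- idx[mol$atoms$element[idx] %in% c("O", "N")]
    if (length(donors) == 0) donors <- setdiff(idx, junction)
    pt <- colMeans(xyz[donors, , drop = FALSE])
    out <- unit_vec(pt - xyz[junction, ])
    tibble::tibble(bg_id = b, junction = junction,
                   atoms = list(idx), donors = list(donors),
                   point = list(pt), outward = list(out))
  })
  dplyr::bind_rows(rows)
}

slot_multiplicity <- function(template, position) {
  if (template$arrangement == "three_planar" &&
      template$slots$accepts[match(position, template$slots$position)] != "node") 3L else 1L
}

cbu_side_chain_total <- function(template, assignment) {
  sum(vapply(template$slots$position, function(p) {
    frag <- assignment[[as.character(p)]]
    ns <- frag$n_side_chains + as.integer(frag$frag_type == "side_chain")
    ns * slot_multiplicity(template, p)
  }, numeric(1)))
}

#' Assemble a CBU with 3D geometry
#'
#' Fragments are joined pairwise: the incoming fragment's local site frame
#' is aligned to the host's, mapping the dummy of one bonding site onto the
#' neighbor atom of the other and vice versa; dummies are removed and a
#' single bond is created. On steric overlap the torsion about the new bond
#' is scanned in `torsion_step` degree increments; if no clash-free torsion
#' exists within 360 degrees an assembly-failure condition is raised
#' (class `mopforge_assembly_failure`). Binding groups are finally aligned:
#' mutually coplanar for two-arm CBUs, otherwise rotated onto the plane
#' through the binding-group contact points.
#'
#' @inheritParams assemble_smiles
#' @param minimize relax the assembled CBU with the MMFF94 force field
#'   (OpenBabel); default off
#' @param torsion_step torsion-scan increment in degrees
#' @param clash_factor clash threshold as a fraction of the vdW-radius sum
#' @return an [is_cbu()] object with coordinates
#' @export
assemble_geometry <- function(template, assignment, orientation = NULL,
                              minimize = FALSE, torsion_step = 10,
                              clash_factor = mf_clash_factor()) {
  if (is.null(orientation)) orientation <- rep(0L, length(linker_slots(template)))
  trace <- new.env(parent = emptyenv())
  trace$torsions <- numeric()
  mol <- assemble_core(template, assignment, orientation, geometry = TRUE,
                       torsion_step = torsion_step, clash_factor = clash_factor,
                       trace = trace)
  mol <- align_binding_groups(mol, template$arrangement, clash_factor)
  if (minimize) mol <- minimize_mmff94(mol)
  keys <- vapply(as.character(template$slots$position),
                 function(k) assignment[[k]]$key, character(1))
  names(keys) <- as.character(template$slots$position)
  new_cbu(mol, canonical_constitution(mol_to_smiles(mol)), template, keys, orientation,
          cbu_side_chain_total(template, assignment), trace$torsions)
}

# Least-squares plane normal of a point set (smallest-variance direction).
plane_normal <- function(pts) {
  svd(sweep(pts, 2, colMeans(pts)))$v[, 3]
}

# Rotate the atoms `idx` of `mol` about the axis through `pivot` along
# `axis` by `theta` radians.
rotate_atoms <- function(mol, idx, axis, pivot, theta) {
  xyz <- mol_coords(mol)
  R <- rotation_about_axis(axis, theta)
  xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, pivot) %*% t(R),
                      2, pivot, `+`)
  mol_set_coords(mol, xyz)
}

# Minimum nonbonded clash margin of a whole molecule, excluding pairs
# within graph distance 3 (1-2, 1-3, 1-4; consistent with the junction
# exclusion rule). >= 0 means clash-free at the given factor.
mol_clash_margin <- function(mol, factor = mf_clash_factor()) {
  n <- nrow(mol$atoms)
  if (n < 2) return(Inf)
  g <- mol_igraph(mol)
  sp <- igraph::distances(g)
  xyz <- mol_coords(mol)
  r <- vdw_radii(mol$atoms$element)
  d <- as.matrix(stats::dist(xyz))
  lim <- factor * outer(r, r, `+`)
  marg <- d - lim
  marg[sp <= 3] <- Inf
  diag(marg) <- Inf
  min(marg)
}

# Align binding groups after assembly. Each binding-group instance is
# rotated about its terminal junction bond only, so the backbone is
# untouched; a rotation that would introduce a new clash is discarded.
align_binding_groups <- function(mol, arrangement, clash_factor = mf_clash_factor()) {
  sites <- cbu_binding_sites(mol)
  if (is.null(sites) || nrow(sites) < 2) return(mol)
  xyz <- mol_coords(mol)
  margin0 <- mol_clash_margin(mol, clash_factor)

  bg_axis <- function(junction) {
    nb <- mol_neighbors(mol, junction)
    chain <- nb[is.na(mol$atoms$bg[nb]) |
                  mol$atoms$bg[nb] != mol$atoms$bg[junction]]
    if (length(chain) == 0) return(NULL)
    list(axis = xyz[junction, ] - xyz[chain[1], ], pivot = xyz[junction, ])
  }

  scan_rotate <- function(mol, idx, ax, objective) {
    best <- list(theta = 0, val = objective(mol_coords(mol)))
    for (deg in seq(2, 358, by = 2)) {
      cand <- rotate_atoms(mol, idx, ax$axis, ax$pivot, deg * pi / 180)
      v <- objective(mol_coords(cand))
      if (v < best$val - 1e-9) best <- list(theta = deg, val = v)
    }
    if (best$theta == 0) return(mol)
    cand <- rotate_atoms(mol, idx, ax$axis, ax$pivot, best$theta * pi / 180)
    if (mol_clash_margin(cand, clash_factor) >= min(0, margin0)) cand else mol
  }

  if (nrow(sites) == 2) {
    # two-arm CBU: spin the second binding group until its plane is
    # parallel to the first's
    heavy1 <- sites$atoms[[1]][!mol$atoms$element[sites$atoms[[1]]] %in% "H"]
    heavy2 <- sites$atoms[[2]][!mol$atoms$element[sites$atoms[[2]]] %in% "H"]
    if (length(heavy1) < 3 || length(heavy2) < 3) return(mol)
    n1 <- plane_normal(xyz[heavy1, , drop = FALSE])
    ax <- bg_axis(sites$junction[2])
    if (is.null(ax)) return(mol)
    mol <- scan_rotate(mol, sites$atoms[[2]], ax, function(cx) {
      n2 <- plane_normal(cx[heavy2, , drop = FALSE])
      1 - abs(sum(n1 * n2))
    })
  } else {
    # rotate every binding group onto the plane through the contact points
    pts <- do.call(rbind, sites$point)
    nrm <- plane_normal(pts)
    ctr <- colMeans(pts)
    for (i in seq_len(nrow(sites))) {
      idx <- sites$atoms[[i]]
      heavy <- idx[!mol$atoms$element[idx] %in% "H"]
      if (length(heavy) < 3) next
      ax <- bg_axis(sites$junction[i])
      if (is.null(ax)) next
      mol <- scan_rotate(mol, idx, ax, function(cx) {
        sum((sweep(cx[heavy, , drop = FALSE], 2, ctr) %*% nrm)^2)
      })
    }
  }
  mol
}

# MMFF94 relaxation via the obabel command-line tool.
minimize_mmff94 <- function(mol, steps = 1500) {
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(mol_to_sdf(mol), fin)
  status <- system2("obabel", c(fin, "-O", fout, "--minimize", "--ff", "MMFF94",
                                "--steps", as.character(steps)),
                    stdout = FALSE, stderr = FALSE)
  res <- if (file.exists(fout)) parse_sdf_text(paste(readLines(fout), collapse = "\n")) else list()
  if (status != 0 || length(res) != 1 || n_atoms(res[[1]]) != n_atoms(mol)) {
    stop("MMFF94 minimization failed", call. = FALSE)
  }
  mol_set_coords(mol, mol_coords(res[[1]]))
}
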