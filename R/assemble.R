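# CBU assembly: joining fragments at their bonding sites.
#
# SMILES-level assembly operates on the molecular graph only and is used
# for fast enumeration. Geometry-level assembly additionally aligns each
# incoming fragment's local site frame to the host's, maps the dummy of
# one bonding site onto the neighbor atom of the other (and vice versa),
# removes the dummies, bonds the neighbors, and resolves steric overlaps
# by scanning the torsion about the new bond.

assembly_failure <- function(message, junction = NA, pair = NULL) {
  rlang::abort(message, class = "mopforge_assembly_failure",
               junction = junction, pair = pair)
}

#' Test whether an object is an assembly failure condition
#' @param x object returned by [tryCatch()] or similar
#' @return logical
#' @export
is_assembly_failure <- function(x) inherits(x, "mopforge_assembly_failure")

max_valence <- function(element, charge = 0L) {
  base <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5, S = 6,
            Cl = 1, Br = 1, I = 3, Se = 6)
  v <- unname(base[element])
  v[is.na(v)] <- 8
  # simple organic-charge adjustment: cations gain a bond, anions lose one
  v + ifelse(element %in% c("N", "O", "S", "P"), charge, 0L)
}

atom_valence_used <- function(mol, i) {
  b <- mol$bonds
  sum(b$order[b$a1 == i | b$a2 == i])
}

# Tag every atom with a unique id (uid) so indices survive joins/deletions.
tag_mol <- function(mol, prefix, slot = NA_character_, bg = NA_character_) {
  mol$atoms$uid <- paste0(prefix, ".", seq_len(nrow(mol$atoms)))
  mol$atoms$slot <- slot
  mol$atoms$bg <- bg
  mol
}

uid_index <- function(mol, uid) {
  i <- match(uid, mol$atoms$uid)
  if (anyNA(i)) stop("internal: uid not found", call. = FALSE)
  i
}

# Local right-handed site frame: origin at the site's anchor atom, x toward
# the dummy, y orthogonalized toward the nearest other neighbor.
site_frame <- function(mol, anchor, dummy) {
  xyz <- mol_coords(mol)
  x_dir <- xyz[dummy, ] - xyz[anchor, ]
  others <- setdiff(mol_neighbors(mol, anchor), dummy)
  y_hint <- NULL
  if (length(others) > 0) {
    d <- sqrt(rowSums((xyz[others, , drop = FALSE] -
                         matrix(xyz[anchor, ], length(others), 3, byrow = TRUE))^2))
    y_hint <- xyz[others[which.min(d)], ] - xyz[anchor, ]
  }
  build_frame(x_dir, y_hint)
}

# Exclusion pairs across the new bond: atoms within graph distance 3
# (1-2, 1-3 and 1-4). 1-4 separations are fixed by bond geometry, not by
# the junction torsion, and routinely sit near the hard-core threshold in
# valid chemistry; the torsion scan acts on 1-5 and longer contacts.
junction_exclusions <- function(mol, na_idx, nb_idx) {
  sp <- igraph::distances(mol_igraph(mol))
  which(sp <= 3, arr.ind = TRUE)
}

# Join guest onto host at the given sites. Sites are lists
# list(anchor = uid, dummy = uid). With geometry = TRUE the guest is
# rigidly placed, the torsion about the new bond is scanned on clash
# (torsion_step degrees, up to 360), and failure raises an assembly
# failure condition. Returns list(mol, torsion_used, junction = c(anchor
# uids)); the consumed dummies are removed.
join_fragments <- function(host, host_site, guest, guest_site,
                           geometry = TRUE, torsion_step = 10,
                           clash_factor = mf_clash_factor(),
                           junction = NA) {
  ha <- uid_index(host, host_site$anchor)
  hd <- uid_index(host, host_site$dummy)
  ga <- uid_index(guest, guest_site$anchor)
  gd <- uid_index(guest, guest_site$dummy)

  # valence feasibility at the junction (dummy slot is reused, so joining
  # only violates valence for malformed fragments)
  v_h <- atom_valence_used(host, ha) - 1 + 1
  v_g <- atom_valence_used(guest, ga) - 1 + 1
  if (v_h > max_valence(host$atoms$element[ha], host$atoms$charge[ha]) ||
      v_g > max_valence(guest$atoms$element[ga], guest$atoms$charge[ga])) {
    assembly_failure("valence violation at junction", junction = junction)
  }

  if (geometry) {
    if (!mol_has_geometry(host) || !mol_has_geometry(guest)) {
      stop("both fragments need geometry for geometric assembly", call. = FALSE)
    }
    hx <- mol_coords(host)
    gx <- mol_coords(guest)
    # guest anchor lands along the host anchor->dummy direction at the new
    # bond length (the longer of the two stored site lengths, so sites cut
    # from a common parent reproduce the original bond exactly); the guest
    # anchor->dummy direction points back at the host anchor
    bond_len <- max(sqrt(sum((hx[hd, ] - hx[ha, ])^2)),
                    sqrt(sum((gx[gd, ] - gx[ga, ])^2)))
    target_pos <- hx[ha, ] + unit_vec(hx[hd, ] - hx[ha, ]) * bond_len
    F_target <- build_frame(hx[ha, ] - target_pos,
                            site_frame(host, ha, hd)[, 2])
    F_guest <- site_frame(guest, ga, gd)
    R <- F_target %*% t(F_guest)
    gx <- sweep(gx, 2, gx[ga, ])
    gx <- gx %*% t(R)
    gx <- sweep(gx, 2, target_pos, `+`)
    guest <- mol_set_coords(guest, gx)
  }

  bound <- mol_bind(host, guest)
  comb <- bound$mol
  na_i <- ha
  nb_i <- ga + bound$offset
  comb$bonds <- dplyr::bind_rows(comb$bonds,
                                 tibble::tibble(a1 = na_i, a2 = nb_i, order = 1L))

  torsion_used <- 0
  if (geometry) {
    cx <- mol_coords(comb)
    host_idx <- setdiff(seq_len(nrow(host$atoms)), hd)
    guest_idx <- setdiff(seq_len(nrow(guest$atoms)) + bound$offset,
                         gd + bound$offset)
    excl_glob <- junction_exclusions(comb, na_i, nb_i)
    # map exclusion pairs into (host row, guest row) positions
    excl <- cbind(match(excl_glob[, 1], host_idx), match(excl_glob[, 2], guest_idx))
    swap <- is.na(excl[, 1])
    excl[swap, ] <- cbind(match(excl_glob[swap, 2], host_idx),
                          match(excl_glob[swap, 1], guest_idx))
    excl <- excl[stats::complete.cases(excl), , drop = FALSE]

    axis <- cx[nb_i, ] - cx[na_i, ]
    pivot <- cx[na_i, ]
    elem_h <- comb$atoms$element[host_idx]
    elem_g <- comb$atoms$element[guest_idx]
    ok <- FALSE
    for (ang in seq(0, 360 - torsion_step, by = torsion_step)) {
      gxyz <- cx[guest_idx, , drop = FALSE]
      if (ang > 0) {
        Rrot <- rotation_about_axis(axis, ang * pi / 180)
        gxyz <- sweep(sweep(gxyz, 2, pivot) %*% t(Rrot), 2, pivot, `+`)
      }
      margin <- clash_score(cx[host_idx, , drop = FALSE], elem_h,
                            gxyz, elem_g, factor = clash_factor, exclude = excl)
      if (margin >= 0) {
        cx[guest_idx, ] <- gxyz
        torsion_used <- ang
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      assembly_failure("unresolvable steric clash at junction", junction = junction)
    }
    comb <- mol_set_coords(comb, cx)
  }

  comb <- mol_drop_atoms(comb, c(hd, gd + bound$offset))
  list(mol = comb, torsion_used = torsion_used,
       junction = c(host_site$anchor, guest_site$anchor))
}

# Sites of a tagged fragment instance as uid-based descriptors, in stored
# dummy order.
instance_sites <- function(mol) {
  s <- fragment_sites(mol)
  lapply(seq_len(nrow(s)), function(i) {
    list(anchor = mol$atoms$uid[s$anchor[i]], dummy = mol$atoms$uid[s$dummy[i]])
  })
}

# Resolve an assignment entry to a one-row fragment tibble.
assignment_fragment <- function(assignment, position) {
  frag <- assignment[[as.character(position)]]
  if (is.null(frag)) stop("missing assignment for slot ", position, call. = FALSE)
  frag
}

# Build the ordered chain (binding group, linkers...) and return the
# partially assembled arm plus its open site. Used for both two-arm and
# node templates. `orientation` holds one bit per linker slot.
assemble_arm <- function(template, assignment, orientation, geometry,
                         prefix = "a", torsion_step = 10,
                         clash_factor = mf_clash_factor(), trace = NULL) {
  slots <- template$slots
  lpos <- linker_slots(template)
  bg <- assignment_fragment(assignment, slots$position[1])
  part <- tag_mol(fragment_instance_mol(bg, geometry), paste0(prefix, ".s0"),
                  slot = "0", bg = paste0(prefix, ".bg0"))
  sites <- instance_sites(part)
  if (length(sites) != 1) {
    assembly_failure("binding group must expose exactly one bonding site",
                     junction = 0)
  }
  part$atoms$bg_anchor <- part$atoms$uid == sites[[1]]$anchor
  open <- sites[[1]]

  for (j in seq_along(lpos)) {
    pos <- lpos[j]
    frag <- assignment_fragment(assignment, pos)
    inst <- tag_mol(fragment_instance_mol(frag, geometry),
                    paste0(prefix, ".s", pos), slot = as.character(pos))
    inst$atoms$bg_anchor <- FALSE
    fs <- instance_sites(inst)
    if (length(fs) != 2) {
      assembly_failure("linker must expose exactly two bonding sites", junction = pos)
    }
    bit <- orientation[j]
    first <- if (bit == 0L) fs[[1]] else fs[[2]]
    second <- if (bit == 0L) fs[[2]] else fs[[1]]
    res <- join_fragments(part, open, inst, first, geometry = geometry,
                          torsion_step = torsion_step,
                          clash_factor = clash_factor, junction = pos)
    if (!is.null(trace)) trace$torsions <- c(trace$torsions, res$torsion_used)
    part <- res$mol
    open <- second
  }
  list(mol = part, open = open)
}

fragment_instance_mol <- function(frag, geometry) {
  mol <- frag$mol[[1]]
  if (geometry && !mol_has_geometry(mol)) {
    mol2 <- geometry_for_smiles(frag$key)
    if (!mol_has_geometry(mol2)) {
      stop("fragment has no 3D geometry: ", frag$key, call. = FALSE)
    }
    mol <- mol2
  }
  mol
}

# Core assembly driver shared by SMILES- and geometry-level assembly.
assemble_core <- function(template, assignment, orientation, geometry,
                          torsion_step = 10, clash_factor = mf_clash_factor(),
                          trace = NULL) {
  check <- validate_assignment(template, assignment)
  if (!check$valid) {
    stop("invalid assignment: ", paste(check$reasons, collapse = "; "),
         call. = FALSE)
  }
  lpos <- linker_slots(template)
  stopifnot(length(orientation) == length(lpos))
  slots <- template$slots
  last_pos <- slots$position[nrow(slots)]

  if (template$arrangement == "three_planar") {
    node <- assignment_fragment(assignment, last_pos)
    nmol <- tag_mol(fragment_instance_mol(node, geometry), "node",
                    slot = as.character(last_pos))
    nmol$atoms$bg_anchor <- FALSE
    nsites <- instance_sites(nmol)
    out <- nmol
    for (k in seq_along(nsites)) {
      arm <- assemble_arm(template, assignment, orientation, geometry,
                          prefix = paste0("arm", k),
                          torsion_step = torsion_step,
                          clash_factor = clash_factor, trace = trace)
      # node-site uids persist through joins, so they resolve in `out`
      res <- join_fragments(out, nsites[[k]], arm$mol, arm$open,
                            geometry = geometry, torsion_step = torsion_step,
                            clash_factor = clash_factor, junction = last_pos)
      if (!is.null(trace)) trace$torsions <- c(trace$torsions, res$torsion_used)
      out <- res$mol
    }
  } else {
    arm <- assemble_arm(template, assignment, orientation, geometry,
                        torsion_step = torsion_step, clash_factor = clash_factor,
                        trace = trace)
    bg2 <- assignment_fragment(assignment, last_pos)
    inst <- tag_mol(fragment_instance_mol(bg2, geometry),
                    paste0("s", last_pos), slot = as.character(last_pos),
                    bg = "bg1")
    bsites <- instance_sites(inst)
    if (length(bsites) != 1) {
      assembly_failure("binding group must expose exactly one bonding site",
                       junction = last_pos)
    }
    inst$atoms$bg_anchor <- inst$atoms$uid == bsites[[1]]$anchor
    res <- join_fragments(arm$mol, arm$open, inst, bsites[[1]],
                          geometry = geometry, torsion_step = torsion_step,
                          clash_factor = clash_factor, junction = last_pos)
    if (!is.null(trace)) trace$torsions <- c(trace$torsions, res$torsion_used)
    out <- res$mol
  }
  if (length(dummy_idx(out)) != 0) {
    stop("internal: dummy atoms remain after assembly", call. = FALSE)
  }
  out
}

#' Assemble a CBU at the SMILES level
#'
#' Joins the assigned fragments along the template sequence, consuming one
#' dummy site per junction, and returns the canonical SMILES of the
#' dummy-free product.
#'
#' @inheritParams validate_assignment
#' @param orientation integer vector of orientation bits, one per linker
#'   slot (see [expand_orientations()])
#' @return canonical SMILES string
#' @export
assemble_smiles <- function(template, assignment, orientation = NULL) {
  if (is.null(orientation)) orientation <- rep(0L, length(linker_slots(template)))
  mol <- assemble_core(template, assignment, orientation, geometry = FALSE)
  canonical_constitution(mol_to_smiles(mol))
}
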