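# CBU templates: typed, positioned fragment slots with constraints.
#
# A template is an ordered sequence of slots. Sequence position 0 holds the
# first binding group; linker slots follow at positions 1..k; the terminal
# slot is either a second binding group (two_linear / two_bent
# arrangements) or a node fragment (three_planar), in which case the
# partially assembled arm is replicated onto every node bonding site.

template_arrangements <- function() c("two_linear", "two_bent", "three_planar")

#' Construct a CBU template
#'
#' @param name template identifier
#' @param arrangement one of `two_linear`, `two_bent`, `three_planar`
#' @param slots tibble with columns `position` (integer), `accepts`
#'   (fragment type) and optional constraint columns `max_atoms` (heavy-atom
#'   cap), `cyclic`, `linear` (required flag values; NA = unconstrained)
#' @param symmetric_required force the symmetric orientation constraint in
#'   enumeration and optimization over this template
#' @return object of class `mf_template`
#' @export
cbu_template <- function(name, arrangement, slots, symmetric_required = FALSE) {
  arrangement <- match.arg(arrangement, template_arrangements())
  slots <- tibble::as_tibble(slots)
  for (col in c("max_atoms", "cyclic", "linear")) {
    if (is.null(slots[[col]])) slots[[col]] <- NA
  }
  slots$position <- as.integer(slots$position)
  slots <- dplyr::arrange(slots, .data$position)
  stopifnot(!anyDuplicated(slots$position), all(slots$accepts %in% fragment_types()))
  term <- slots$accepts[nrow(slots)]
  if (slots$accepts[1] != "binding_group") {
    stop("slot at position 0 must accept a binding group", call. = FALSE)
  }
  if (arrangement == "three_planar" && term != "node") {
    stop("three_planar templates terminate in a node slot", call. = FALSE)
  }
  if (arrangement != "three_planar" && term != "binding_group") {
    stop("two_linear/two_bent templates terminate in a binding group", call. = FALSE)
  }
  structure(list(name = name, arrangement = arrangement, slots = slots,
                 symmetric_required = isTRUE(symmetric_required)),
            class = "mf_template")
}

#' @export
print.mf_template <- function(x, ...) {
  cat("<mf_template>", x$name, paste0("(", x$arrangement, ")"),
      if (x$symmetric_required) "[symmetric]" else "", "\n")
  print(x$slots)
  invisible(x)
}

linker_slots <- function(template) {
  template$slots$position[template$slots$accepts == "linker"]
}

# degree of the assembled CBU: number of binding groups it exposes
template_degree <- function(template) {
  if (template$arrangement == "three_planar") 3L else 2L
}

slot_admits <- function(slot, frag) {
  if (frag$frag_type != slot$accepts) return("type mismatch")
  if (!is.na(slot$max_atoms) && heavy_count(frag$mol[[1]]) > slot$max_atoms) {
    return("atom count exceeds slot limit")
  }
  if (!is.na(slot$cyclic) && !identical(as.logical(slot$cyclic), frag$cyclic)) {
    return("cyclicity constraint violated")
  }
  if (!is.na(slot$linear)) {
    if (is.na(frag$linear)) return("linearity unknown (fragment has no geometry)")
    if (!identical(as.logical(slot$linear), frag$linear)) {
      return("linearity constraint violated")
    }
  }
  NULL
}

#' Validate a fragment assignment against a template
#'
#' An assignment maps each slot position to one fragment (a one-row
#' fragment tibble). Validation checks that every slot is filled, types
#' match, slot constraints hold, and that a single binding-group species is
#' used across all binding-group slots (mixed binding groups are rejected).
#'
#' @param template an `mf_template`
#' @param assignment named list: slot position (as character) -> fragment row
#' @return list with elements `valid` (logical) and `reasons` (character)
#' @export
validate_assignment <- function(template, assignment) {
  reasons <- character()
  for (i in seq_len(nrow(template$slots))) {
    slot <- template$slots[i, ]
    key <- as.character(slot$position)
    frag <- assignment[[key]]
    if (is.null(frag)) {
      reasons <- c(reasons, paste0("slot ", key, ": unfilled"))
      next
    }
    bad <- slot_admits(slot, frag)
    if (!is.null(bad)) reasons <- c(reasons, paste0("slot ", key, ": ", bad))
  }
  bg_pos <- template$slots$position[template$slots$accepts == "binding_group"]
  bg_keys <- unique(unlist(lapply(as.character(bg_pos), function(k) {
    f <- assignment[[k]]
    if (is.null(f)) NULL else f$key
  })))
  if (length(bg_keys) > 1) {
    reasons <- c(reasons, "mixed binding groups")
  }
  list(valid = length(reasons) == 0, reasons = reasons)
}

#' Expand linker orientation vectors for an assignment
#'
#' Each linker slot carries one bit choosing which of the linker's two
#' bonding sites joins the preceding fragment. Symmetric linkers contribute
#' a fixed 0 bit. With `symmetric = FALSE` every asymmetric linker
#' contributes both bits (cartesian expansion); with `symmetric = TRUE`
#' asymmetric linkers receive the alternating bit `position %% 2`, keeping
#' coordination environments equivalent, and exactly one vector results.
#'
#' @inheritParams validate_assignment
#' @param symmetric apply the symmetric orientation constraint
#' @return list of integer orientation vectors (one bit per linker slot,
#'   in sequence-position order)
#' @export
expand_orientations <- function(template, assignment, symmetric = FALSE) {
  pos <- linker_slots(template)
  if (length(pos) == 0) return(list(integer(0)))
  sym_frag <- vapply(as.character(pos), function(k) {
    isTRUE(assignment[[k]]$symmetric)
  }, logical(1))
  if (symmetric) {
    # alternate along the linker sequence, phase 0 at the first linker slot
    bits <- ifelse(sym_frag, 0L, (pos - min(pos)) %% 2L)
    return(list(as.integer(bits)))
  }
  choices <- lapply(sym_frag, function(s) if (s) 0L else c(0L, 1L))
  grid <- expand.grid(rev(choices), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(choices)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(unlist(grid[i, ])))
}

# --- JSON (de)serialization ----------------------------------------------

template_to_list <- function(template) {
  list(
    name = template$name,
    arrangement = template$arrangement,
    symmetric_required = template$symmetric_required,
    slots = lapply(seq_len(nrow(template$slots)), function(i) {
      s <- template$slots[i, ]
      con <- list()
      if (!is.na(s$max_atoms)) con$max_atoms <- as.integer(s$max_atoms)
      if (!is.na(s$cyclic)) con$cyclic <- as.logical(s$cyclic)
      if (!is.na(s$linear)) con$linear <- as.logical(s$linear)
      list(position = as.integer(s$position), accepts = s$accepts, constraints = con)
    })
  )
}

template_from_list <- function(x) {
  slots <- dplyr::bind_rows(lapply(x$slots, function(s) {
    tibble::tibble(
      position = as.integer(s$position),
      accepts = s$accepts,
      max_atoms = if (is.null(s$constraints$max_atoms)) NA_integer_ else as.integer(s$constraints$max_atoms),
      cyclic = if (is.null(s$constraints$cyclic)) NA else as.logical(s$constraints$cyclic),
      linear = if (is.null(s$constraints$linear)) NA else as.logical(s$constraints$linear)
    )
  }))
  cbu_template(x$name, x$arrangement, slots,
               symmetric_required = isTRUE(x$symmetric_required))
}

#' Read CBU templates from a JSON file
#' @param path JSON file with a list of template definitions
#' @return named list of `mf_template`
#' @export
read_templates <- function(path) {
  xs <- jsonlite::read_json(path)
  out <- lapply(xs, template_from_list)
  stats::setNames(out, vapply(out, function(t) t$name, character(1)))
}

#' Write CBU templates to JSON
#' @param templates list of `mf_template`
#' @param path output file
#' @export
write_templates <- function(templates, path) {
  jsonlite::write_json(lapply(templates, template_to_list), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Built-in CBU template set
#'
#' Eight templates mirroring the category structure of the study space:
#' four two_linear (one to three linker slots), two two_bent and two
#' three_planar. Slot constraints are representative stand-ins, not a
#' reproduction of any published template table.
#' @return named list of `mf_template`
#' @export
shipped_templates <- function() {
  path <- system.file("extdata", "templates.json", package = "mopforge")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "templates.json")
  read_templates(path)
}
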