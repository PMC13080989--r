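# Enumeration of the CBU design space of a template: cartesian product of
# admissible fragments per slot, crossed with linker orientation vectors,
# deduplicated by canonical SMILES.

#' Admissible fragments for each slot of a template
#'
#' Filters a fragment library by each slot's accepted type and constraints.
#' @inheritParams validate_assignment
#' @param library fragment library tibble (see [fragment_library()])
#' @return named list (by slot position) of fragment tibbles
#' @export
admissible_fragments <- function(template, library) {
  out <- lapply(seq_len(nrow(template$slots)), function(i) {
    slot <- template$slots[i, ]
    keep <- vapply(seq_len(nrow(library)), function(j) {
      is.null(slot_admits(slot, library[j, ]))
    }, logical(1))
    library[keep, ] |> dplyr::arrange(.data$key)
  })
  names(out) <- as.character(template$slots$position)
  empty <- vapply(out, nrow, integer(1)) == 0
  if (any(empty)) {
    stop("no admissible fragments for slot(s): ",
         paste(names(out)[empty], collapse = ", "), call. = FALSE)
  }
  out
}

#' Enumerate all CBUs of a template over a fragment library
#'
#' Walks the cartesian product of admissible fragments per slot and, for
#' each assignment, the linker orientation vectors from
#' [expand_orientations()]. Products are deduplicated by canonical SMILES.
#' With `mode = "geometry"` each unique product is additionally assembled
#' in 3D; assignments whose geometric assembly fails are recorded in the
#' `failures` attribute and excluded.
#'
#' @inheritParams validate_assignment
#' @param library fragment library tibble
#' @param symmetric apply the symmetric orientation constraint
#' @param mode `"smiles"` (fast, graph only) or `"geometry"`
#' @return tibble with one row per unique CBU: `smiles`, `template`,
#'   `assignment` (named key vector), `orientation`; plus `cbu` list-column
#'   in geometry mode. Attribute `failures` is a tibble of failed geometric
#'   assemblies.
#' @export
enumerate_cbus <- function(template, library, symmetric = FALSE,
                           mode = c("smiles", "geometry")) {
  mode <- match.arg(mode)
  if (template$symmetric_required) symmetric <- TRUE
  admiss <- admissible_fragments(template, library)
  pos <- as.character(template$slots$position)
  counts <- vapply(admiss, nrow, integer(1))

  grid <- expand.grid(rev(lapply(counts, seq_len)), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(counts)), drop = FALSE]
  names(grid) <- pos

  rows <- list()
  mols <- list()
  failures <- list()
  for (g in seq_len(nrow(grid))) {
    assignment <- stats::setNames(lapply(pos, function(p) {
      admiss[[p]][grid[g, p], ]
    }), pos)
    ok <- validate_assignment(template, assignment)
    if (!ok$valid) next
    for (ori in expand_orientations(template, assignment, symmetric)) {
      res <- tryCatch(
        assemble_core(template, assignment, ori, geometry = FALSE),
        mopforge_assembly_failure = function(e) e
      )
      if (is_assembly_failure(res)) next
      rows[[length(rows) + 1L]] <- list(assignment = assignment, orientation = ori)
      mols[[length(mols) + 1L]] <- res
    }
  }
  if (length(mols) == 0) {
    return(structure(tibble::tibble(smiles = character(), template = character(),
                                    assignment = list(), orientation = list()),
                     failures = tibble::tibble()))
  }
  smi <- canonical_constitution(mols_to_smiles(mols))
  keep <- !duplicated(smi)

  out <- tibble::tibble(
    smiles = smi[keep],
    template = template$name,
    assignment = lapply(rows[keep], function(r) {
      vapply(r$assignment, function(f) f$key, character(1))
    }),
    orientation = lapply(rows[keep], function(r) r$orientation)
  )

  if (mode == "geometry") {
    cbus <- vector("list", nrow(out))
    ok <- rep(TRUE, nrow(out))
    ridx <- which(keep)
    for (i in seq_len(nrow(out))) {
      r <- rows[[ridx[i]]]
      res <- tryCatch(
        assemble_geometry(template, r$assignment, r$orientation),
        mopforge_assembly_failure = function(e) e
      )
      if (is_assembly_failure(res)) {
        ok[i] <- FALSE
        failures[[length(failures) + 1L]] <- tibble::tibble(
          smiles = out$smiles[i], reason = conditionMessage(res),
          junction = as.character(res$junction %||% NA)
        )
      } else {
        cbus[[i]] <- res
      }
    }
    out$cbu <- cbus
    out <- out[ok, ]
  }
  attr(out, "failures") <- dplyr::bind_rows(failures)
  out
}

#' Count MOP configurations without assembling them
#'
#' Pure combinatorics: for each assembly model, the number of organic CBUs
#' compatible with the model's organic class, times the number of metal
#' CBUs; summed over models.
#'
#' @param cbu_sets named list mapping an arrangement (e.g. `two_linear`) to
#'   a set (vector or tibble) of organic CBUs
#' @param models list of assembly models (see [assembly_model()]); each
#'   contributes its organic gbu class
#' @param metals list or vector of metal CBUs
#' @return integer count
#' @export
count_configurations <- function(cbu_sets, models, metals) {
  n_metal <- if (is.data.frame(metals)) nrow(metals) else length(metals)
  total <- 0
  for (m in models) {
    arr <- model_organic_arrangement(m)
    set <- cbu_sets[[arr]]
    n_org <- if (is.null(set)) 0L else if (is.data.frame(set)) nrow(set) else length(set)
    total <- total + n_org * n_metal
  }
  as.integer(total)
}
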