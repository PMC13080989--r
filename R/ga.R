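# Genetic algorithm over the fragment-encoded MOP design space.
#
# One run optimizes within a fixed CBU template. A chromosome is an
# integer gene vector: [assembly-model index, metal index, one fragment
# index per template slot, one orientation bit per linker slot]. The
# population evolves by elitism, tournament selection, uniform gene
# crossover and per-gene mutation, with optional replacement of duplicate
# chromosomes by random ones.

#' Build a search space for one CBU template
#'
#' Filters the fragment library per slot and fixes the ordered lists the
#' chromosome indexes into.
#'
#' @param template `mf_template` (fixed for the whole run)
#' @param library fragment library tibble
#' @param models list of `mf_assembly_model` compatible with the template
#'   arrangement
#' @param metals list of metal CBUs
#' @return `mf_search_space`
#' @export
search_space <- function(template, library, models, metals) {
  if (!is.list(models) || inherits(models, "mf_assembly_model")) models <- list(models)
  arr <- template$arrangement
  ok <- vapply(models, function(m) identical(model_organic_arrangement(m), arr),
               logical(1))
  if (!all(ok)) {
    stop("all assembly models must match the template arrangement", call. = FALSE)
  }
  admiss <- admissible_fragments(template, library)
  structure(list(
    template = template,
    models = models,
    metals = metals,
    slots = admiss,
    linker_positions = linker_slots(template)
  ), class = "mf_search_space")
}

space_gene_sizes <- function(space) {
  unname(c(length(space$models), length(space$metals),
           vapply(space$slots, nrow, integer(1)),
           rep(2L, length(space$linker_positions))))
}

space_size <- function(space) prod(space_gene_sizes(space))

chromosome_length <- function(space) 2L + length(space$slots) + length(space$linker_positions)

#' Decode a chromosome into a concrete configuration
#'
#' @param chrom integer gene vector (1-based indices; orientation genes in
#'   1:2 decode to bits 0/1)
#' @param space `mf_search_space`
#' @return list: model, metal, assignment (slot -> fragment row),
#'   orientation (integer bits)
#' @export
decode_chromosome <- function(chrom, space) {
  sizes <- space_gene_sizes(space)
  if (length(chrom) != length(sizes)) {
    stop("chromosome length ", length(chrom), " does not match space (",
         length(sizes), ")", call. = FALSE)
  }
  if (any(chrom < 1L | chrom > sizes)) {
    stop("gene out of range", call. = FALSE)
  }
  ns <- length(space$slots)
  assignment <- stats::setNames(lapply(seq_len(ns), function(i) {
    space$slots[[i]][chrom[2L + i], ]
  }), names(space$slots))
  list(
    model = space$models[[chrom[1]]],
    metal = space$metals[[chrom[2]]],
    assignment = assignment,
    orientation = as.integer(chrom[2L + ns + seq_along(space$linker_positions)] - 1L)
  )
}

#' Encode a configuration back into a chromosome
#' @param config list as returned by [decode_chromosome()]
#' @param space `mf_search_space`
#' @return integer gene vector
#' @export
encode_chromosome <- function(config, space) {
  mi <- which(vapply(space$models, function(m) identical(m$name, config$model$name),
                     logical(1)))[1]
  ti <- which(vapply(space$metals, function(m) identical(m$smiles, config$metal$smiles),
                     logical(1)))[1]
  fi <- vapply(names(space$slots), function(k) {
    match(config$assignment[[k]]$key, space$slots[[k]]$key)
  }, integer(1))
  as.integer(c(mi, ti, fi, config$orientation + 1L))
}

# Phenotype key for caching: symmetric linkers erase their orientation bit.
config_key <- function(chrom, space) {
  ns <- length(space$slots)
  bits <- chrom[2L + ns + seq_along(space$linker_positions)] - 1L
  if (length(bits)) {
    lp <- as.character(space$linker_positions)
    sym <- vapply(seq_along(lp), function(i) {
      isTRUE(space$slots[[lp[i]]][chrom[2L + which(names(space$slots) == lp[i])], ]$symmetric)
    }, logical(1))
    bits[sym] <- 0L
  }
  paste(c(chrom[seq_len(2L + ns)], bits), collapse = "-")
}

#' Cavity-targeting fitness
#'
#' `fitness = -(w_vol * |V - target| + w_sa * SA + w_side * n_side)`:
#' penalizes deviation from the target inner-sphere volume (A^3), the
#' SAscore and the side-chain count, combined as printed with the default
#' 1:10:10 weight ratio (no unit normalization).
#'
#' @param volume inner-sphere volume (A^3)
#' @param sa SAscore
#' @param n_side side-chain fragment count
#' @param target_volume target cavity volume (A^3); default 625, i.e.
#'   1.05x the van der Waals volume of C60
#' @param weights numeric length-3: volume, SAscore, side-chain weights
#' @return numeric fitness (higher is better; 0 is the ideal)
#' @export
cavity_fitness <- function(volume, sa, n_side, target_volume = 625,
                           weights = c(1, 10, 10)) {
  stopifnot(length(weights) == 3, all(weights >= 0))
  -(weights[1] * abs(volume - target_volume) + weights[2] * sa +
      weights[3] * n_side)
}

#' Interaction-energy fitness
#'
#' `fitness = -<U_int>`: more strongly binding (more negative) mean
#' interaction energies rank higher.
#' @param mean_u_int ensemble-average interaction energy (eV)
#' @return numeric fitness
#' @export
energy_fitness <- function(mean_u_int) -mean_u_int

#' Full MOP evaluation pipeline as a GA fitness function
#'
#' Decodes a configuration, assembles the organic CBU (geometry) and the
#' MOP, and scores it: `mode = "cavity"` combines inner-sphere volume,
#' SAscore and side-chain count via [cavity_fitness()];
#' `mode = "energy"` runs Widom insertion and uses [energy_fitness()].
#' Failed assemblies return NA (the GA ranks them below every evaluated
#' candidate with a sentinel one unit worse than the worst finite
#' fitness).
#'
#' @param space `mf_search_space`
#' @param mode `"cavity"` or `"energy"`
#' @param target_volume,weights cavity-fitness parameters
#' @param n_insertions,widom_seed Widom parameters for `mode = "energy"`
#' @return function(config) -> list(fitness, details)
#' @export
mop_fitness <- function(space, mode = c("cavity", "energy"),
                        target_volume = 625, weights = c(1, 10, 10),
                        n_insertions = 2000, widom_seed = 1L) {
  mode <- match.arg(mode)
  function(config) {
    res <- tryCatch({
      cbu <- assemble_geometry(space$template, config$assignment,
                               config$orientation)
      mop <- assemble_mop(config$model, config$metal, cbu)
      if (mode == "cavity") {
        inn <- inner_sphere(mop)
        sa <- sa_score(cbu$smiles)
        ns <- side_chain_count(cbu)
        list(fitness = cavity_fitness(inn$volume, sa, ns,
                                      target_volume, weights),
             details = tibble::tibble(volume = inn$volume, sa = sa,
                                      n_side = ns))
      } else {
        w <- widom_average(mop, n_insertions = n_insertions, seed = widom_seed)
        list(fitness = energy_fitness(w$mean_U_int),
             details = tibble::tibble(mean_U_int = w$mean_U_int,
                                      n_accessible = w$n_accessible))
      }
    }, mopforge_assembly_failure = function(e) {
      list(fitness = NA_real_, details = tibble::tibble(reason = conditionMessage(e)))
    })
    res
  }
}

#' Default GA hyperparameters
#'
#' Population 30 evolved for 30 generations; mutation probability 0.15,
#' crossover probability 0.9, elitism proportion 0.05 (at least one
#' elite), tournament size 3.
#' @param pop_size population size
#' @param n_generations number of generations
#' @param p_mut per-gene mutation probability
#' @param p_cross per-pair crossover probability
#' @param elitism_frac elite proportion
#' @param tournament_size tournament size
#' @param replace_duplicates replace duplicate chromosomes with random ones
#' @return list of parameters
#' @export
ga_params <- function(pop_size = 30, n_generations = 30, p_mut = 0.15,
                      p_cross = 0.9, elitism_frac = 0.05,
                      tournament_size = 3, replace_duplicates = TRUE) {
  stopifnot(p_mut >= 0, p_mut <= 1, p_cross >= 0, p_cross <= 1,
            elitism_frac >= 0, elitism_frac <= 1)
  list(pop_size = as.integer(pop_size),
       n_generations = as.integer(n_generations),
       p_mut = p_mut, p_cross = p_cross, elitism_frac = elitism_frac,
       tournament_size = as.integer(tournament_size),
       replace_duplicates = isTRUE(replace_duplicates))
}

random_chromosome <- function(sizes) {
  vapply(sizes, function(s) sample.int(s, 1L), integer(1))
}

#' Evolve a population over a search space
#'
#' Generation 0 is drawn uniformly at random from the seed. Each
#' generation: rank by fitness (failures last), copy the elites, fill the
#' rest by tournament selection, uniform per-gene crossover (probability
#' `p_cross`), per-gene mutation (probability `p_mut`, resampling the gene
#' excluding its current value), and optional replacement of duplicate
#' chromosomes by random ones. Fitness evaluations are cached by
#' configuration key, so re-visited configurations cost nothing.
#'
#' @param space `mf_search_space`
#' @param fitness function(config) -> list(fitness, details) (see
#'   [mop_fitness()]), or function(config) -> numeric
#' @param params list from [ga_params()]
#' @param seed integer seed; the whole trajectory is reproducible from it
#' @return `mf_ga_run`: trajectory tibble (per generation: best/mean
#'   fitness, best chromosome), evaluation log, best configuration
#' @export
evolve <- function(space, fitness, params = ga_params(), seed = 1L) {
  sizes <- space_gene_sizes(space)
  n_elite <- max(1L, round(params$elitism_frac * params$pop_size))

  cache <- new.env(parent = emptyenv())
  evals <- list()
  evaluate <- function(chrom) {
    key <- config_key(chrom, space)
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    res <- fitness(decode_chromosome(chrom, space))
    if (is.numeric(res)) res <- list(fitness = res, details = NULL)
    assign(key, res, envir = cache)
    evals[[length(evals) + 1L]] <<- tibble::tibble(
      key = key, genes = paste(chrom, collapse = "-"),
      fitness = res$fitness %||% NA_real_)
    res
  }

  run_with_seed(seed, {
    pop <- lapply(seq_len(params$pop_size), function(i) random_chromosome(sizes))
    traj <- list()
    for (gen in 0:params$n_generations) {
      fit <- vapply(pop, function(ch) evaluate(ch)$fitness, numeric(1))
      finite <- fit[!is.na(fit)]
      sentinel <- if (length(finite)) min(finite) - 1 else -Inf
      fit_rank <- ifelse(is.na(fit), sentinel, fit)
      ord <- order(fit_rank, decreasing = TRUE)
      traj[[gen + 1L]] <- tibble::tibble(
        generation = gen,
        best_fitness = fit_rank[ord[1]],
        mean_fitness = mean(fit_rank),
        best_genes = paste(pop[[ord[1]]], collapse = "-")
      )
      if (gen == params$n_generations) break

      new_pop <- pop[ord[seq_len(n_elite)]]
      tournament <- function() {
        idx <- sample.int(params$pop_size, min(params$tournament_size, params$pop_size))
        pop[[idx[which.max(fit_rank[idx])]]]
      }
      while (length(new_pop) < params$pop_size) {
        p1 <- tournament()
        p2 <- tournament()
        child <- if (stats::runif(1) < params$p_cross) {
          mask <- stats::runif(length(sizes)) < 0.5
          ifelse(mask, p1, p2)
        } else p1
        mut <- which(stats::runif(length(sizes)) < params$p_mut & sizes > 1L)
        for (g in mut) {
          child[g] <- sample(setdiff(seq_len(sizes[g]), child[g]), 1L)
        }
        new_pop[[length(new_pop) + 1L]] <- as.integer(child)
      }
      if (params$replace_duplicates) {
        keys <- vapply(new_pop, function(ch) paste(ch, collapse = "-"), character(1))
        dup <- which(duplicated(keys))
        for (d in dup) new_pop[[d]] <- random_chromosome(sizes)
      }
      pop <- new_pop
    }

    trajectory <- dplyr::bind_rows(traj)
    best_row <- trajectory[which.max(trajectory$best_fitness), ]
    best_chrom <- as.integer(strsplit(best_row$best_genes, "-")[[1]])
    structure(list(
      trajectory = trajectory,
      evaluations = dplyr::bind_rows(evals),
      best = list(chromosome = best_chrom,
                  fitness = best_row$best_fitness,
                  config = decode_chromosome(best_chrom, space)),
      params = params, seed = seed,
      space_size = space_size(space)
    ), class = "mf_ga_run")
  })
}

#' @export
print.mf_ga_run <- function(x, ...) {
  cat("<mf_ga_run>", nrow(x$trajectory) - 1, "generations, ",
      nrow(x$evaluations), "unique evaluations /", x$space_size,
      "configurations\n")
  cat("  best fitness:", x$best$fitness, "\n")
  invisible(x)
}

#' Exhaustive search over a (small) space
#'
#' Reference optimum for validating GA runs: evaluates every configuration
#' and returns the best.
#' @inheritParams evolve
#' @return list: chromosome, fitness, n_evaluated
#' @export
exhaustive_search <- function(space, fitness) {
  sizes <- space_gene_sizes(space)
  grid <- expand.grid(rev(lapply(sizes, seq_len)), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(sizes)), drop = FALSE]
  best <- NULL
  seen <- new.env(parent = emptyenv())
  n_eval <- 0L
  for (i in seq_len(nrow(grid))) {
    chrom <- as.integer(unlist(grid[i, ]))
    key <- config_key(chrom, space)
    if (!is.null(get0(key, envir = seen))) next
    assign(key, TRUE, envir = seen)
    res <- fitness(decode_chromosome(chrom, space))
    f <- if (is.numeric(res)) res else res$fitness
    n_eval <- n_eval + 1L
    if (!is.na(f) && (is.null(best) || f > best$fitness)) {
      best <- list(chromosome = chrom, fitness = f)
    }
  }
  c(best, list(n_evaluated = n_eval))
}
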