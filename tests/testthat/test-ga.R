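# Genetic algorithm: encoding, fitness arithmetic, evolution dynamics.

# small spaces built on the fixture library
toy_space <- function(template_name = "linear_1", n_models = 2, n_metals = 3) {
  lib <- generate_fixture_library(seed = 1)
  models <- list(assembly_model("(3-pyramidal)4(2-linear)6"),
                 assembly_model("(3-pyramidal)2(2-linear)3"))[seq_len(n_models)]
  metals <- lapply(c("small", "medium", "large")[seq_len(n_metals)], synthetic_metal_cbu)
  search_space(tpl(template_name), lib, models, metals)
}

# deterministic, additively structured toy fitness: heavy-atom counts with
# mild gene interactions, cheap enough to enumerate exhaustively
toy_fitness <- function(cfg) {
  ha <- sum(vapply(cfg$assignment, function(f) {
    mopforge:::heavy_count(f$mol[[1]])
  }, numeric(1)))
  -(3 * abs(ha - 17) +
      5 * (cfg$model$name == "(3-pyramidal)2(2-linear)3") +
      2 * (cfg$metal$smiles == "synthetic-M3O-small") +
      sum(cfg$orientation))
}

test_that("chromosomes decode to configurations and back", {
  sp <- toy_space()
  sizes <- mopforge:::space_gene_sizes(sp)
  set.seed(11)
  for (i in 1:25) {
    chrom <- vapply(sizes, function(s) sample.int(s, 1L), integer(1))
    cfg <- decode_chromosome(chrom, sp)
    expect_identical(encode_chromosome(cfg, sp), chrom)
  }
  expect_error(decode_chromosome(rep(1L, length(sizes) + 1L), sp), "length")
  bad <- rep(1L, length(sizes)); bad[1] <- 99L
  expect_error(decode_chromosome(bad, sp), "out of range")
  # all-zero-offset chromosome selects the first element of every list
  first <- decode_chromosome(rep(1L, length(sizes)), sp)
  expect_identical(first$model$name, sp$models[[1]]$name)
  expect_identical(first$assignment[["1"]]$key, sp$slots[["1"]]$key[1])
})

test_that("cavity fitness reproduces the printed weighting", {
  expect_identical(cavity_fitness(625, 0, 0), 0)
  expect_identical(cavity_fitness(625, 2, 1, weights = c(1, 10, 10)), -30)
  # hand-computed: |600-625|*1 + 3*10 + 2*10 = 75
  expect_identical(cavity_fitness(600, 3, 2), -75)
  # candidates nearer the target rank higher at equal SA and side count
  expect_gt(cavity_fitness(620, 2, 1), cavity_fitness(520, 2, 1))
})

test_that("energy fitness ranks stronger binders higher", {
  expect_identical(energy_fitness(0), 0)
  expect_gt(energy_fitness(-0.3), energy_fitness(-0.1))
})

test_that("best-so-far fitness is monotone and the same seed reproduces the run", {
  sp <- toy_space()
  r1 <- evolve(sp, toy_fitness, ga_params(), seed = 7)
  r2 <- evolve(sp, toy_fitness, ga_params(), seed = 7)
  expect_identical(r1$trajectory, r2$trajectory)
  best_so_far <- cummax(r1$trajectory$best_fitness)
  expect_identical(r1$trajectory$best_fitness, best_so_far)
  # evaluation cache: unique evaluations bounded by pop x (gens + 1)
  expect_lte(nrow(r1$evaluations), 30 * 31)
})

test_that("without variation operators the population is stationary", {
  sp <- toy_space()
  p <- ga_params(p_mut = 0, p_cross = 0, replace_duplicates = FALSE,
                 n_generations = 8)
  run <- evolve(sp, toy_fitness, p, seed = 3)
  tr <- run$trajectory
  # after generation 1 the chromosome pool only reshuffles: best is constant
  expect_identical(unique(tr$best_fitness[-1]), tr$best_fitness[2])
  expect_true(all(diff(tr$mean_fitness[-1]) >= -1e-12))
})

test_that("failed evaluations rank below every evaluated candidate", {
  sp <- toy_space()
  flaky <- function(cfg) {
    if (cfg$metal$smiles == "synthetic-M3O-small") {
      return(list(fitness = NA_real_, details = NULL))
    }
    list(fitness = toy_fitness(cfg), details = NULL)
  }
  run <- evolve(sp, flaky, ga_params(n_generations = 10), seed = 2)
  expect_true(is.finite(run$best$fitness))
  expect_false(identical(run$best$config$metal$smiles, "synthetic-M3O-small"))
})

test_that("the GA finds the exhaustive optimum in most seeds with partial coverage", {
  sp <- toy_space()
  expect_lte(mopforge:::space_size(sp), 1000)
  ex <- exhaustive_search(sp, toy_fitness)
  hits <- 0
  fracs <- numeric()
  for (seed in 1:10) {
    run <- evolve(sp, toy_fitness, ga_params(), seed = seed)
    if (run$best$fitness >= ex$fitness - 1e-12) hits <- hits + 1
    fracs <- c(fracs, nrow(run$evaluations) / mopforge:::space_size(sp))
    expect_identical(run$trajectory$best_fitness,
                     cummax(run$trajectory$best_fitness))
  }
  expect_gte(hits, 9)
  expect_lt(mean(fracs), 0.5)
})
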