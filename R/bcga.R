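#' @title Binary-coded genetic algorithm for gene-subset search
#'
#' @description
#' Candidate solutions are fixed-length bit strings over the gene index
#' set: bit i set means gene i enters the classifier.  Each generation
#' ranks the population by fitness, draws parents by normalized geometric
#' ranking, recombines pairs with a hybrid operator that produces four
#' offspring (two by uniform crossover, two by two-point crossover) and
#' keeps the best two, mutates offspring at a low per-bit rate, and carries
#' the best individual seen so far into the next generation unchanged
#' (elitism), which makes the best-so-far fitness monotone.
#'
#' @name bcga
NULL

#' Genetic-algorithm configuration
#'
#' Defaults follow the published protocol: population 200, crossover
#' probability 0.80, mutation probability 0.20, geometric selection
#' parameter q = 0.01, 50 generations, initial chromosomes carrying
#' between 20 and 200 genes.
#'
#' The mutation probability is interpreted per offspring: with probability
#' `mutation_prob` an offspring is mutated, and mutation then flips each
#' bit independently with rate `1/L` (one expected flip).  A per-bit rate
#' of 0.20 on chromosomes with thousands of loci would randomise thousands
#' of genes per event and destroy convergence.
#'
#' @param population_size Even positive integer (parents are paired).
#' @param crossover_prob Per-pair probability of applying hybrid crossover.
#' @param mutation_prob Per-offspring probability of applying mutation.
#' @param selection_q Geometric ranking parameter q in (0, 1).
#' @param max_generations Number of generations to run (0 = initial
#'   population only).
#' @param init_gene_range Integer pair: inclusive range for the number of
#'   set bits in each initial chromosome.
#' @param target_accuracy Optional early-stop threshold on the best mean
#'   validation accuracy.
#' @param split_mode `"shared"` (all chromosomes within a generation are
#'   scored on identical splits, reducing comparison noise) or
#'   `"independent"`.
#' @param master_seed Integer seed fixing the whole run.
#' @return A `ga_config` object.
#' @export
ga_config <- function(population_size = 200L, crossover_prob = 0.80,
                      mutation_prob = 0.20, selection_q = 0.01,
                      max_generations = 50L, init_gene_range = c(20L, 200L),
                      target_accuracy = NULL,
                      split_mode = c("shared", "independent"),
                      master_seed = 1L) {
  split_mode <- match.arg(split_mode)
  population_size <- as.integer(population_size)
  if (population_size < 2L || population_size %% 2L != 0L)
    stop("population_size must be an even integer >= 2 (pairing requirement)")
  for (p in c(crossover_prob, mutation_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (!(selection_q > 0 && selection_q < 1))
    stop("selection_q must lie in (0, 1)")
  init_gene_range <- as.integer(init_gene_range)
  if (length(init_gene_range) != 2L || init_gene_range[1] < 1L ||
      init_gene_range[1] > init_gene_range[2])
    stop("init_gene_range must be an increasing pair of positive integers")
  structure(list(population_size = population_size,
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 selection_q = selection_q,
                 max_generations = as.integer(max_generations),
                 init_gene_range = init_gene_range,
                 target_accuracy = target_accuracy,
                 split_mode = split_mode,
                 master_seed = as.integer(master_seed)),
            class = "ga_config")
}

#' Initialise a random population
#'
#' Each chromosome's set-bit count is drawn uniformly from
#' `config$init_gene_range` and the set positions uniformly without
#' replacement.
#'
#' @param n_genes Chromosome length.
#' @param config A `ga_config`.
#' @param seed Integer seed.
#' @return List of `population_size` integer 0/1 vectors.
#' @export
init_population <- function(n_genes, config = ga_config(),
                            seed = config$master_seed) {
  rng <- config$init_gene_range
  if (rng[2] > n_genes)
    stop("init_gene_range upper bound (", rng[2],
         ") exceeds the gene count (", n_genes, ")")
  with_seed(seed, {
    lapply(seq_len(config$population_size), function(i) {
      k <- if (rng[1] == rng[2]) rng[1]
           else sample(seq.int(rng[1], rng[2]), 1L)
      bits <- integer(n_genes)
      bits[sample.int(n_genes, k)] <- 1L
      bits
    })
  })
}

#' Normalized geometric ranking selection probabilities
#'
#' Rank r (1 = best) receives probability `q' (1-q)^(r-1)` with
#' `q' = q / (1 - (1-q)^N)`, so the probabilities sum to one and decay
#' geometrically from best to worst.
#'
#' @param n Population size (>= 1).
#' @param q Selection parameter in (0, 1).
#' @return Probability vector of length `n`, best rank first.
#' @export
selection_probabilities <- function(n, q) {
  if (!(q > 0 && q < 1)) stop("q must lie in (0, 1)")
  if (n < 1L) stop("n must be >= 1")
  qp <- q / (1 - (1 - q)^n)
  qp * (1 - q)^(seq_len(n) - 1)
}

#' Uniform crossover
#'
#' A fair per-locus mask decides which parent each child copies: child 1
#' takes parent a where the mask is set and parent b elsewhere; child 2 is
#' the complement.
#'
#' @param a,b Equal-length 0/1 parent vectors.
#' @param seed Integer seed.
#' @return List of two children.
#' @export
uniform_crossover <- function(a, b, seed = 1L) {
  if (length(a) != length(b))
    stop("parents differ in length: ", length(a), " vs ", length(b))
  mask <- with_seed(seed, stats::runif(length(a)) < 0.5)
  list(ifelse(mask, a, b), ifelse(mask, b, a))
}

#' Two-point crossover
#'
#' Two cut points `0 <= i < j <= L` are drawn uniformly without
#' replacement; the children exchange the half-open segment `[i, j)`
#' (0-based) and inherit the rest unchanged.
#'
#' @param a,b Equal-length 0/1 parent vectors (length >= 2).
#' @param seed Integer seed.
#' @param cuts Optional integer pair of cut points, overriding the random
#'   draw (useful for worked examples).
#' @return List of two children.
#' @export
two_point_crossover <- function(a, b, seed = 1L, cuts = NULL) {
  L <- length(a)
  if (L != length(b))
    stop("parents differ in length: ", L, " vs ", length(b))
  if (L < 2L) stop("two-point crossover needs length >= 2")
  if (is.null(cuts))
    cuts <- with_seed(seed, sort(sample(0:L, 2L)))
  else
    cuts <- sort(as.integer(cuts))
  if (cuts[1] < 0L || cuts[2] > L || cuts[1] == cuts[2])
    stop("cuts must satisfy 0 <= i < j <= L")
  seg <- seq.int(cuts[1] + 1L, cuts[2]) # R indices of [i, j)
  c1 <- a; c1[seg] <- b[seg]
  c2 <- b; c2[seg] <- a[seg]
  list(c1, c2)
}

# Any all-zero chromosome gets one uniformly chosen bit set: the fitness
# divides by the set-bit count, so empty subsets are never admitted.
repair_chromosome <- function(bits, seed = 1L) {
  if (sum(bits) == 0L)
    bits[with_seed(seed, sample.int(length(bits), 1L))] <- 1L
  bits
}

#' Hybrid crossover: four offspring, keep the best two
#'
#' Builds two offspring by uniform crossover and two by two-point
#' crossover, repairs any all-zero offspring, evaluates all four with the
#' supplied fitness function, and returns the two fittest as replacements
#' for the parents.
#'
#' @param a,b Parent chromosomes.
#' @param fitness_fn Function taking a chromosome and returning either a
#'   numeric fitness or a `fitness_result`.
#' @param seed Integer seed.
#' @return List with `chromosomes` (the two winners), `fitness` (their
#'   fitness records) and `offspring` (all four, for inspection).
#' @export
hybrid_crossover <- function(a, b, fitness_fn, seed = 1L) {
  u <- uniform_crossover(a, b, seed = derive_seed(seed, 1L))
  t <- two_point_crossover(a, b, seed = derive_seed(seed, 2L))
  kids <- c(u, t)
  kids <- lapply(seq_along(kids), function(i)
    repair_chromosome(kids[[i]], seed = derive_seed(seed, 3L, i)))
  fits <- lapply(kids, fitness_fn)
  vals <- vapply(fits, fitness_value, numeric(1))
  ord <- order(-vals, vapply(kids, sum, numeric(1)), seq_along(kids))
  keep <- ord[1:2]
  list(chromosomes = kids[keep], fitness = fits[keep], offspring = kids)
}

#' Random mutation
#'
#' Each bit flips independently with probability `per_bit_rate`; the result
#' is repaired to carry at least one set bit.
#'
#' @param bits Chromosome.
#' @param per_bit_rate Flip probability per locus, in \[0, 1\].
#' @param seed Integer seed.
#' @return Mutated chromosome.
#' @export
mutate <- function(bits, per_bit_rate, seed = 1L) {
  if (per_bit_rate < 0 || per_bit_rate > 1)
    stop("per_bit_rate must lie in [0, 1]")
  flip <- with_seed(seed, stats::runif(length(bits)) < per_bit_rate)
  bits[flip] <- 1L - bits[flip]
  repair_chromosome(bits, seed = derive_seed(seed, 99L))
}

fitness_value <- function(fit) {
  if (inherits(fit, "fitness_result")) fit$fitness else as.numeric(fit)
}

fitness_accuracy <- function(fit) {
  if (inherits(fit, "fitness_result")) fit$mean_accuracy else as.numeric(fit)
}

# Best-first ranking: fitness descending, then fewer selected genes, then
# stable insertion order.
rank_population <- function(pop) {
  vals <- vapply(pop, function(p) fitness_value(p$fit), numeric(1))
  sizes <- vapply(pop, function(p) sum(p$bits), numeric(1))
  order(-vals, sizes, seq_along(pop))
}

#' Run the generational loop
#'
#' Evolves a population of gene-subset chromosomes against the
#' split-train-test fitness of [evaluate_subset()] (or a caller-supplied
#' surrogate).  Each generation: rank, draw parents by normalized
#' geometric ranking, recombine each pair with probability
#' `crossover_prob` via [hybrid_crossover()] (otherwise the parents pass
#' through), mutate each offspring with probability `mutation_prob`,
#' replace one slot with an untouched copy of the best individual ever
#' seen, and re-score the population.  Within a generation every
#' chromosome is scored on the same random splits (under the default
#' `split_mode = "shared"`), so fitness comparisons are not confounded by
#' split luck.  Identical chromosomes within a generation are scored once
#' (memoised); the fitness itself is always the full repeated-split
#' evaluation, never a cheaper proxy.
#'
#' Termination: after `max_generations`, or as soon as the best mean
#' validation accuracy reaches `target_accuracy`.
#'
#' @param dataset A labeled `expression_dataset` (may be `NULL` when a
#'   surrogate `fitness_fn` is supplied).
#' @param config A `ga_config`.
#' @param params A `fitness_params` object.
#' @param elm Classifier settings passed to [evaluate_subset()].
#' @param fitness_fn Optional surrogate fitness `function(bits)`
#'   (e.g. OneMax for sanity checks); when supplied, `dataset` is ignored
#'   and `n_genes` must be given.
#' @param n_genes Chromosome length; defaults to `n_genes(dataset)`.
#' @param verbose If `TRUE`, log per-generation best/mean fitness to
#'   stderr.
#' @return A `ga_state`: final `population` (chromosomes with cached
#'   fitness), `best_ever`, per-generation `history` data frame, and the
#'   echoed configuration.
#' @export
evolve <- function(dataset = NULL, config = ga_config(),
                   params = fitness_params(), elm = list(),
                   fitness_fn = NULL, n_genes = NULL, verbose = FALSE) {
  if (is.null(fitness_fn)) {
    stopifnot(inherits(dataset, "expression_dataset"))
    n_genes <- n_genes %||% nrow(dataset$matrix)
    gene_ids <- dataset$gene_ids
  } else {
    if (is.null(n_genes))
      stop("n_genes is required when a surrogate fitness_fn is supplied")
    gene_ids <- if (!is.null(dataset)) dataset$gene_ids
                else paste0("gene_", seq_len(n_genes))
  }
  master <- config$master_seed

  # generation-g fitness: shared split seed across the population unless
  # split_mode = "independent", in which case each distinct evaluation
  # draws its own stream; memoised on the bit pattern within a generation
  make_eval <- function(gen) {
    gen_seed <- derive_seed(master, 1000L, gen)
    cache <- new.env(parent = emptyenv())
    counter <- 0L
    function(bits) {
      key <- paste(which(bits == 1L), collapse = ",")
      if (!is.null(cache[[key]])) return(cache[[key]])
      counter <<- counter + 1L
      sd <- if (config$split_mode == "shared") gen_seed
            else derive_seed(gen_seed, counter)
      fit <- if (is.null(fitness_fn))
        evaluate_subset(dataset, bits, params, elm, seed = sd)
      else fitness_fn(bits)
      cache[[key]] <- fit
      fit
    }
  }

  evaluate_pop <- function(bits_list, eval_fn) {
    lapply(bits_list, function(b) list(bits = b, fit = eval_fn(b)))
  }

  better <- function(fa, fb) { # is fa strictly better than fb?
    fitness_value(fa) > fitness_value(fb)
  }

  eval0 <- make_eval(0L)
  pop <- evaluate_pop(
    init_population(n_genes, config, seed = derive_seed(master, 1L)), eval0)
  best_ever <- pop[[rank_population(pop)[1]]]

  hist_rows <- list()
  record <- function(gen) {
    vals <- vapply(pop, function(p) fitness_value(p$fit), numeric(1))
    hist_rows[[length(hist_rows) + 1L]] <<- data.frame(
      generation = gen,
      best_fitness = max(vals),
      mean_fitness = mean(vals),
      best_ever_fitness = fitness_value(best_ever$fit),
      best_ever_accuracy = fitness_accuracy(best_ever$fit),
      best_ever_n_selected = sum(best_ever$bits))
    if (verbose)
      message(sprintf("gen %3d: best %.4f mean %.4f best-ever %.4f (%d genes)",
                      gen, max(vals), mean(vals),
                      fitness_value(best_ever$fit), sum(best_ever$bits)))
  }
  record(0L)

  done <- function() {
    !is.null(config$target_accuracy) &&
      fitness_accuracy(best_ever$fit) >= config$target_accuracy
  }

  gen <- 0L
  while (gen < config$max_generations && !done()) {
    gen <- gen + 1L
    eval_g <- make_eval(gen)
    N <- config$population_size
    probs <- selection_probabilities(N, config$selection_q)
    ranked <- rank_population(pop)

    coins <- with_seed(derive_seed(master, 2L, gen), list(
      parents = sample(ranked, N, replace = TRUE, prob = probs),
      cx = stats::runif(N / 2L),
      mut = stats::runif(N)))

    new_pop <- vector("list", N)
    for (pr in seq_len(N / 2L)) {
      ia <- coins$parents[2L * pr - 1L]; ib <- coins$parents[2L * pr]
      if (coins$cx[pr] < config$crossover_prob) {
        hc <- hybrid_crossover(pop[[ia]]$bits, pop[[ib]]$bits, eval_g,
                               seed = derive_seed(master, 3L, gen, pr))
        pair <- list(list(bits = hc$chromosomes[[1]], fit = hc$fitness[[1]]),
                     list(bits = hc$chromosomes[[2]], fit = hc$fitness[[2]]))
      } else {
        pair <- list(list(bits = pop[[ia]]$bits, fit = NULL),
                     list(bits = pop[[ib]]$bits, fit = NULL))
      }
      new_pop[[2L * pr - 1L]] <- pair[[1]]
      new_pop[[2L * pr]] <- pair[[2]]
    }

    for (j in seq_len(N)) {
      if (coins$mut[j] < config$mutation_prob) {
        new_pop[[j]]$bits <- mutate(new_pop[[j]]$bits, 1 / n_genes,
                                    seed = derive_seed(master, 4L, gen, j))
        new_pop[[j]]$fit <- NULL
      }
    }

    # elitism: the best individual ever seen re-enters unchanged
    new_pop[[N]] <- list(bits = best_ever$bits, fit = NULL)

    for (j in seq_len(N))
      if (is.null(new_pop[[j]]$fit))
        new_pop[[j]]$fit <- eval_g(new_pop[[j]]$bits)
    pop <- new_pop

    cand <- pop[[rank_population(pop)[1]]]
    if (better(cand$fit, best_ever$fit)) best_ever <- cand
    record(gen)
  }

  structure(list(generation = gen, population = pop, best_ever = best_ever,
                 history = do.call(rbind, hist_rows),
                 config = config, params = params, elm = elm,
                 n_genes = n_genes, gene_ids = gene_ids),
            class = "ga_state")
}

#' Extract the best solution of a run
#'
#' @param state A `ga_state` returned by [evolve()].
#' @return List with `gene_ids` (identifiers at the set-bit positions of
#'   the best chromosome ever seen), `chromosome`, and `fitness` (its
#'   cached `fitness_result`).
#' @export
best_solution <- function(state) {
  if (!inherits(state, "ga_state") || is.null(state$best_ever$fit))
    stop("state has no evaluated best individual")
  bits <- state$best_ever$bits
  list(gene_ids = state$gene_ids[bits == 1L],
       chromosome = bits,
       fitness = state$best_ever$fit)
}

#' @export
print.ga_state <- function(x, ...) {
  cat(sprintf("<ga_state> %d generations, population %d, best fitness %.4f (%d genes)\n",
              x$generation, length(x$population),
              fitness_value(x$best_ever$fit), sum(x$best_ever$bits)))
  invisible(x)
}
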