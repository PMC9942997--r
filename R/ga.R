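#' Genetic-algorithm configuration
#'
#' The study's GA settings: population 50, crossover 0.85, per-bit
#' mutation 0.01, tournament selection of size 2 with one elite. The study
#' ran 500 generations; because the default chromosome is a 5-bit
#' hidden-layer-size gene (20 distinct architectures), the desk default is
#' 40 generations with early stopping after 15 stagnant generations, which
#' reaches the same optimum at a fraction of the cost. Set
#' `generations = 500, early_stop_generations = Inf` to run the full
#' schedule.
#'
#' @param population_size Even number of chromosomes per generation.
#' @param crossover_rate Probability of single-point crossover per pair.
#' @param mutation_rate Per-bit mutation probability.
#' @param generations Maximum generations.
#' @param n_bits Chromosome length.
#' @param tournament_size Tournament size for selection.
#' @param elitism Number of elites carried over (1).
#' @param early_stop_generations Stop after this many generations without
#'   improvement of the best fitness (`Inf` disables).
#' @param seed RNG seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50, crossover_rate = 0.85,
                      mutation_rate = 0.01, generations = 40,
                      n_bits = 5, tournament_size = 2, elitism = 1,
                      early_stop_generations = 15, seed = 1) {
  stopifnot(population_size %% 2 == 0, population_size >= 4,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            generations >= 1, n_bits >= 1)
  structure(list(population_size = as.integer(population_size),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 generations = as.integer(generations),
                 n_bits = as.integer(n_bits),
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 early_stop_generations = early_stop_generations,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Elitist binary genetic algorithm
#'
#' Minimizes `fitness` over bitstring chromosomes with tournament
#' selection, single-point crossover, per-bit mutation and one elite.
#' Fitness values are cached by `key(chromosome)` (default: the bit
#' pattern), so a deterministic fitness is evaluated at most once per
#' distinct key. A fitness call returning a non-finite value quarantines
#' that chromosome at `+Inf` with a warning.
#'
#' @param fitness Function taking a 0/1 integer vector, returning a single
#'   numeric value to minimize.
#' @param cfg A [ga_config()].
#' @param key Optional function mapping a chromosome to a cache key string
#'   (e.g. its decoded value, so that chromosomes decoding to the same
#'   architecture share one evaluation).
#' @return A `ga_result`: `best_chromosome`, `best_fitness`, a `history`
#'   data frame (one row per generation executed: best and mean fitness),
#'   `evaluations` (one row per distinct key: key, fitness), cache
#'   statistics, and the final population.
#' @export
run_ga <- function(fitness, cfg = ga_config(), key = NULL) {
  if (is.null(key)) key <- function(bits) paste(bits, collapse = "")
  cache <- new.env(parent = emptyenv())
  stats <- new.env(parent = emptyenv())
  stats$calls <- 0L
  evaluate <- function(bits) {
    k <- key(bits)
    if (!is.null(cache[[k]])) return(cache[[k]]$fitness)
    stats$calls <- stats$calls + 1L
    v <- fitness(bits)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      warning("non-finite fitness for chromosome ", k,
              "; quarantined at +Inf", call. = FALSE)
      v <- Inf
    }
    cache[[k]] <- list(fitness = v, bits = bits)
    v
  }

  with_seed(cfg$seed, {
    pop <- matrix(sample(0:1, cfg$population_size * cfg$n_bits,
                         replace = TRUE),
                  nrow = cfg$population_size)
    fit <- apply(pop, 1, evaluate)
    history <- data.frame(generation = integer(0), best = numeric(0),
                          mean = numeric(0))
    stagnant <- 0L
    best_so_far <- min(fit)
    for (gen in seq_len(cfg$generations)) {
      elite_i <- which.min(fit)
      elite <- pop[elite_i, ]
      elite_fit <- fit[elite_i]
      children <- matrix(0L, cfg$population_size, cfg$n_bits)
      for (pair in seq_len(cfg$population_size / 2)) {
        parents <- vapply(1:2, function(ignored) {
          cand <- sample.int(cfg$population_size, cfg$tournament_size,
                             replace = TRUE)
          cand[which.min(fit[cand])]
        }, integer(1))
        c1 <- pop[parents[1], ]; c2 <- pop[parents[2], ]
        if (cfg$n_bits > 1 && runif(1) < cfg$crossover_rate) {
          cut <- sample.int(cfg$n_bits - 1, 1)
          tmp <- c1[(cut + 1):cfg$n_bits]
          c1[(cut + 1):cfg$n_bits] <- c2[(cut + 1):cfg$n_bits]
          c2[(cut + 1):cfg$n_bits] <- tmp
        }
        flip1 <- runif(cfg$n_bits) < cfg$mutation_rate
        flip2 <- runif(cfg$n_bits) < cfg$mutation_rate
        c1[flip1] <- 1L - c1[flip1]
        c2[flip2] <- 1L - c2[flip2]
        children[2 * pair - 1, ] <- c1
        children[2 * pair, ] <- c2
      }
      child_fit <- apply(children, 1, evaluate)
      if (cfg$elitism > 0 && elite_fit < max(child_fit)) {
        worst <- which.max(child_fit)
        children[worst, ] <- elite
        child_fit[worst] <- elite_fit
      }
      pop <- children
      fit <- child_fit
      gen_best <- min(fit)
      history <- rbind(history,
                       data.frame(generation = gen, best = gen_best,
                                  mean = mean(fit[is.finite(fit)])))
      if (gen_best < best_so_far - 1e-15) {
        best_so_far <- gen_best
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
      }
      if (is.finite(cfg$early_stop_generations) &&
          stagnant >= cfg$early_stop_generations) break
    }
  })

  keys <- ls(cache)
  evaluations <- data.frame(
    key = keys,
    fitness = vapply(keys, function(k) cache[[k]]$fitness, numeric(1)),
    stringsAsFactors = FALSE)
  best_key <- evaluations$key[which.min(evaluations$fitness)]
  structure(list(best_chromosome = cache[[best_key]]$bits,
                 best_fitness = cache[[best_key]]$fitness,
                 history = history, evaluations = evaluations,
                 n_evaluations = stats$calls,
                 final_population = pop, cfg = cfg),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA result: best fitness %.6g after %d generations (%d distinct evaluations)\n",
              x$best_fitness, nrow(x$history), x$n_evaluations))
  invisible(x)
}

#' Serialize a GA result
#'
#' JSON rendering of the search outcome: winner, per-generation best/mean
#' fitness history (the convergence curve), the evaluation cache and its
#' statistics. `ga_history_csv()` writes just the convergence curve, for
#' plotting.
#'
#' @param result A `ga_result` from [run_ga()].
#' @param path Output CSV path (history only).
#' @return A JSON string, or (for the CSV writer) `path` invisibly.
#' @export
ga_result_json <- function(result) {
  jsonlite::toJSON(list(
    best_chromosome = result$best_chromosome,
    best_fitness = result$best_fitness,
    history = result$history,
    evaluations = result$evaluations,
    n_evaluations = result$n_evaluations
  ), auto_unbox = TRUE, digits = NA, dataframe = "columns")
}

#' @rdname ga_result_json
#' @export
ga_history_csv <- function(result, path) {
  write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}

#' Decode a 5-bit gene into a hidden-layer size
#'
#' Maps the integer value of the bits (0-31) onto 1-20 by modulo; the
#' search space of architectures is 1 to 20 hidden neurons.
#'
#' @param bits 0/1 integer vector.
#' @return Integer hidden-layer size in `[1, 20]`.
#' @export
decode_hidden_n <- function(bits) {
  1L + sum(bits * 2L^(seq_along(bits) - 1L)) %% 20L
}

#' Select a hidden-layer size by GA over a fitness on sizes
#'
#' Runs [run_ga()] with 5-bit chromosomes decoded by [decode_hidden_n()],
#' caching fitness per decoded size. The winner is taken from the full
#' evaluation cache; exact fitness ties are broken toward fewer hidden
#' neurons.
#'
#' @param fitness_h Function `hidden_n -> numeric` to minimize.
#' @param cfg A [ga_config()].
#' @return List: `hidden_n`, `fitness`, the underlying `ga_result`, and
#'   the `evaluations` table with decoded sizes.
#' @export
ga_select_hidden <- function(fitness_h, cfg = ga_config()) {
  res <- run_ga(function(bits) fitness_h(decode_hidden_n(bits)),
                cfg = cfg,
                key = function(bits) as.character(decode_hidden_n(bits)))
  ev <- res$evaluations
  ev$hidden_n <- as.integer(ev$key)
  ev <- ev[order(ev$fitness, ev$hidden_n), ]
  list(hidden_n = ev$hidden_n[1], fitness = ev$fitness[1],
       ga = res, evaluations = ev)
}

#' GA architecture search for one response
#'
#' The study's architecture optimization: the GA minimizes the
#' cross-validated pooled test RMSE of the network over hidden-layer sizes
#' 1-20. During the search each candidate size is scored with
#' `search_replicates` cross-validation replicate(s) of the plan and a
#' fixed training seed, so fitness is deterministic and cached; the winner
#' is then re-scored with the full plan and refit on all records for the
#' downstream sensitivity analysis.
#'
#' @inheritParams crossval_evaluate
#' @param ga_cfg A [ga_config()].
#' @param train_cfg A [train_config()].
#' @param search_replicates CV replicates used during the search
#'   (default 1).
#' @return List: `hidden_n` (winner), `search` (the [ga_select_hidden()]
#'   result), `report` (full-plan `fit_report` of the winner), `model`
#'   (winner refit on all records) and `lambda`.
#' @export
optimize_architecture <- function(data, response, plan,
                                  ga_cfg = ga_config(),
                                  train_cfg = train_config(),
                                  boxcox = c("pooled", "per_fold", "none"),
                                  inputs = substrate_components(),
                                  search_replicates = 1) {
  boxcox <- match.arg(boxcox)
  response <- response_column(response)
  search_plan <- restrict_plan(plan, search_replicates)
  fitness_h <- function(h) {
    rep_ <- crossval_evaluate(data, response, h, search_plan,
                              cfg = train_cfg, boxcox = boxcox,
                              inputs = inputs)
    rep_$pooled$rmse[rep_$pooled$subset == "test"]
  }
  search <- ga_select_hidden(fitness_h, cfg = ga_cfg)
  report <- crossval_evaluate(data, response, search$hidden_n, plan,
                              cfg = train_cfg, boxcox = boxcox,
                              inputs = inputs)
  lambda <- if (boxcox == "none") NULL else
    boxcox_mle(data[[response]])$lambda
  model <- train_mlp(as.matrix(as.data.frame(data)[, inputs]),
                     data[[response]], search$hidden_n, train_cfg,
                     lambda = lambda)
  list(hidden_n = search$hidden_n, search = search, report = report,
       model = model, lambda = lambda)
}
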