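# Real- and integer-coded genetic algorithm with roulette-wheel selection,
# used for hidden-layer architecture search and substrate-input optimization.

#' Genetic algorithm settings
#'
#' Defaults follow the published configuration: population 50, 500
#' generations, crossover rate 0.85, mutation rate 0.01. One elite individual
#' is carried over unchanged each generation so the best-so-far fitness trace
#' is nondecreasing.
#'
#' @param bounds Two-row matrix (or list of \code{lower}/\code{upper}
#'   vectors): per-gene lower and upper bounds.
#' @param encoding \code{"real"} for continuous genes (arithmetic crossover,
#'   Gaussian mutation with SD 10\% of the gene range) or \code{"integer"}
#'   (single-point crossover, uniform-redraw mutation).
#' @param population_size,generations,crossover_rate,mutation_rate GA
#'   parameters.
#' @param elitism_count Number of elites copied unchanged (>= 0).
#' @param seed Integer seed; a run is fully determined by (seed, config).
#' @return An object of class \code{"ga_config"}.
#' @export
ga_config <- function(bounds, encoding = c("real", "integer"),
                      population_size = 50L, generations = 500L,
                      crossover_rate = 0.85, mutation_rate = 0.01,
                      elitism_count = 1L, seed = 1L) {
  encoding <- match.arg(encoding)
  if (is.list(bounds)) bounds <- rbind(bounds$lower, bounds$upper)
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2 || any(!is.finite(bounds)) || any(bounds[1, ] >= bounds[2, ]))
    stop_domain("bounds must be finite with lower < upper for every gene")
  stopifnot(population_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1, elitism_count >= 0)
  structure(list(bounds = bounds, encoding = encoding,
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 elitism_count = as.integer(elitism_count),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Roulette-wheel parent selection
#'
#' Selection probability proportional to fitness after shifting by the
#' population minimum (plus a small epsilon so the least-fit individual keeps
#' a nonzero weight); this accommodates negative fitness values such as
#' \code{-RMSE}. Consumes the current RNG stream.
#'
#' @param fitnesses Numeric vector of fitness values (maximisation).
#' @return The selected index.
#' @export
roulette_select <- function(fitnesses) {
  if (!length(fitnesses)) stop_domain("empty population")
  if (length(fitnesses) == 1) return(1L)
  span <- max(fitnesses) - min(fitnesses)
  w <- fitnesses - min(fitnesses) + (if (span > 0) 0.01 * span else 1)
  sample.int(length(fitnesses), 1, prob = w)
}

init_population <- function(config) {
  p <- config$population_size
  g <- ncol(config$bounds)
  lo <- config$bounds[1, ]; hi <- config$bounds[2, ]
  if (config$encoding == "integer") {
    pop <- matrix(0, p, g)
    for (j in seq_len(g)) {
      vals <- seq(ceiling(lo[j]), floor(hi[j]))
      # cover every level once when the population is large enough (single gene)
      if (g == 1 && p >= length(vals))
        pop[, j] <- c(vals, sample(vals, p - length(vals), replace = TRUE))
      else
        pop[, j] <- sample(vals, p, replace = TRUE)
    }
    pop
  } else {
    matrix(stats::runif(p * g, rep(lo, each = p), rep(hi, each = p)), p, g)
  }
}

#' Crossover and mutation
#'
#' With probability \code{crossover_rate} the parents recombine (arithmetic
#' blend for real genes, single-point for integer genes), otherwise they are
#' copied. Each offspring gene then mutates with probability
#' \code{mutation_rate}: real genes by a clipped Gaussian perturbation with
#' SD 10\% of the gene range, integer genes by a uniform redraw. Offspring
#' always stay inside the bounds.
#'
#' @param parent_a,parent_b Parent chromosomes.
#' @param config A [ga_config()].
#' @return A list of two offspring chromosomes.
#' @export
ga_reproduce <- function(parent_a, parent_b, config) {
  lo <- config$bounds[1, ]; hi <- config$bounds[2, ]
  g <- length(parent_a)
  if (stats::runif(1) < config$crossover_rate) {
    if (config$encoding == "real") {
      a <- stats::runif(1)
      c1 <- a * parent_a + (1 - a) * parent_b
      c2 <- a * parent_b + (1 - a) * parent_a
    } else {
      if (g > 1) {
        cut <- sample.int(g - 1, 1)
        c1 <- c(parent_a[seq_len(cut)], parent_b[(cut + 1):g])
        c2 <- c(parent_b[seq_len(cut)], parent_a[(cut + 1):g])
      } else { c1 <- parent_a; c2 <- parent_b }
    }
  } else { c1 <- parent_a; c2 <- parent_b }
  mutate <- function(ch) {
    hit <- stats::runif(g) < config$mutation_rate
    if (any(hit)) {
      if (config$encoding == "real") {
        ch[hit] <- ch[hit] + stats::rnorm(sum(hit), 0, 0.1 * (hi[hit] - lo[hit]))
        ch <- pmin(pmax(ch, lo), hi)
      } else {
        for (j in which(hit))
          ch[j] <- sample(seq(ceiling(lo[j]), floor(hi[j])), 1)
      }
    }
    ch
  }
  list(mutate(c1), mutate(c2))
}

#' Run the genetic algorithm
#'
#' Maximises \code{fitness_fn} over the bounded box: initialise, evaluate,
#' roulette-select parents, recombine, mutate, and carry elites, for a fixed
#' number of generations. The run is deterministic given the seed in the
#' config.
#'
#' @param fitness_fn Function mapping a chromosome (numeric vector) to a
#'   finite scalar fitness (maximisation convention).
#' @param config A [ga_config()].
#' @param seed_population Optional matrix of chromosomes injected into the
#'   initial population (rows beyond \code{population_size} are dropped).
#' @return An object of class \code{"ga_result"}: \code{best} (chromosome),
#'   \code{best_fitness}, \code{trace} (per-generation best-so-far fitness),
#'   \code{n_evaluations}, \code{seed} and the config echo.
#' @export
run_ga <- function(fitness_fn, config, seed_population = NULL) {
  with_seed(config$seed, {
    pop <- init_population(config)
    if (!is.null(seed_population)) {
      seed_population <- as.matrix(seed_population)
      k <- min(nrow(seed_population), config$population_size)
      pop[seq_len(k), ] <- seed_population[seq_len(k), , drop = FALSE]
    }
    evaluate <- function(P) {
      f <- vapply(seq_len(nrow(P)), function(i) fitness_fn(P[i, ]), numeric(1))
      if (any(!is.finite(f)))
        stop_domain("fitness returned a non-finite value for chromosome [",
                    paste(signif(P[which(!is.finite(f))[1], ], 6), collapse = ", "), "]")
      f
    }
    fit <- evaluate(pop)
    n_eval <- nrow(pop)
    best_i <- which.max(fit)
    best <- pop[best_i, ]; best_fit <- fit[best_i]
    trace <- numeric(config$generations)
    for (gen in seq_len(config$generations)) {
      elite_idx <- order(fit, decreasing = TRUE)[seq_len(config$elitism_count)]
      offspring <- list()
      while (length(offspring) < config$population_size - config$elitism_count) {
        pa <- pop[roulette_select(fit), ]
        pb <- pop[roulette_select(fit), ]
        offspring <- c(offspring, ga_reproduce(pa, pb, config))
      }
      newpop <- do.call(rbind, offspring[seq_len(config$population_size - config$elitism_count)])
      if (config$elitism_count > 0)
        newpop <- rbind(pop[elite_idx, , drop = FALSE], newpop)
      pop <- newpop
      fit <- evaluate(pop)
      n_eval <- n_eval + nrow(pop)
      gi <- which.max(fit)
      if (fit[gi] > best_fit) { best_fit <- fit[gi]; best <- pop[gi, ] }
      trace[gen] <- best_fit
    }
    structure(list(best = best, best_fitness = best_fit, trace = trace,
                   n_evaluations = n_eval, seed = config$seed, config = config),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("Genetic algorithm result\n")
  cat(sprintf("  best fitness : %.6g\n", x$best_fitness))
  cat("  best solution: ", paste(signif(x$best, 6), collapse = ", "), "\n", sep = "")
  cat(sprintf("  generations  : %d  (%d fitness evaluations, seed %d)\n",
              x$config$generations, x$n_evaluations, x$seed))
  invisible(x)
}
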