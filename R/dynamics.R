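# Deterministic life cycle: selection -> meiosis -> mutation -> random union,
# equilibrium detection, and population summaries.
#
# The per-generation R functions below are the reference implementation of
# each life-cycle stage; long runs go through the compiled recursion
# (cpp_iterate), which is tested to agree with the composed R steps exactly.

#' Construct a population state
#'
#' A population state is a frequency distribution at a life-cycle stage:
#' zygotes and adults are `H x H` symmetric matrices over ordered haplotype
#' pairs (so the unordered genotype `i/j`, `i != j`, carries mass
#' `2 * freqs[i, j]`), a gamete pool is a length-`H` vector.
#'
#' @param freqs Frequency matrix (zygote/adult) or vector (gamete pool);
#'   non-negative, summing to 1 (renormalised here).
#' @param stage One of `"zygote"`, `"adult"`, `"gamete_pool"`.
#' @param generation Generation counter.
#' @return An object of class `population_state`.
#' @export
population_state <- function(freqs, stage = c("zygote", "adult", "gamete_pool"),
                             generation = 0L) {
  stage <- match.arg(stage)
  if (stage == "gamete_pool") {
    stopifnot(is.numeric(freqs), is.null(dim(freqs)))
  } else {
    stopifnot(is.matrix(freqs), nrow(freqs) == ncol(freqs))
  }
  stopifnot(all(freqs >= -1e-15))
  freqs[freqs < 0] <- 0
  s <- sum(freqs)
  stopifnot(abs(s - 1) < 1e-6)
  structure(
    list(freqs = freqs / s, stage = stage, generation = as.integer(generation)),
    class = "population_state"
  )
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> stage %s, generation %d, %s states\n",
              x$stage, x$generation,
              if (is.matrix(x$freqs)) paste0(nrow(x$freqs), "x", ncol(x$freqs))
              else length(x$freqs)))
  invisible(x)
}

#' Initial population for equilibration
#'
#' Monomorphic wild type at all selected loci and monomorphic for one modifier
#' allele; recurrent mutation then builds the mutation-selection balance,
#' whose equilibrium is the unique attractor under purifying selection.
#'
#' @param model A [modifier_model()].
#' @param modifier_allele Fixed modifier allele, 0 (default) or 1.
#' @return A zygote-stage [population_state()].
#' @export
initial_population <- function(model, modifier_allele = 0L) {
  p <- initial_pool(model, modifier_allele)
  random_union(population_state(p, "gamete_pool", generation = 0L))
}

# gamete-pool form of the initial population
initial_pool <- function(model, modifier_allele = 0L) {
  stopifnot(modifier_allele %in% c(0L, 1L))
  H <- model$H
  wild <- which(model$modbit == modifier_allele &
                  rowSums(model$selbits) == 0L)
  p <- numeric(H)
  p[wild] <- 1
  names(p) <- model$hap_table$label
  p
}

#' Selection step (zygotes to adults)
#'
#' Reweights zygote genotype frequencies by fitness and renormalises by the
#' population mean fitness.
#'
#' @param state Zygote-stage [population_state()].
#' @param model A [modifier_model()].
#' @return Adult-stage `population_state`.
#' @export
selection_step <- function(state, model) {
  stopifnot(state$stage == "zygote")
  X <- state$freqs * model$W
  wbar <- sum(X)
  if (wbar <= 0) stop("population mean fitness is zero (extinction)")
  population_state(X / wbar, "adult", state$generation)
}

#' Meiosis step (adults to gamete pool)
#'
#' The gamete pool is the adult-frequency-weighted mixture of the
#' per-genotype gamete distributions (each genotype's realized interval rates
#' reflect its carried modifier alleles and, for plastic strategies, its
#' fitness).
#'
#' @param state Adult-stage [population_state()].
#' @param model A [modifier_model()].
#' @return Gamete-pool-stage `population_state`.
#' @export
gamete_pool <- function(state, model) {
  stopifnot(state$stage == "adult")
  p <- as.numeric(crossprod(model$Tmat, as.vector(state$freqs)))
  names(p) <- model$hap_table$label
  population_state(p, "gamete_pool", state$generation)
}

#' Random union of gametes (gamete pool to zygotes)
#'
#' Zygote frequencies are the Hardy-Weinberg product of gamete frequencies;
#' in the ordered-pair representation `X = p %o% p`, so an unordered
#' heterozygous pair receives `2 p_i p_j`.
#'
#' @param state Gamete-pool-stage [population_state()].
#' @return Zygote-stage `population_state` (same generation counter; the
#'   counter advances in [advance_generation()]).
#' @export
random_union <- function(state) {
  stopifnot(state$stage == "gamete_pool")
  X <- outer(state$freqs, state$freqs)
  population_state(X, "zygote", state$generation)
}

#' Advance the population by one full generation
#'
#' Composes selection, meiosis, mutation of the gamete pool, and random
#' union, and increments the generation counter.
#'
#' @param state Zygote-stage [population_state()].
#' @param model A [modifier_model()].
#' @return Zygote-stage `population_state` of the next generation.
#' @export
advance_generation <- function(state, model) {
  adults <- selection_step(state, model)
  pool <- gamete_pool(adults, model)
  pm <- mutate_pool(pool$freqs, model$config)
  out <- random_union(population_state(pm, "gamete_pool", state$generation))
  out$generation <- state$generation + 1L
  out
}

#' Iterate the recursion to mutation-selection balance
#'
#' Runs the compiled life-cycle recursion until the largest per-selected-locus
#' change in mutant allele frequency between consecutive generations (measured
#' at the zygote census) drops below `tol`, or `max_generations` is reached.
#' Non-convergence is flagged, not raised.
#'
#' @param model A [modifier_model()].
#' @param state Optional starting [population_state()] (zygote or gamete-pool
#'   stage); defaults to [initial_population()] with modifier allele 0.
#' @param tol Convergence tolerance on allele-frequency change per generation.
#' @param max_generations Iteration cap.
#' @param track_every If > 0, record a trajectory row (generation, modifier
#'   frequency, mean fitness, per-locus mutant frequencies) every this many
#'   generations.
#' @param log_file Optional path: the trajectory is also written there as CSV.
#' @return An object of class `equilibrium`: the final gamete-pool-stage
#'   `state`, an `EquilibriumReport`-style `report` (`converged`,
#'   `generations_used`, `final_delta`), the equilibrium `allele_freqs`,
#'   `modifier_freq`, `mean_fitness`, and optionally `trajectory`.
#' @export
run_to_equilibrium <- function(model, state = NULL, tol = 1e-12,
                               max_generations = 1e6, track_every = 0,
                               log_file = NULL) {
  stopifnot(tol > 0)
  p0 <- state_to_pool(model, state)
  res <- cpp_iterate(p0, model$W, model$Tmat, model$Mmat, model$selbits,
                     model$modbit, as.integer(max_generations), tol, TRUE,
                     as.integer(track_every))
  finish_run(model, res, track_every, log_file)
}

#' Run the recursion for a fixed number of generations
#'
#' Like [run_to_equilibrium()] but without a convergence check: always runs
#' exactly `generations` generations.
#'
#' @inheritParams run_to_equilibrium
#' @param generations Number of generations to iterate.
#' @return An `equilibrium` object (with `report$converged = FALSE` since no
#'   convergence criterion was applied).
#' @export
run_generations <- function(model, generations, state = NULL, track_every = 0,
                            log_file = NULL) {
  p0 <- state_to_pool(model, state)
  res <- cpp_iterate(p0, model$W, model$Tmat, model$Mmat, model$selbits,
                     model$modbit, as.integer(generations), 0, FALSE,
                     as.integer(track_every))
  finish_run(model, res, track_every, log_file)
}

state_to_pool <- function(model, state) {
  if (is.null(state)) return(initial_pool(model, 0L))
  if (inherits(state, "equilibrium")) state <- state$state
  stopifnot(inherits(state, "population_state"))
  if (state$stage == "gamete_pool") return(state$freqs)
  # a zygote-stage state is advanced through one partial cycle
  # (selection -> meiosis -> mutation) to reach its gamete pool
  adults <- selection_step(state, model)
  mutate_pool(gamete_pool(adults, model)$freqs, model$config)
}

finish_run <- function(model, res, track_every, log_file) {
  p <- res$pool
  names(p) <- model$hap_table$label
  q <- res$allele_freqs
  names(q) <- colnames(model$selbits)
  out <- structure(
    list(
      state = population_state(p, "gamete_pool",
                               generation = res$generations),
      report = list(converged = res$converged,
                    generations_used = res$generations,
                    final_delta = res$final_delta),
      allele_freqs = q,
      modifier_freq = res$modifier_freq,
      mean_fitness = pool_mean_fitness(p, model)
    ),
    class = "equilibrium"
  )
  if (track_every > 0) {
    traj <- as.data.frame(res$trajectory)
    colnames(traj) <- c("generation", "modifier_freq", "mean_fitness",
                        paste0("q_", colnames(model$selbits)))
    out$trajectory <- traj
    if (!is.null(log_file)) {
      utils::write.csv(traj, log_file, row.names = FALSE)
    }
  }
  out
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf(
    "<equilibrium> %s after %d generations (final delta %.3g)\n",
    if (x$report$converged) "converged" else "stopped",
    x$report$generations_used, x$report$final_delta
  ))
  cat("  mutant allele freqs:",
      paste(sprintf("%s = %.6g", names(x$allele_freqs), x$allele_freqs),
            collapse = ", "), "\n")
  cat(sprintf("  modifier allele-1 freq: %.6g; mean fitness: %.12g\n",
              x$modifier_freq, x$mean_fitness))
  invisible(x)
}

# mean fitness of the zygotes a gamete pool produces
pool_mean_fitness <- function(pool, model) {
  as.numeric(t(pool) %*% model$W %*% pool)
}

#' Population mean fitness
#'
#' Fitness of all genotypes weighted by their frequencies. A gamete-pool
#' state is scored through the zygotes it produces by random union.
#'
#' @param state A [population_state()] or `equilibrium` object.
#' @param model A [modifier_model()].
#' @return Scalar mean fitness.
#' @export
mean_fitness <- function(state, model) {
  if (inherits(state, "equilibrium")) state <- state$state
  if (state$stage == "gamete_pool") return(pool_mean_fitness(state$freqs, model))
  sum(state$freqs * model$W)
}

#' Allele frequencies at the selected and modifier loci
#'
#' @param state A [population_state()] or `equilibrium` object.
#' @param model A [modifier_model()].
#' @return Named vector: mutant allele frequency per selected locus plus
#'   `modifier` (frequency of modifier allele 1).
#' @export
allele_frequencies <- function(state, model) {
  if (inherits(state, "equilibrium")) state <- state$state
  hf <- if (state$stage == "gamete_pool") state$freqs else rowSums(state$freqs)
  q <- as.numeric(crossprod(model$selbits, hf))
  names(q) <- colnames(model$selbits)
  c(q, modifier = sum(hf * model$modbit))
}

#' Population genetic variation within the selected system
#'
#' The loci-averaged standard deviation of allele frequencies,
#' `v = (1/n) * sum_i sqrt(p_i (1 - p_i))`.
#'
#' @param state A [population_state()] or `equilibrium` object.
#' @param model A [modifier_model()].
#' @return Scalar `v` in `[0, 0.5]`.
#' @export
genetic_variation <- function(state, model) {
  q <- allele_frequencies(state, model)
  q <- q[setdiff(names(q), "modifier")]
  mean(sqrt(q * (1 - q)))
}

#' Population mean realized recombination rate within the selected system
#'
#' Frequency-weighted mean over genotypes of the realized selected-interval
#' rate (the mean of `r_AB` and `r_BC` for three selected loci), reported both
#' over all genotypes and over recombination-responsive genotypes only.
#'
#' @param state A [population_state()] or `equilibrium` object (gamete-pool
#'   states are expanded to zygotes by random union).
#' @param model A [modifier_model()].
#' @return Named numeric `c(all = ..., responsive = ...)`; the responsive
#'   entry is `NA` when no responsive genotypes are present.
#' @export
mean_realized_rs <- function(state, model) {
  if (inherits(state, "equilibrium")) state <- state$state
  X <- if (state$stage == "gamete_pool") {
    outer(state$freqs, state$freqs)
  } else {
    state$freqs
  }
  x <- as.vector(X)
  sel_cols <- setdiff(colnames(model$rates), "r0")
  rs <- rowMeans(model$rates[, sel_cols, drop = FALSE])
  H <- model$H
  idx <- expand.grid(i = seq_len(H), j = seq_len(H))
  nhet <- rowSums(abs(model$selbits[idx$i, , drop = FALSE] -
                        model$selbits[idx$j, , drop = FALSE]))
  resp <- nhet >= 2
  out_all <- sum(x * rs)
  out_resp <- if (any(resp & x > 0)) sum(x[resp] * rs[resp]) / sum(x[resp])
  else NA_real_
  c(all = out_all, responsive = out_resp)
}
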