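# Modifier experiments: invasion/resistance tests between recombination
# strategies, the two-test advantage criterion, the bracketing search for the
# optimal constant recombination rate, comparisons of plastic strategies
# against the optimum, and the selection-strength probe.

# Resident equilibria are expensive (up to 1e6 generations) and shared across
# many invasion tests within a search, so they are memoised per
# (strategy, params, config) in a session-local cache.
.eq_cache <- new.env(parent = emptyenv())

strategy_key <- function(st) {
  paste(st$kind, st$r_min, st$r_max,
        paste(st$target_intervals, collapse = ""),
        if (is.null(st$r_nontarget)) "-" else st$r_nontarget,
        if (is.null(st$selfish_rMA)) "-" else
          paste(st$selfish_rMA$r0_min, st$selfish_rMA$r0_max, sep = ","),
        sep = "|")
}

model_key <- function(params, config) {
  paste(params$s, params$h, params$e_axa, params$e_axd, params$e_dxd,
        config$n_selected, config$r_MA, config$u, config$c, sep = "|")
}

#' Clear the cached resident equilibria
#'
#' Equilibria computed by [invasion_test()] and friends are memoised for the
#' session; this empties the cache (mainly useful to bound memory in very
#' long scans).
#' @return Invisibly, the number of entries dropped.
#' @export
clear_equilibrium_cache <- function() {
  n <- length(ls(.eq_cache))
  rm(list = ls(.eq_cache), envir = .eq_cache)
  invisible(n)
}

# equilibrium of a population monomorphic for `strategy`, cached
resident_equilibrium <- function(strategy, params, config, tol = 1e-12,
                                 max_generations = 1e6) {
  key <- paste(strategy_key(strategy), model_key(params, config), tol, sep = "#")
  if (!is.null(.eq_cache[[key]])) return(.eq_cache[[key]])
  model <- modifier_model(config, params, strategy, strategy)
  eq <- run_to_equilibrium(model, tol = tol, max_generations = max_generations)
  out <- list(eq = eq, model = model)
  .eq_cache[[key]] <- out
  out
}

#' Invasion test of one modifier allele against a resident
#'
#' The population is first equilibrated to mutation-selection balance while
#' monomorphic for the resident modifier allele. The invader allele is then
#' introduced at frequency 0.05 in linkage equilibrium with the resident's
#' equilibrium distribution of selected haplotypes (5% of every resident
#' haplotype's mass switches modifier allele, selected alleles unchanged),
#' and the system is run for `generations` generations with the polymorphic
#' modifier. The invader is deemed to invade when its final frequency exceeds
#' `0.05 + eps`.
#'
#' @param resident,invader `recomb_strategy` objects.
#' @param params A [fitness_params()].
#' @param config A [system_config()].
#' @param generations Generations run after introduction (default 10,000).
#' @param eps Absolute frequency gain required to call invasion. The default
#'   1e-11 sits an order of magnitude above the numerical noise of the
#'   recursion (neutral modifier pairs drift by at most ~1e-12 over 10,000
#'   generations) while staying below the weakest genuine selective responses
#'   (per-step search signals down to ~2e-11 under very strong selection, and
#'   ~5e-10 and up for favoured plastic alleles).
#' @param invader_cost Optional multiplicative fitness cost on carriers of the
#'   invader allele (see [modifier_model()]).
#' @param details If `TRUE`, return a list with the final invader frequency,
#'   its change, the modifier-frequency trajectory, and a flag for
#'   non-convergent resident equilibration instead of a bare logical.
#' @param tol,max_generations Equilibration settings for the resident.
#' @return Logical (did the invader invade?), or a detail list.
#' @export
invasion_test <- function(resident, invader, params, config,
                          generations = 10000, eps = 1e-11, invader_cost = 0,
                          details = FALSE, tol = 1e-12,
                          max_generations = 1e6) {
  res <- resident_equilibrium(resident, params, config, tol, max_generations)
  model <- modifier_model(config, params, resident, invader,
                          allele1_cost = invader_cost)
  p <- introduce_invader(res$eq$state$freqs, model, freq = 0.05)
  run <- run_generations(
    model, generations,
    state = population_state(p, "gamete_pool"),
    track_every = if (details) max(1L, generations %/% 200L) else 0L
  )
  invaded <- run$modifier_freq > 0.05 + eps
  if (!details) return(invaded)
  list(
    invaded = invaded,
    final_freq = run$modifier_freq,
    delta_freq = run$modifier_freq - 0.05,
    trajectory = run$trajectory,
    resident_converged = res$eq$report$converged,
    run = run
  )
}

# move `freq` of each resident-allele haplotype onto the invader allele,
# selected background unchanged (linkage equilibrium at introduction)
introduce_invader <- function(pool, model, freq = 0.05) {
  n <- model$config$n_selected
  H <- model$H
  p <- numeric(H)
  for (k in seq_len(H)) {
    if (pool[k] == 0) next
    flip <- if (model$modbit[k] == 0L) k + 2L^n else k - 2L^n
    p[k] <- p[k] + (1 - freq) * pool[k]
    p[flip] <- p[flip] + freq * pool[k]
  }
  names(p) <- model$hap_table$label
  p
}

#' Resistance test: does a nearly fixed strategy repel a challenger?
#'
#' Symmetric to [invasion_test()] with roles swapped: the tested strategy is
#' resident (frequency 0.95) and resists when the challenger fails to invade.
#'
#' @inheritParams invasion_test
#' @param challenger `recomb_strategy` attempting to invade the resident.
#' @return Logical (did the resident resist?).
#' @export
resistance_test <- function(resident, challenger, params, config,
                            generations = 10000, eps = 1e-11,
                            tol = 1e-12, max_generations = 1e6) {
  !invasion_test(resident = resident, invader = challenger,
                 params = params, config = config, generations = generations,
                 eps = eps, tol = tol, max_generations = max_generations)
}

#' Two-test advantage criterion between strategies
#'
#' Strategy `S1` is evolutionarily more advantageous than `S2` when its
#' modifier allele both (a) invades a population in which `S2` is nearly
#' fixed and (b) resists invasion by `S2` when nearly fixed itself. The
#' outcome also records the differences in equilibrium mean fitness, genetic
#' variation and mean realized recombination rate between the two monomorphic
#' equilibria.
#'
#' @inheritParams invasion_test
#' @param S1,S2 `recomb_strategy` objects.
#' @param trajectories If `TRUE`, keep the modifier-frequency trajectories of
#'   both tests.
#' @return An object of class `comparison_outcome` with flags `s1_invades`,
#'   `s1_resists`, `advantageous`, and `deltas` (S1 minus S2 at the
#'   monomorphic equilibria).
#' @export
is_more_advantageous <- function(S1, S2, params, config, generations = 10000,
                                 eps = 1e-11, trajectories = FALSE,
                                 tol = 1e-12, max_generations = 1e6) {
  inv <- invasion_test(S2, S1, params, config, generations, eps,
                       details = TRUE, tol = tol,
                       max_generations = max_generations)
  back <- invasion_test(S1, S2, params, config, generations, eps,
                        details = TRUE, tol = tol,
                        max_generations = max_generations)
  eq1 <- resident_equilibrium(S1, params, config, tol, max_generations)
  eq2 <- resident_equilibrium(S2, params, config, tol, max_generations)
  deltas <- c(
    mean_fitness = eq1$eq$mean_fitness - eq2$eq$mean_fitness,
    v = genetic_variation(eq1$eq, eq1$model) -
      genetic_variation(eq2$eq, eq2$model),
    mean_rs_all = unname(mean_realized_rs(eq1$eq, eq1$model)["all"] -
                           mean_realized_rs(eq2$eq, eq2$model)["all"])
  )
  structure(
    list(
      S1 = S1$label, S2 = S2$label,
      s1_invades = inv$invaded,
      s1_resists = !back$invaded,
      advantageous = inv$invaded && !back$invaded,
      invasion_delta_freq = inv$delta_freq,
      resistance_delta_freq = back$delta_freq,
      deltas = deltas,
      resident_converged = c(S2 = inv$resident_converged,
                             S1 = back$resident_converged),
      modifier_trajectories = if (trajectories) {
        list(invasion = inv$trajectory, resistance = back$trajectory)
      }
    ),
    class = "comparison_outcome"
  )
}

#' @export
print.comparison_outcome <- function(x, ...) {
  cat(sprintf("<comparison_outcome> %s vs %s: invades = %s, resists = %s -> %s\n",
              x$S1, x$S2, x$s1_invades, x$s1_resists,
              if (x$advantageous) "ADVANTAGEOUS" else "not advantageous"))
  cat(sprintf("  delta mean fitness = %.3g; delta v = %.3g; delta mean rS = %.3g\n",
              x$deltas[["mean_fitness"]], x$deltas[["v"]],
              x$deltas[["mean_rs_all"]]))
  invisible(x)
}

#' Search for the optimal constant recombination rate
#'
#' Three-iteration bracketing sweep based on invasion tests between constant
#' strategies. Iteration 1 (step 0.01): starting from `r_S = 0`, each rate is
#' challenged by the one-step-higher rate; while the higher rate invades it
#' becomes the new resident (a hill-climbing chain), and the chain's end is
#' the lower estimate. A mirrored downward chain from `r_S = 0.5` gives the
#' higher estimate. Iterations 2 and 3 repeat the two chains between the
#' current estimates with 10x smaller steps (0.001, then 0.0001), so the
#' final bracket is at most 0.0001 wide; the optimum is the bracket midpoint.
#'
#' Before sweeping, a neutrality probe (0 vs 0.25 and 0.5 vs 0.25) detects
#' landscapes where modifier alleles are neutral (purely multiplicative
#' selection): these are classified `"free/neutral"` and no search is run.
#'
#' @inheritParams invasion_test
#' @param steps Decreasing step sizes of the three iterations.
#' @param neutral_eps Frequency-change threshold below which the probe calls
#'   the landscape neutral.
#' @return An object of class `optimal_rr`: `r_low`, `r_high`, `r_star`,
#'   `classification` (`"zero"`, `"intermediate"` or `"free/neutral"`),
#'   `resolved_by` (`"sweeps"`; `"endpoint_dominance"` when per-step signals
#'   fall below `eps` and the stalled bracket is settled by pitting its
#'   endpoints against each other; `"plateau_midpoint"` when even the
#'   endpoints are selectively equivalent, in which case `r_star` is the
#'   midpoint of the flat region and `plateau` records its bounds), and
#'   `n_tests`, the number of invasion tests spent.
#' @export
optimal_constant_rr <- function(params, config, steps = c(0.01, 0.001, 1e-4),
                                generations = 10000, eps = 1e-11,
                                neutral_eps = 1e-11, tol = 1e-12,
                                max_generations = 1e6) {
  stopifnot(all(diff(steps) < 0), all(steps > 0))
  unit <- steps[length(steps)]
  k_max <- as.integer(round(0.5 / unit))
  step_k <- as.integer(round(steps / unit))
  n_tests <- 0L

  probe <- function(res_r, inv_r) {
    n_tests <<- n_tests + 1L
    invasion_test(constant_strategy(res_r), constant_strategy(inv_r),
                  params, config, generations, eps, details = TRUE,
                  tol = tol, max_generations = max_generations)
  }
  p1 <- probe(0, 0.25)
  p2 <- probe(0.5, 0.25)
  if (abs(p1$delta_freq) <= neutral_eps && abs(p2$delta_freq) <= neutral_eps) {
    return(structure(
      list(r_low = 0, r_high = 0.5, r_star = NA_real_,
           classification = "free/neutral", n_tests = n_tests),
      class = "optimal_rr"
    ))
  }

  invades <- function(res_k, inv_k) {
    n_tests <<- n_tests + 1L
    invasion_test(constant_strategy(res_k * unit),
                  constant_strategy(inv_k * unit),
                  params, config, generations, eps,
                  tol = tol, max_generations = max_generations)
  }
  sweep_up <- function(k, k_top, dk) {
    while (k + dk <= k_top && invades(k, k + dk)) k <- k + dk
    k
  }
  sweep_down <- function(k, k_bot, dk) {
    while (k - dk >= k_bot && invades(k, k - dk)) k <- k - dk
    k
  }

  # Each iteration localises the optimum to within one step of its two
  # estimates, so the next (finer) iteration sweeps a window extended by one
  # previous-step unit beyond them; otherwise estimates that coincide on the
  # coarse grid would never be refined to the final resolution.
  k_low <- 0L
  k_high <- k_max
  prev_dk <- NA_integer_
  for (dk in step_k) {
    lo_start <- if (is.na(prev_dk)) 0L else max(k_low - prev_dk, 0L)
    hi_start <- if (is.na(prev_dk)) k_max else min(k_high + prev_dk, k_max)
    k_low <- sweep_up(lo_start, hi_start, dk)
    k_high <- sweep_down(hi_start, k_low, dk)
    prev_dk <- dk
  }
  if (k_low > k_high) { # pathological landscape; keep an honest bracket
    warning("optimal-RR sweeps crossed; landscape may be multi-peaked")
    tmp <- k_low; k_low <- k_high; k_high <- tmp
  }

  # Very strong selection can leave per-step invasion signals below eps while
  # the landscape is still decided over larger rate differences: the stepped
  # sweeps then stall with a wide bracket. Disambiguate by pitting the two
  # bracket endpoints directly against each other (a large jump with a
  # correspondingly strong signal). If one endpoint dominates, the plateau
  # between them is below resolution and the dominating endpoint is reported
  # as the optimum.
  resolved_by <- "sweeps"
  plateau <- NULL
  if (k_high - k_low > step_k[length(step_k)]) {
    a <- invades(k_high, k_low) # lower endpoint invades upper's resident
    b <- invades(k_low, k_high) # and vice versa
    if (a && !b) {
      k_high <- k_low
      resolved_by <- "endpoint_dominance"
    } else if (b && !a) {
      k_low <- k_high
      resolved_by <- "endpoint_dominance"
    } else {
      # Flat plateau: every rate in the bracket is selectively equivalent at
      # measurement resolution (pairwise responses at or below the numerical
      # noise floor). The plateau is the optimum set; report its midpoint as
      # the canonical representative and keep the full range alongside.
      plateau <- c(k_low, k_high) * unit
      k_mid <- as.integer(round((k_low + k_high) / 2))
      k_low <- k_mid
      k_high <- k_mid
      resolved_by <- "plateau_midpoint"
    }
  }

  r_low <- k_low * unit
  r_high <- k_high * unit
  structure(
    list(
      r_low = r_low, r_high = r_high, r_star = (r_low + r_high) / 2,
      classification = if (k_high == 0L) "zero" else "intermediate",
      bracket_width = r_high - r_low,
      resolved_by = resolved_by,
      plateau = plateau,
      n_tests = n_tests
    ),
    class = "optimal_rr"
  )
}

#' @export
print.optimal_rr <- function(x, ...) {
  if (x$classification == "free/neutral") {
    cat("<optimal_rr> neutral landscape: all constant rates equivalent\n")
  } else {
    cat(sprintf("<optimal_rr> r* = %g (%s), bracket [%g, %g], %d invasion tests\n",
                x$r_star, x$classification, x$r_low, x$r_high, x$n_tests))
  }
  invisible(x)
}

#' Compare a fitness-dependent strategy against the optimal constant rate
#'
#' Builds the plastic strategy implied by the optimum `r*` and the requested
#' variant, then applies the two-test advantage criterion against the
#' constant-`r*` strategy:
#' \describe{
#'   \item{`"+FD"`}{rates vary above the optimum, `(r*, r* + Delta)`; with a
#'     zero optimum this is `(0, Delta)`.}
#'   \item{`"-FD"`}{rates vary below the optimum, `(r* - Delta, r*)` (clipped
#'     at 0 and flagged when `r* < Delta`).}
#'   \item{`"fringe"`}{rates straddle the optimum,
#'     `(r* - Delta/2, r* + Delta/2)`.}
#'   \item{`"distant"`}{fitness affects only the `B-C` interval (the one
#'     farther from the modifier), with twice the magnitude,
#'     `(r*, r* + 2 Delta)`; the `A-B` interval is held constant at `r*`.
#'     Three-locus systems only.}
#'   \item{`"selfish"`}{constant `r*` within the selected system but a
#'     fitness-dependent `M-A` rate spanning `Delta` around `r_MA`
#'     (abandon-ship rule; expected neutral in diploids).}
#' }
#'
#' @inheritParams invasion_test
#' @param delta Plastic magnitude `Delta = r_max - r_min` (default 0.05).
#' @param variant One of `"+FD"`, `"-FD"`, `"fringe"`, `"distant"`,
#'   `"selfish"`.
#' @param opt Optional precomputed [optimal_constant_rr()] result; computed
#'   here when `NULL`.
#' @return A `comparison_outcome` with extra fields `variant`, `delta`,
#'   `r_star`, `clipped` and `fd_strategy`.
#' @export
compare_fd_vs_optimal <- function(params, config, delta = 0.05,
                                  variant = c("+FD", "-FD", "fringe",
                                              "distant", "selfish"),
                                  opt = NULL, generations = 10000, eps = 1e-11,
                                  trajectories = FALSE, tol = 1e-12,
                                  max_generations = 1e6) {
  variant <- match.arg(variant)
  if (is.null(opt)) {
    opt <- optimal_constant_rr(params, config, generations = generations,
                               eps = eps, tol = tol,
                               max_generations = max_generations)
  }
  if (opt$classification == "free/neutral") {
    stop("no optimal constant rate on a neutral landscape; nothing to compare")
  }
  r_star <- opt$r_star
  clipped <- FALSE
  clip <- function(x) {
    y <- min(max(x, 0), 0.5)
    if (y != x) clipped <<- TRUE
    y
  }
  fd <- switch(
    variant,
    "+FD" = fd_strategy(r_star, clip(r_star + delta)),
    "-FD" = fd_strategy(clip(r_star - delta), r_star),
    "fringe" = fd_strategy(clip(r_star - delta / 2), clip(r_star + delta / 2)),
    "distant" = {
      if (config$n_selected != 3L) {
        stop("the distant-interval variant requires three selected loci")
      }
      fd_strategy(r_star, clip(r_star + 2 * delta),
                  target_intervals = "BC", r_nontarget = r_star)
    },
    "selfish" = with_selfish_rMA(
      constant_strategy(r_star),
      max(config$r_MA - delta / 2, 0), min(config$r_MA + delta / 2, 0.5)
    )
  )
  out <- is_more_advantageous(fd, constant_strategy(r_star), params, config,
                              generations, eps, trajectories = trajectories,
                              tol = tol, max_generations = max_generations)
  out$variant <- variant
  out$delta <- delta
  out$r_star <- r_star
  out$classification <- opt$classification
  out$clipped <- clipped
  out$fd_strategy <- fd
  out
}

#' Selection-strength probe: fitness cost that stops an invading modifier
#'
#' Indirect selection on a recombination modifier is extremely weak; this
#' probe quantifies it as the smallest multiplicative fitness cost on
#' carriers of the plastic allele at which its invasion fails. The cost is
#' scanned upward by decades from `cost_min` and then bisected geometrically
#' until the pass/fail bracket is within a factor of 2.
#'
#' @inheritParams invasion_test
#' @param fd_strategy The plastic `recomb_strategy` whose invasion is probed.
#' @param resident Resident `recomb_strategy` (typically the optimal constant
#'   rate).
#' @param cost_min Smallest cost probed (decade scan start).
#' @return A list: `undefined` (`TRUE` when the allele does not invade even at
#'   zero cost), `cost_low` (largest cost still invading), `cost_high`
#'   (smallest cost stopping invasion), `threshold` (geometric midpoint) and
#'   `n_tests`.
#' @export
selection_strength_probe <- function(params, config, fd_strategy, resident,
                                     generations = 10000, eps = 1e-11,
                                     cost_min = 1e-14, tol = 1e-12,
                                     max_generations = 1e6) {
  n_tests <- 0L
  invades_at <- function(cost) {
    n_tests <<- n_tests + 1L
    invasion_test(resident, fd_strategy, params, config, generations, eps,
                  invader_cost = cost, tol = tol,
                  max_generations = max_generations)
  }
  if (!invades_at(0)) {
    return(list(undefined = TRUE, cost_low = NA_real_, cost_high = NA_real_,
                threshold = NA_real_, n_tests = n_tests))
  }
  cost <- cost_min
  lo <- 0
  hi <- NA_real_
  while (cost <= 1) {
    if (invades_at(cost)) {
      lo <- cost
    } else {
      hi <- cost
      break
    }
    cost <- cost * 10
  }
  if (is.na(hi)) {
    stop("invasion not stopped even by a lethal cost; inconsistent model state")
  }
  if (lo == 0) lo <- hi / 10 # decade scan failed at its first probe
  while (hi / lo > 2) {
    mid <- sqrt(lo * hi)
    if (invades_at(mid)) lo <- mid else hi <- mid
  }
  list(undefined = FALSE, cost_low = lo, cost_high = hi,
       threshold = sqrt(lo * hi), n_tests = n_tests)
}

#' Optimal magnitude of the plastic effect
#'
#' Round-robin tournament between recombination-increasing plastic strategies
#' that differ only in magnitude `Delta`: strategy `i` dominates `j` when it
#' invades `j`'s resident population and `j` does not invade `i`'s. Returns
#' the undominated magnitude(s).
#'
#' @inheritParams invasion_test
#' @param delta_grid Magnitudes to enter in the tournament.
#' @param opt Optional precomputed [optimal_constant_rr()] result.
#' @return A list: `delta_star` (the unique undominated magnitude, or `NA`
#'   on ties), `undominated`, `all_neutral` flag, and the pairwise logical
#'   `invasion_matrix` (`[i, j]` = does `j` invade resident `i`).
#' @export
optimal_plasticity_magnitude <- function(params, config, delta_grid,
                                         opt = NULL, generations = 10000,
                                         eps = 1e-11, tol = 1e-12,
                                         max_generations = 1e6) {
  stopifnot(length(delta_grid) >= 1)
  if (length(delta_grid) == 1L) {
    return(list(delta_star = delta_grid, undominated = delta_grid,
                all_neutral = FALSE, invasion_matrix = NULL))
  }
  if (is.null(opt)) {
    opt <- optimal_constant_rr(params, config, generations = generations,
                               eps = eps, tol = tol,
                               max_generations = max_generations)
  }
  r_star <- if (opt$classification == "intermediate") opt$r_star else 0
  strat <- lapply(delta_grid, function(d) {
    fd_strategy(r_star, min(r_star + d, 0.5))
  })
  m <- length(strat)
  inv <- matrix(NA, m, m,
                dimnames = list(resident = delta_grid, invader = delta_grid))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      inv[i, j] <- invasion_test(strat[[i]], strat[[j]], params, config,
                                 generations, eps, tol = tol,
                                 max_generations = max_generations)
    }
  }
  dominated <- vapply(seq_len(m), function(i) {
    any(vapply(seq_len(m), function(j) {
      j != i && inv[i, j] && !inv[j, i]
    }, logical(1)))
  }, logical(1))
  undominated <- delta_grid[!dominated]
  all_neutral <- !any(inv, na.rm = TRUE)
  list(
    delta_star = if (!all_neutral && length(undominated) == 1L) undominated
    else NA_real_,
    undominated = undominated,
    all_neutral = all_neutral,
    invasion_matrix = inv
  )
}
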