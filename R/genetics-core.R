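# Genetic system: haplotype/genotype encodings, the epistatic fitness model,
# and recombination-strategy reaction norms.

#' System configuration for the modifier model
#'
#' Defines the genetic map `M - A - B (- C)`: the number of selected loci, the
#' linkage of the neutral modifier locus `M` to the selected system, the
#' per-locus mutation rate and the coefficient of coincidence governing
#' crossover interference between the two selected intervals.
#'
#' @param n_selected Number of selected loci, 2 or 3.
#' @param r_MA Recombination fraction between the modifier locus and the first
#'   selected locus, in `[0, 0.5]`. `0.5` is an unlinked modifier, `0.05` the
#'   conventional linked case.
#' @param u Per-locus, per-gamete mutation probability. Mutation is
#'   unidirectional (wild type to mutant); the modifier locus never mutates.
#' @param c Coefficient of coincidence for the `A-B` x `B-C` interval pair, in
#'   `[0, 2]`: 0 = complete positive interference (no double crossovers),
#'   1 = no interference, 2 = negative interference. Ignored when
#'   `n_selected = 2` (single selected interval).
#' @return An object of class `system_config`.
#' @examples
#' system_config(n_selected = 3, r_MA = 0.05, u = 1e-4, c = 1)
#' @export
system_config <- function(n_selected = 3, r_MA = 0.5, u = 1e-4, c = 1) {
  stopifnot(length(n_selected) == 1, n_selected %in% c(2L, 3L))
  stopifnot(length(r_MA) == 1, r_MA >= 0, r_MA <= 0.5)
  stopifnot(length(u) == 1, u >= 0, u < 1)
  stopifnot(length(c) == 1, c >= 0, c <= 2)
  structure(
    list(
      n_selected = as.integer(n_selected),
      modifier_linked = r_MA < 0.5,
      r_MA = as.numeric(r_MA),
      u = as.numeric(u),
      c = as.numeric(c)
    ),
    class = "system_config"
  )
}

#' @export
print.system_config <- function(x, ...) {
  cat(sprintf(
    "<system_config> %d selected loci; r_MA = %g (%s modifier); u = %g; c = %g\n",
    x$n_selected, x$r_MA, if (x$modifier_linked) "linked" else "unlinked",
    x$u, x$c
  ))
  invisible(x)
}

#' Selection parameters of the epistatic fitness model
#'
#' A genotype carrying `N_he` heterozygous and `N_ho` homozygous deleterious
#' mutations across the selected loci has fitness
#' \deqn{W = (1-hs)^{N_{he}} (1-s)^{N_{ho}} (1+e_{axa})^{P_{axa}}
#'           (1+e_{axd})^{P_{axd}} (1+e_{dxd})^{P_{dxd}}}
#' where the interaction counts `P` follow from `N_he` and `N_ho` (see
#' [epistatic_powers()]). All selected loci share the same `s` and `h`.
#'
#' @param s Deleterious effect of a mutation in the homozygous state, `[0, 1]`.
#' @param h Dominance of the mutation, `[0, 1]` (`hs` is the heterozygous
#'   effect).
#' @param e_axa,e_axd,e_dxd Additive-by-additive, additive-by-dominance and
#'   dominance-by-dominance epistasis components, each in `[-1, 1]`. Zero means
#'   purely multiplicative selection across loci.
#' @return An object of class `fitness_params`.
#' @export
fitness_params <- function(s, h, e_axa = 0, e_axd = 0, e_dxd = 0) {
  stopifnot(s >= 0, s <= 1, h >= 0, h <= 1)
  stopifnot(
    e_axa >= -1, e_axa <= 1, e_axd >= -1, e_axd <= 1,
    e_dxd >= -1, e_dxd <= 1
  )
  structure(
    list(
      s = as.numeric(s), h = as.numeric(h),
      e_axa = as.numeric(e_axa), e_axd = as.numeric(e_axd),
      e_dxd = as.numeric(e_dxd)
    ),
    class = "fitness_params"
  )
}

#' @export
print.fitness_params <- function(x, ...) {
  cat(sprintf(
    "<fitness_params> s = %g, h = %g, e_axa = %g, e_axd = %g, e_dxd = %g\n",
    x$s, x$h, x$e_axa, x$e_axd, x$e_dxd
  ))
  invisible(x)
}

# ---- haplotype / genotype encodings -----------------------------------------

# Internally a haplotype is an integer code in 0..(2^(n+1) - 1):
# bit n (most significant) is the modifier allele, bits (n-1)..0 hold the
# selected loci in map order A, B, C (1 = mutant). Codes are 0-based; R-side
# vectors over haplotypes use index code + 1.

#' Number of haplotypes in a configuration
#' @param config A [system_config()].
#' @return `2^(n_selected + 1)`.
#' @export
n_haplotypes <- function(config) {
  2L^(config$n_selected + 1L)
}

hap_code <- function(mod, sel, n) {
  # sel: 0/1 vector of length n in locus order A, B, C
  as.integer(mod) * 2L^n + sum(as.integer(sel) * 2L^((n - 1L):0L))
}

hap_mod <- function(code, n) as.integer(code %/% 2^n)

hap_sel <- function(code, n) {
  r <- code %% 2^n
  vapply(
    (n - 1L):0L,
    function(b) as.integer((r %/% 2^b) %% 2),
    integer(1)
  )
}

#' Haplotype table for a configuration
#'
#' @param config A [system_config()].
#' @return A data frame with one row per haplotype: its 0-based integer
#'   `code`, the modifier allele `mod`, one 0/1 column per selected locus
#'   (`A`, `B`, `C`) and a human-readable `label` (upper case = wild type,
#'   lower case = mutant, e.g. `"M0:AbC"`).
#' @export
haplotype_table <- function(config) {
  n <- config$n_selected
  H <- n_haplotypes(config)
  codes <- 0:(H - 1L)
  mod <- vapply(codes, hap_mod, integer(1), n = n)
  sel <- t(vapply(codes, hap_sel, integer(n), n = n))
  locus_names <- c("A", "B", "C")[seq_len(n)]
  colnames(sel) <- locus_names
  labels <- vapply(seq_along(codes), function(i) {
    chars <- ifelse(sel[i, ] == 1L, tolower(locus_names), locus_names)
    paste0("M", mod[i], ":", paste0(chars, collapse = ""))
  }, character(1))
  out <- data.frame(code = codes, mod = mod, sel, label = labels,
                    stringsAsFactors = FALSE)
  rownames(out) <- labels
  out
}

#' Parse a haplotype written as a string
#'
#' Accepts `"AbC"` style strings (upper case wild type, lower case mutant), and
#' optionally a modifier-allele prefix `"M0:"` / `"M1:"` (default modifier
#' allele 0).
#'
#' @param x Haplotype string.
#' @return A list with elements `mod` (0 or 1) and `sel` (0/1 vector over the
#'   selected loci in map order).
#' @export
parse_haplotype <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  mod <- 0L
  if (grepl("^M[01]:", x)) {
    mod <- as.integer(substr(x, 2, 2))
    x <- sub("^M[01]:", "", x)
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (!n %in% c(2L, 3L) ||
      !all(toupper(chars) == c("A", "B", "C")[seq_len(n)])) {
    stop("haplotype must list loci in map order, e.g. \"AbC\" or \"M1:ab\"")
  }
  list(mod = mod, sel = as.integer(chars %in% c("a", "b", "c")))
}

#' Construct a diploid genotype from two haplotypes
#'
#' Genotypes are unordered pairs of haplotypes; `genotype(h1, h2)` and
#' `genotype(h2, h1)` denote the same state and all downstream quantities
#' (fitness, gamete output) are symmetric in the two haplotypes.
#'
#' @param h1,h2 Haplotype strings (see [parse_haplotype()]) or lists as
#'   returned by it.
#' @return An object of class `genotype` with elements `hap1`, `hap2` and
#'   `n_selected`.
#' @examples
#' genotype("AbC", "aBC")
#' genotype("M1:AB", "M0:ab")
#' @export
genotype <- function(h1, h2) {
  if (is.character(h1)) h1 <- parse_haplotype(h1)
  if (is.character(h2)) h2 <- parse_haplotype(h2)
  stopifnot(length(h1$sel) == length(h2$sel))
  structure(
    list(hap1 = h1, hap2 = h2, n_selected = length(h1$sel)),
    class = "genotype"
  )
}

#' @export
print.genotype <- function(x, ...) {
  fmt <- function(h) {
    locus_names <- c("A", "B", "C")[seq_len(x$n_selected)]
    paste0("M", h$mod, ":",
           paste0(ifelse(h$sel == 1L, tolower(locus_names), locus_names),
                  collapse = ""))
  }
  cat("<genotype> ", fmt(x$hap1), " / ", fmt(x$hap2), "\n", sep = "")
  invisible(x)
}

#' Count heterozygous and homozygous mutations in a genotype
#'
#' The modifier locus is ignored: only selected loci contribute.
#'
#' @param g A [genotype()].
#' @return Named integer vector `c(N_he = ..., N_ho = ...)`: the number of
#'   selected loci carrying exactly one, respectively two, mutant alleles.
#' @examples
#' count_mutations(genotype("abC", "aBC")) # A homozygous, B heterozygous
#' @export
count_mutations <- function(g) {
  stopifnot(inherits(g, "genotype"))
  tot <- g$hap1$sel + g$hap2$sel
  c(N_he = sum(tot == 1L), N_ho = sum(tot == 2L))
}

#' Epistatic interaction counts from mutation counts
#'
#' The number of pairwise epistatic interactions among the mutations carried by
#' a genotype, split by type:
#' \deqn{P_{axa} = N_{he}(N_{he}-1)/2 + 2 N_{he} N_{ho} + 4 N_{ho}(N_{ho}-1)/2}
#' \deqn{P_{axd} = N_{he} N_{ho} + 4 N_{ho}(N_{ho}-1)/2}
#' \deqn{P_{dxd} = N_{ho}(N_{ho}-1)/2}
#'
#' @param N_he,N_ho Non-negative integer counts of heterozygous and homozygous
#'   mutations (vectorised).
#' @return A matrix (or named vector for scalar input) with columns `P_axa`,
#'   `P_axd`, `P_dxd`.
#' @export
epistatic_powers <- function(N_he, N_ho) {
  stopifnot(all(N_he >= 0), all(N_ho >= 0))
  P_axa <- N_he * (N_he - 1) / 2 + 2 * N_he * N_ho + 4 * N_ho * (N_ho - 1) / 2
  P_axd <- N_he * N_ho + 4 * N_ho * (N_ho - 1) / 2
  P_dxd <- N_ho * (N_ho - 1) / 2
  out <- cbind(P_axa = P_axa, P_axd = P_axd, P_dxd = P_dxd)
  if (length(N_he) == 1 && length(N_ho) == 1) out[1, ] else out
}

# Vectorised fitness from mutation counts; the workhorse behind
# genotype_fitness() and the model tensors.
fitness_from_counts <- function(N_he, N_ho, params) {
  P <- epistatic_powers(N_he, N_ho)
  if (is.null(dim(P))) {
    P <- matrix(P, nrow = 1, dimnames = list(NULL, names(P)))
  }
  (1 - params$h * params$s)^N_he * (1 - params$s)^N_ho *
    (1 + params$e_axa)^P[, "P_axa"] *
    (1 + params$e_axd)^P[, "P_axd"] *
    (1 + params$e_dxd)^P[, "P_dxd"]
}

#' Fitness of a diploid genotype
#'
#' Multiplicative-with-epistasis fitness; the modifier locus is selectively
#' neutral so fitness depends only on the selected loci, and only through the
#' counts `N_he`, `N_ho`.
#'
#' @param g A [genotype()].
#' @param params A [fitness_params()].
#' @return Scalar fitness `W >= 0`; the wild-type genotype has `W = 1`.
#' @examples
#' genotype_fitness(genotype("Abc", "ABC"), fitness_params(s = 0.2, h = 0.5))
#' @export
genotype_fitness <- function(g, params) {
  counts <- count_mutations(g)
  unname(fitness_from_counts(counts[["N_he"]], counts[["N_ho"]], params))
}

#' Is a genotype recombination-responsive?
#'
#' A diploid is recombination-responsive when it is heterozygous at two or more
#' selected loci: only then does its gamete output depend on the recombination
#' rates within the selected system. The modifier locus is not counted.
#'
#' @param g A [genotype()].
#' @return Logical flag.
#' @export
is_recombination_responsive <- function(g) {
  stopifnot(inherits(g, "genotype"))
  sum(g$hap1$sel != g$hap2$sel) >= 2L
}

#' Fitness range used to anchor the plastic reaction norm
#'
#' For three selected loci the range is taken over all *possible*
#' recombination-responsive genotypes (double and triple heterozygotes); this
#' set is enumerated, not frequency-weighted, so the reaction norm does not
#' drift with the population state. For two selected loci the only responsive
#' genotype is the double heterozygote, so the range is taken over all possible
#' genotypes instead.
#'
#' @param params A [fitness_params()].
#' @param config A [system_config()].
#' @return Named numeric `c(W_min = ..., W_max = ...)`.
#' @export
fitness_bounds <- function(params, config) {
  n <- config$n_selected
  # all per-genotype mutation-count classes: N_he + N_ho <= n
  classes <- expand.grid(N_he = 0:n, N_ho = 0:n)
  classes <- classes[classes$N_he + classes$N_ho <= n, ]
  if (n == 3L) {
    classes <- classes[classes$N_he >= 2L, ] # responsive genotypes only
  }
  W <- fitness_from_counts(classes$N_he, classes$N_ho, params)
  c(W_min = min(W), W_max = max(W))
}

#' Is the wild type the fittest genotype (the balance assumption)?
#'
#' The mutation-selection-balance framework assumes the wild-type genotype is
#' the fittest and every mutation deleterious. Strong positive epistasis can
#' violate this: multiplicative interaction factors `(1+e)^P > 1` may lift
#' multi-mutant genotypes above fitness 1, in which case mutant alleles sweep
#' instead of balancing and the recombination landscape degenerates (the
#' selected system fixes and all modifier alleles become neutral). Use this
#' check to restrict parameter grids to the model's domain of validity.
#'
#' With `from_rarity = TRUE` (default) only purely heterozygous genotype
#' classes (`N_ho = 0`) are screened: alleles maintained by recurrent mutation
#' are rare and occur almost exclusively in heterozygotes, so a balance is
#' destabilised only when some heterozygous class beats the wild type; a
#' fitter multi-homozygote class alone is unreachable from rarity and leaves
#' the balance locally stable. With `from_rarity = FALSE` the literal global
#' assumption (no genotype whatsoever fitter than the wild type) is checked.
#'
#' @param params A [fitness_params()].
#' @param config A [system_config()].
#' @param from_rarity Screen only heterozygous (rarity-reachable) classes.
#' @return `TRUE` when no screened genotype class exceeds the wild-type
#'   fitness of 1.
#' @export
wild_type_is_fittest <- function(params, config, from_rarity = TRUE) {
  n <- config$n_selected
  classes <- expand.grid(N_he = 0:n, N_ho = 0:n)
  classes <- classes[classes$N_he + classes$N_ho <= n, ]
  if (from_rarity) classes <- classes[classes$N_ho == 0L, ]
  W <- fitness_from_counts(classes$N_he, classes$N_ho, params)
  max(W) <= 1 + 1e-12
}

# ---- recombination strategies ----------------------------------------------

new_recomb_strategy <- function(kind, r_min, r_max, target_intervals,
                                r_nontarget, selfish_rMA, label) {
  stopifnot(kind %in% c("constant", "FD"))
  stopifnot(r_min >= 0, r_max <= 0.5, r_min <= r_max)
  structure(
    list(
      kind = kind,
      r_min = as.numeric(r_min),
      r_max = as.numeric(r_max),
      target_intervals = target_intervals,
      r_nontarget = r_nontarget,
      selfish_rMA = selfish_rMA,
      label = label
    ),
    class = "recomb_strategy"
  )
}

#' Constant recombination strategy
#'
#' The modifier allele confers the same recombination rate `r_S` within the
#' selected system to every genotype. Equivalent to a fitness-dependent
#' strategy with plastic magnitude zero.
#'
#' @param r Recombination rate per selected interval, `[0, 0.5]`.
#' @return A `recomb_strategy`.
#' @export
constant_strategy <- function(r) {
  new_recomb_strategy(
    kind = "constant", r_min = r, r_max = r,
    target_intervals = c("AB", "BC"), r_nontarget = NULL, selfish_rMA = NULL,
    label = sprintf("const(%g)", r)
  )
}

#' Fitness-dependent (plastic) recombination strategy
#'
#' The rate in each targeted selected interval decreases linearly with
#' genotype fitness from `r_max` (at the lowest responsive fitness `W_min`) to
#' `r_min` (at `W_max`); see [fd_rate()]. The two-interval form targets both
#' `A-B` and `B-C`; the distant-interval form targets only `B-C` and holds
#' `A-B` at the constant rate `r_nontarget`.
#'
#' @param r_min,r_max Bounds of the reaction norm, `0 <= r_min <= r_max <= 0.5`.
#'   The plastic magnitude is `Delta = r_max - r_min`.
#' @param target_intervals Character subset of `c("AB", "BC")`: which selected
#'   intervals respond to fitness.
#' @param r_nontarget Constant rate applied to a non-targeted selected
#'   interval. Required when `target_intervals` does not cover both intervals
#'   of a three-locus system.
#' @return A `recomb_strategy`.
#' @export
fd_strategy <- function(r_min, r_max, target_intervals = c("AB", "BC"),
                        r_nontarget = NULL) {
  stopifnot(all(target_intervals %in% c("AB", "BC")),
            length(target_intervals) >= 1)
  if (!is.null(r_nontarget)) {
    stopifnot(r_nontarget >= 0, r_nontarget <= 0.5)
  }
  new_recomb_strategy(
    kind = "FD", r_min = r_min, r_max = r_max,
    target_intervals = sort(target_intervals), r_nontarget = r_nontarget,
    selfish_rMA = NULL,
    label = sprintf("FD(%g,%g|%s)", r_min, r_max,
                    paste(sort(target_intervals), collapse = "+"))
  )
}

#' Attach a "selfish" fitness-dependent rule for the modifier-adjacent interval
#'
#' Makes the rate of the `M-A` interval itself fitness-dependent (interpolating
#' between `r0_min` and `r0_max` by the same rule as [fd_rate()]), while the
#' strategy's rates within the selected system are unchanged. Used to test the
#' abandon-ship mechanism, which is expected to be neutral in diploids.
#'
#' @param strategy A `recomb_strategy`.
#' @param r0_min,r0_max Bounds for the `M-A` rate, `0 <= r0_min <= r0_max <= 0.5`.
#' @return The strategy with the selfish rule attached.
#' @export
with_selfish_rMA <- function(strategy, r0_min, r0_max) {
  stopifnot(inherits(strategy, "recomb_strategy"))
  stopifnot(r0_min >= 0, r0_max <= 0.5, r0_min <= r0_max)
  strategy$selfish_rMA <- list(r0_min = as.numeric(r0_min),
                               r0_max = as.numeric(r0_max))
  strategy$label <- paste0(strategy$label,
                           sprintf("+selfish(%g,%g)", r0_min, r0_max))
  strategy
}

#' @export
print.recomb_strategy <- function(x, ...) {
  cat("<recomb_strategy> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Plastic magnitude of a strategy
#' @param strategy A `recomb_strategy`.
#' @return `r_max - r_min` (zero for constant strategies).
#' @export
plastic_magnitude <- function(strategy) strategy$r_max - strategy$r_min

#' Fitness-dependent recombination rate
#'
#' Linear reaction norm mapping genotype fitness to the recombination rate of
#' a targeted interval: `r_min` at `W = W_max`, `r_max` at `W = W_min`, and
#' linear interpolation in between. Fitness values outside `[W_min, W_max]`
#' (possible only for non-responsive genotypes in the three-locus system,
#' whose rates are immaterial) are clamped to the range. When the fitness
#' landscape over the anchoring set is flat (`W_min = W_max`), the norm is
#' undefined and the midpoint `(r_min + r_max)/2` is returned; any choice is
#' selection-neutral in that case. Constant strategies return their rate
#' unchanged.
#'
#' @param W Genotype fitness (vectorised).
#' @param strategy A `recomb_strategy`.
#' @param bounds Named numeric `c(W_min, W_max)` from [fitness_bounds()].
#' @return Rate(s) in `[r_min, r_max]`, clipped to `[0, 0.5]`.
#' @export
fd_rate <- function(W, strategy, bounds) {
  stopifnot(inherits(strategy, "recomb_strategy"))
  r_min <- strategy$r_min
  r_max <- strategy$r_max
  if (strategy$kind == "constant" || r_max == r_min) {
    return(pmin(pmax(rep(r_min, length(W)), 0), 0.5))
  }
  W_min <- bounds[["W_min"]]
  W_max <- bounds[["W_max"]]
  if (W_max == W_min) {
    r <- rep((r_min + r_max) / 2, length(W))
  } else {
    Wc <- pmin(pmax(W, W_min), W_max)
    r <- r_min + (r_max - r_min) * (W_max - Wc) / (W_max - W_min)
  }
  pmin(pmax(r, 0), 0.5)
}
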