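# Gamete production: per-genotype interval rates under codominant modifier
# expression, crossover patterns with interference, and the unidirectional
# mutation operator acting on the gamete pool.

#' Interval recombination rates of a genotype
#'
#' @param r0 Rate of the `M-A` interval.
#' @param r1 Rate of the `A-B` interval.
#' @param r2 Rate of the `B-C` interval, or `NULL` for two selected loci.
#' @return Named numeric vector of class `interval_rates`.
#' @export
interval_rates <- function(r0, r1, r2 = NULL) {
  r <- c(r0 = r0, r1 = r1)
  if (!is.null(r2)) r <- c(r, r2 = r2)
  stopifnot(all(r >= 0), all(r <= 0.5))
  structure(r, class = "interval_rates")
}

#' Realized interval rates for a genotype under its carried modifier alleles
#'
#' Each carried modifier allele evaluates its strategy's reaction norm at the
#' genotype's fitness; modifier alleles are purely codominant, so the
#' genotype's realized rate in each interval is the arithmetic mean of the two
#' alleles' realized rates (a homozygote simply expresses its allele's rate).
#' The `M-A` interval is held at `config$r_MA` unless a carried allele has a
#' selfish fitness-dependent rule for it (see [with_selfish_rMA()]).
#'
#' @param g A [genotype()]; its haplotypes' `mod` fields index into
#'   `strategies`.
#' @param strategies List of one or two `recomb_strategy` objects; element 1
#'   is the strategy of modifier allele 0, element 2 of allele 1.
#' @param params A [fitness_params()].
#' @param config A [system_config()].
#' @param bounds Optional precomputed [fitness_bounds()] (recomputed if `NULL`).
#' @param W Optional precomputed fitness of `g` (recomputed if `NULL`). The
#'   reaction norm is always evaluated at the selected-system fitness.
#' @return An [interval_rates()] vector (with `r2` present iff three selected
#'   loci).
#' @export
realized_rates <- function(g, strategies, params, config, bounds = NULL,
                           W = NULL) {
  stopifnot(inherits(g, "genotype"))
  if (inherits(strategies, "recomb_strategy")) strategies <- list(strategies)
  if (is.null(bounds)) bounds <- fitness_bounds(params, config)
  if (is.null(W)) W <- genotype_fitness(g, params)

  one_allele <- function(mod) {
    st <- strategies[[mod + 1L]]
    if (is.null(st)) stop("no strategy attached to modifier allele ", mod)
    rate_for <- function(interval) {
      if (st$kind == "FD" && !(interval %in% st$target_intervals)) {
        if (is.null(st$r_nontarget)) {
          stop("FD strategy does not target interval ", interval,
               " and has no r_nontarget rate")
        }
        return(st$r_nontarget)
      }
      fd_rate(W, st, bounds)
    }
    r0 <- if (!is.null(st$selfish_rMA)) {
      sr <- st$selfish_rMA
      tmp <- st
      tmp$kind <- "FD"
      tmp$r_min <- sr$r0_min
      tmp$r_max <- sr$r0_max
      fd_rate(W, tmp, bounds)
    } else {
      config$r_MA
    }
    c(r0, rate_for("AB"), if (config$n_selected == 3L) rate_for("BC"))
  }

  ra <- one_allele(g$hap1$mod)
  rb <- one_allele(g$hap2$mod)
  r <- pmin(pmax((ra + rb) / 2, 0), 0.5)
  if (config$n_selected == 3L) {
    interval_rates(r[1], r[2], r[3])
  } else {
    interval_rates(r[1], r[2])
  }
}

#' Joint crossover-pattern probabilities with interference
#'
#' A crossover pattern is a 0/1 indicator per interval (in map order `M-A`,
#' `A-B`, and `B-C` for three selected loci). The `M-A` interval assorts
#' independently; interference couples only the `A-B` x `B-C` pair through the
#' coefficient of coincidence `c`:
#' `P(1,1) = c r1 r2`, `P(1,0) = r1 - c r1 r2`, `P(0,1) = r2 - c r1 r2`,
#' `P(0,0) = 1 - r1 - r2 + c r1 r2`. `c = 0` forbids double crossovers; `c = 1`
#' makes the intervals independent; `c = 2` doubles the double-crossover
#' frequency.
#'
#' @param rates An [interval_rates()] vector.
#' @param c Coefficient of coincidence (ignored with two selected loci).
#' @return Named numeric vector over patterns (names like `"010"`, one bit per
#'   interval in map order), summing to 1.
#' @export
crossover_pattern_probs <- function(rates, c = 1) {
  r0 <- rates[["r0"]]
  r1 <- rates[["r1"]]
  if (length(rates) == 2L) {
    pats <- expand.grid(b1 = 0:1, b0 = 0:1)
    p <- ifelse(pats$b0 == 1, r0, 1 - r0) * ifelse(pats$b1 == 1, r1, 1 - r1)
    names(p) <- paste0(pats$b0, pats$b1)
  } else {
    r2 <- rates[["r2"]]
    dbl <- c * r1 * r2
    q <- c(`00` = 1 - r1 - r2 + dbl, `10` = r1 - dbl, `01` = r2 - dbl,
           `11` = dbl)
    if (any(q < -1e-15)) {
      stop(sprintf(
        "invalid (r, c) combination: pattern probability %.3g < 0 at r1=%g, r2=%g, c=%g",
        min(q), r1, r2, c
      ))
    }
    q <- pmax(q, 0)
    pats <- expand.grid(b12 = names(q), b0 = 0:1, stringsAsFactors = FALSE)
    p <- ifelse(pats$b0 == 1, r0, 1 - r0) * q[pats$b12]
    names(p) <- paste0(pats$b0, pats$b12)
  }
  ord <- order(names(p))
  p[ord]
}

# Lean pattern enumeration shared by gamete_distribution() and the model
# builder: bits matrix (one row per crossover pattern, one column per
# interval in map order) and the pattern probabilities.
pattern_probs_core <- function(rates, cc, n) {
  r0 <- rates[[1L]]
  r1 <- rates[[2L]]
  if (n == 2L) {
    bits <- cbind(b0 = c(0L, 0L, 1L, 1L), b1 = c(0L, 1L, 0L, 1L))
    probs <- c((1 - r0) * (1 - r1), (1 - r0) * r1, r0 * (1 - r1), r0 * r1)
  } else {
    r2 <- rates[[3L]]
    dbl <- cc * r1 * r2
    q <- c(1 - r1 - r2 + dbl, r1 - dbl, r2 - dbl, dbl) # (00, 10, 01, 11)
    if (any(q < -1e-15)) {
      stop(sprintf(
        "invalid (r, c) combination: pattern probability %.3g < 0 at r1=%g, r2=%g, c=%g",
        min(q), r1, r2, cc
      ))
    }
    q <- pmax(q, 0)
    b12 <- cbind(c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L))
    bits <- cbind(
      b0 = rep(c(0L, 1L), each = 4L),
      rbind(b12[c(1, 2, 3, 4), ], b12[c(1, 2, 3, 4), ])
    )
    probs <- c((1 - r0) * q[c(1, 2, 3, 4)], r0 * q[c(1, 2, 3, 4)])
  }
  list(bits = bits, probs = probs)
}

# strand walk over one genotype; par is a 2 x (n+1) 0/1 matrix (modifier
# first), returns an unnamed length-H probability vector
gamete_dist_core <- function(par, rates, cc, n) {
  pat <- pattern_probs_core(rates, cc, n)
  H <- 2L^(n + 1L)
  out <- numeric(H)
  pow <- 2L^(n:0L) # place values: modifier, then A, B, C
  for (k in seq_along(pat$probs)) {
    pr <- pat$probs[k]
    if (pr == 0) next
    b <- pat$bits[k, ]
    for (start in 1:2) {
      strand <- start
      code <- par[strand, 1L] * pow[1L]
      for (t in seq_len(n)) {
        if (b[t] == 1L) strand <- 3L - strand
        code <- code + par[strand, t + 1L] * pow[t + 1L]
      }
      out[code + 1L] <- out[code + 1L] + 0.5 * pr
    }
  }
  out
}

#' Gamete distribution of a diploid genotype
#'
#' Gametes are produced by a strand walk along the map `M - A - B (- C)`: the
#' walk starts on either parental haplotype with probability 1/2 and switches
#' strands at every interval whose crossover-pattern bit is 1; the resulting
#' distribution is the pattern-probability-weighted mixture over all patterns.
#' Every heterozygous locus is transmitted 1:1 marginally.
#'
#' @param g A [genotype()].
#' @param rates An [interval_rates()] vector for this genotype.
#' @param c Coefficient of coincidence.
#' @param config A [system_config()].
#' @return Named numeric vector of length [n_haplotypes()] (named by haplotype
#'   label) with the probability of each gamete haplotype; sums to 1.
#' @export
gamete_distribution <- function(g, rates, c, config) {
  stopifnot(inherits(g, "genotype"), g$n_selected == config$n_selected)
  n <- config$n_selected
  # loci sequence along the walk: modifier first, then selected loci
  par <- rbind(c(g$hap1$mod, g$hap1$sel), c(g$hap2$mod, g$hap2$sel))
  out <- gamete_dist_core(par, rates, c, n)
  names(out) <- haplotype_table(config)$label
  out
}

#' Mutation matrix over haplotypes
#'
#' Entry `[k, l]` is the probability that gamete haplotype `l` becomes
#' haplotype `k` by mutation: independently per selected locus, wild type
#' mutates to mutant with probability `u`; back mutation does not occur and
#' the modifier locus never mutates.
#'
#' @param config A [system_config()].
#' @return An `H x H` column-stochastic matrix.
#' @export
mutation_matrix <- function(config) {
  n <- config$n_selected
  u <- config$u
  H <- n_haplotypes(config)
  tab <- haplotype_table(config)
  sel <- as.matrix(tab[, c("A", "B", "C")[seq_len(n)], drop = FALSE])
  M <- matrix(0, H, H)
  for (l in seq_len(H)) {
    for (k in seq_len(H)) {
      if (tab$mod[k] != tab$mod[l]) next
      p <- 1
      for (t in seq_len(n)) {
        from <- sel[l, t]
        to <- sel[k, t]
        p <- p * if (from == 0L && to == 0L) (1 - u)
        else if (from == 0L && to == 1L) u
        else if (from == 1L && to == 1L) 1
        else 0
        if (p == 0) break
      }
      M[k, l] <- p
    }
  }
  dimnames(M) <- list(tab$label, tab$label)
  M
}

#' Apply one round of mutation to a gamete pool
#'
#' @param pool Named numeric vector of haplotype frequencies (a gamete pool).
#' @param config A [system_config()] (supplies `u`).
#' @return The mutated pool, renormalised to sum to 1.
#' @export
mutate_pool <- function(pool, config) {
  M <- mutation_matrix(config)
  out <- as.numeric(M %*% pool)
  names(out) <- rownames(M)
  out / sum(out)
}

#' Dump per-genotype gamete distributions as a table
#'
#' Debug/inspection helper: the full transmission operator as a
#' genotype-by-haplotype table, written as TSV if `file` is given.
#'
#' @param model A [modifier_model()].
#' @param file Optional path; if supplied the table is written as
#'   tab-separated text.
#' @return Invisibly, a data frame with one row per unordered genotype and one
#'   probability column per gamete haplotype.
#' @export
transmission_table <- function(model, file = NULL) {
  H <- model$H
  tab <- model$hap_table
  rows <- list()
  for (i in seq_len(H)) {
    for (j in i:H) {
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = paste(tab$label[i], tab$label[j], sep = "/"),
        t(model$Tmat[(j - 1L) * H + i, ]),
        check.names = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  colnames(out)[-1] <- tab$label
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
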