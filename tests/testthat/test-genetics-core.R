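test_that("mutation counts distinguish heterozygous and homozygous loci", {
  expect_equal(count_mutations(genotype("ABC", "ABC")), c(N_he = 0, N_ho = 0))
  expect_equal(count_mutations(genotype("aBC", "ABC")), c(N_he = 1, N_ho = 0))
  expect_equal(count_mutations(genotype("abC", "aBC")), c(N_he = 1, N_ho = 1))
  expect_equal(count_mutations(genotype("abc", "abc")), c(N_he = 0, N_ho = 3))
  # modifier allele never counts
  expect_equal(count_mutations(genotype("M1:ABC", "M0:ABC")),
               c(N_he = 0, N_ho = 0))
})

test_that("epistatic interaction counts follow the pairwise formulas", {
  expect_equal(unname(epistatic_powers(0, 0)), c(0, 0, 0))
  expect_equal(unname(epistatic_powers(2, 0)), c(1, 0, 0))
  expect_equal(unname(epistatic_powers(1, 1)), c(2, 1, 0))
  expect_equal(unname(epistatic_powers(0, 2)), c(4, 4, 1))
  # agreement with direct combinatorial counting for all counts up to 3 loci
  for (nhe in 0:3) {
    for (nho in 0:(3 - nhe)) {
      expect_equal(
        unname(epistatic_powers(nhe, nho)),
        c(choose(nhe, 2) + 2 * nhe * nho + 4 * choose(nho, 2),
          nhe * nho + 4 * choose(nho, 2),
          choose(nho, 2))
      )
    }
  }
})

test_that("genotype fitness matches the first-principles oracle", {
  expect_equal(genotype_fitness(genotype("ABC", "ABC"),
                                fitness_params(0.7, 0.3, -0.5, 0.2, 0.1)), 1)
  expect_equal(genotype_fitness(genotype("ABc", "ABC"),
                                fitness_params(0.2, 0.5)), 0.9)
  expect_equal(genotype_fitness(genotype("AbC", "aBC"),
                                fitness_params(0.2, 0.5, e_axa = -0.1)), 0.729)
  pars <- list(
    fitness_params(0.3, 0.25, -0.4, 0.15, -0.05),
    fitness_params(1, 0, 0.5, 0, 0),
    fitness_params(0.05, 1, 0, -1, 1)
  )
  for (p in pars) {
    for (pair in all_selected_pairs(3)) {
      g <- genotype(hap_string(pair$h1), hap_string(pair$h2))
      expect_equal(
        genotype_fitness(g, p),
        oracle_fitness(pair$h1, pair$h2, p$s, p$h, p$e_axa, p$e_axd, p$e_dxd)
      )
    }
  }
})

test_that("fitness is symmetric in haplotypes and depends only on counts", {
  p <- fitness_params(0.4, 0.3, -0.2, 0.1, 0.05)
  expect_equal(genotype_fitness(genotype("Abc", "aBC"), p),
               genotype_fitness(genotype("aBC", "Abc"), p))
  # permuting which loci carry the mutations leaves fitness unchanged
  expect_equal(genotype_fitness(genotype("aBC", "ABC"), p),
               genotype_fitness(genotype("ABc", "ABC"), p))
  expect_equal(genotype_fitness(genotype("abC", "ABC"), p),
               genotype_fitness(genotype("Abc", "ABC"), p))
})

test_that("fitness is multiplicative across loci when epistasis is zero", {
  p <- fitness_params(0.35, 0.6)
  for (pair in all_selected_pairs(3)) {
    per_locus <- pair$h1 + pair$h2
    w_expect <- prod(c(1, 1 - p$h * p$s, 1 - p$s)[per_locus + 1])
    g <- genotype(hap_string(pair$h1), hap_string(pair$h2))
    expect_equal(genotype_fitness(g, p), w_expect)
  }
})

test_that("recombination responsiveness requires two heterozygous selected loci", {
  expect_true(is_recombination_responsive(genotype("ABC", "abc")))
  expect_false(is_recombination_responsive(genotype("aBC", "aBC")))
  expect_true(is_recombination_responsive(genotype("AbC", "aBC")))
  expect_false(is_recombination_responsive(genotype("aBC", "ABC")))
  # modifier heterozygosity does not count
  expect_false(is_recombination_responsive(genotype("M0:aBC", "M1:ABC")))
})

test_that("fitness bounds come from the correct genotype set", {
  cfg2 <- system_config(n_selected = 2)
  cfg3 <- system_config(n_selected = 3)
  expect_equal(fitness_bounds(fitness_params(1, 0.5), cfg2),
               c(W_min = 0, W_max = 1))
  expect_equal(fitness_bounds(fitness_params(0.2, 0.5), cfg3),
               c(W_min = 0.648, W_max = 0.81))
  expect_equal(fitness_bounds(fitness_params(0, 0.5), cfg3),
               c(W_min = 1, W_max = 1))

  # brute-force enumeration oracle over all genotype classes
  for (p in list(fitness_params(0.3, 0.2, -0.3, 0.1, -0.1),
                 fitness_params(0.8, 0.9, 0.4, 0, 0))) {
    for (n in 2:3) {
      cfg <- system_config(n_selected = n)
      ws <- vapply(all_selected_pairs(n), function(pair) {
        resp <- sum(pair$h1 != pair$h2) >= 2
        if (n == 3 && !resp) return(NA_real_)
        oracle_fitness(pair$h1, pair$h2, p$s, p$h, p$e_axa, p$e_axd, p$e_dxd)
      }, numeric(1))
      expect_equal(fitness_bounds(p, cfg),
                   c(W_min = min(ws, na.rm = TRUE),
                     W_max = max(ws, na.rm = TRUE)))
    }
  }
})

test_that("wild-type-fittest check flags fitness runaway under positive epistasis", {
  cfg <- system_config(n_selected = 3)
  expect_true(wild_type_is_fittest(fitness_params(0.2, 0.5, -0.3), cfg))
  # heterozygous classes all below 1, but the triple homozygote is fitter:
  # locally stable balance, globally violated assumption
  p <- fitness_params(0.5, 0.6, 0.3)
  expect_true(wild_type_is_fittest(p, cfg))
  expect_false(wild_type_is_fittest(p, cfg, from_rarity = FALSE))
  # double het: (1 - 0.1)^2 * 1.3 > 1 -> runaway from rarity
  expect_false(wild_type_is_fittest(fitness_params(0.5, 0.2, 0.3), cfg))
})

test_that("the plastic reaction norm interpolates, clamps and falls back", {
  st <- fd_strategy(0.1, 0.3)
  b <- c(W_min = 0.5, W_max = 1)
  expect_equal(fd_rate(1, st, b), 0.1)
  expect_equal(fd_rate(0.5, st, b), 0.3)
  expect_equal(fd_rate(0.75, st, b), 0.2)
  # clamping outside the anchoring range
  expect_equal(fd_rate(1.2, st, b), 0.1)
  expect_equal(fd_rate(0.1, st, b), 0.3)
  # flat landscape falls back to the midpoint
  expect_equal(fd_rate(0.7, st, c(W_min = 1, W_max = 1)), 0.2)
  # constant strategies ignore fitness; zero-magnitude plasticity is constant
  expect_equal(fd_rate(0.6, constant_strategy(0.07), b), 0.07)
  expect_equal(fd_rate(0.6, fd_strategy(0.07, 0.07), b), 0.07)

  # monotone non-increasing in W and bounded, over random evaluations
  set.seed(11)
  for (rep in 1:20) {
    lo <- runif(1, 0, 0.25)
    hi <- runif(1, lo, 0.5)
    stx <- fd_strategy(lo, hi)
    w <- sort(runif(25, 0.2, 1.1))
    r <- fd_rate(w, stx, c(W_min = 0.3, W_max = 1))
    expect_true(all(diff(r) <= 1e-15))
    expect_true(all(r >= lo - 1e-15 & r <= hi + 1e-15))
  }
})

test_that("constructors validate their domains", {
  expect_error(system_config(n_selected = 4))
  expect_error(system_config(r_MA = 0.6))
  expect_error(system_config(c = 2.5))
  expect_error(fitness_params(1.2, 0.5))
  expect_error(fitness_params(0.5, 0.5, e_axa = -1.5))
  expect_error(fd_strategy(0.3, 0.1))
  expect_error(parse_haplotype("BAC"))
})
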