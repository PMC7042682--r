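test_that("crossover pattern probabilities follow the coincidence formula", {
  r <- interval_rates(0.5, 0.1, 0.1)
  p1 <- crossover_pattern_probs(r, c = 1)
  # selected-interval marginal (summed over the M-A bit)
  sel <- function(p, b12) unname(p[paste0("0", b12)] + p[paste0("1", b12)])
  expect_equal(sel(p1, "11"), 0.01)
  expect_equal(sel(p1, "10"), 0.09)
  expect_equal(sel(p1, "01"), 0.09)
  expect_equal(sel(p1, "00"), 0.81)
  p0 <- crossover_pattern_probs(r, c = 0)
  expect_equal(sel(p0, "11"), 0)
  p2 <- crossover_pattern_probs(r, c = 2)
  expect_equal(sel(p2, "11"), 0.02)
  expect_equal(sel(p2, "00"), 0.82)
  for (cc in c(0, 0.5, 1, 2)) {
    expect_equal(sum(crossover_pattern_probs(r, cc)), 1)
  }
  # two-locus system: two independent intervals
  p2loc <- crossover_pattern_probs(interval_rates(0.2, 0.1), c = 1)
  expect_equal(unname(p2loc[["11"]]), 0.02)
  expect_equal(sum(p2loc), 1)
})

test_that("gamete distributions match textbook expectations", {
  cfg <- system_config(n_selected = 3, r_MA = 0.5)
  # fully homozygous genotype transmits its haplotype with probability 1
  d <- gamete_distribution(genotype("M0:aBc", "M0:aBc"),
                           interval_rates(0.5, 0.2, 0.3), 1, cfg)
  expect_equal(unname(d["M0:aBc"]), 1)
  expect_equal(sum(d), 1)

  # triple selected heterozygote, r1 = r2 = 0.1, no interference
  d3 <- gamete_distribution(genotype("M0:ABC", "M0:abc"),
                            interval_rates(0.5, 0.1, 0.1), 1, cfg)
  expect_equal(unname(d3[c("M0:ABC", "M0:abc")]), c(0.405, 0.405))
  expect_equal(unname(d3[c("M0:Abc", "M0:aBC", "M0:ABc", "M0:abC")]),
               rep(0.045, 4))
  expect_equal(unname(d3[c("M0:AbC", "M0:aBc")]), rep(0.005, 2))

  # two-locus double heterozygote at rate r
  cfg2 <- system_config(n_selected = 2, r_MA = 0.5)
  d2 <- gamete_distribution(genotype("M0:AB", "M0:ab"),
                            interval_rates(0.5, 0.1), 1, cfg2)
  expect_equal(unname(d2[c("M0:AB", "M0:ab")]), rep(0.45, 2))
  expect_equal(unname(d2[c("M0:Ab", "M0:aB")]), rep(0.05, 2))
})

test_that("gamete distributions agree with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(2:3, 1)
    cfg <- system_config(n_selected = n, r_MA = 0.5)
    h1 <- c(sample(0:1, 1), sample(0:1, n, replace = TRUE))
    h2 <- c(sample(0:1, 1), sample(0:1, n, replace = TRUE))
    r <- runif(n, 0, 0.5)
    cc <- sample(c(0, runif(1, 0, 2), 1, 2), 1)
    g <- genotype(hap_string(h1[-1], mod = h1[1]),
                  hap_string(h2[-1], mod = h2[1]))
    rates <- if (n == 3) interval_rates(r[1], r[2], r[3]) else
      interval_rates(r[1], r[2])
    d <- gamete_distribution(g, rates, cc, cfg)
    expect_equal(sum(d), 1, tolerance = 1e-12)
    expect_true(all(d >= 0))
    expect_lt(max(abs(unname(d) - oracle_gamete_dist(h1, h2, r, cc))), 1e-14)
  }
})

test_that("heterozygous loci are transmitted 1:1 and marginals equal interval rates", {
  cfg <- system_config(n_selected = 3, r_MA = 0.5)
  tab <- haplotype_table(cfg)
  g <- genotype("M0:ABC", "M0:abc")
  for (cc in c(0, 1, 2)) {
    d <- gamete_distribution(g, interval_rates(0.5, 0.12, 0.3), cc, cfg)
    # marginal transmission of each selected locus is 1/2
    for (locus in c("A", "B", "C")) {
      expect_equal(sum(d[tab[[locus]] == 1]), 0.5)
    }
    # marginal A-B recombinant fraction equals r1 regardless of interference
    rec_ab <- sum(d[tab$A != tab$B])
    expect_equal(rec_ab, 0.12)
    # and B-C equals r2
    expect_equal(sum(d[tab$B != tab$C]), 0.3)
  }
})

test_that("non-responsive genotypes ignore the selected-interval rates", {
  cfg <- system_config(n_selected = 3, r_MA = 0.05)
  g <- genotype("M0:aBC", "M1:ABC") # one selected heterozygous locus
  d1 <- gamete_distribution(g, interval_rates(0.05, 0.0, 0.0), 1, cfg)
  d2 <- gamete_distribution(g, interval_rates(0.05, 0.5, 0.37), 1, cfg)
  expect_equal(d1, d2)
})

test_that("codominant modifier expression averages realized rates", {
  cfg <- system_config(n_selected = 3, r_MA = 0.05)
  p <- fitness_params(0.2, 0.5, e_axa = -0.2)
  strategies <- list(constant_strategy(0), constant_strategy(0.1))
  # homozygous modifier: that allele's rate everywhere
  r_hom <- realized_rates(genotype("M1:ABC", "M1:abc"), strategies, p, cfg)
  expect_equal(unname(r_hom[c("r1", "r2")]), c(0.1, 0.1))
  expect_equal(unname(r_hom[["r0"]]), 0.05)
  # heterozygous modifier: the mean
  r_het <- realized_rates(genotype("M0:ABC", "M1:abc"), strategies, p, cfg)
  expect_equal(unname(r_het[c("r1", "r2")]), c(0.05, 0.05))

  # constant r* vs +FD(r*, r* + delta) at the lowest-fitness genotype
  b <- fitness_bounds(p, cfg)
  strat2 <- list(constant_strategy(0.1), fd_strategy(0.1, 0.15))
  worst <- genotype("M0:abc", "M1:abc") # W below every responsive genotype
  r2 <- realized_rates(worst, strat2, p, cfg)
  expect_equal(unname(r2[["r1"]]), (0.1 + 0.15) / 2)

  # distant-interval strategy: A-B held at the non-target rate
  strat3 <- list(fd_strategy(0.1, 0.2, target_intervals = "BC",
                             r_nontarget = 0.1))
  r3 <- realized_rates(genotype("M0:ABC", "M0:abc"), strat3, p, cfg)
  expect_equal(unname(r3[["r1"]]), 0.1)
  expect_gt(r3[["r2"]], 0.1)

  # selfish rule moves r0 with fitness, leaving selected intervals alone
  strat4 <- list(with_selfish_rMA(constant_strategy(0.1), 0.05, 0.25))
  r4a <- realized_rates(genotype("M0:ABC", "M0:ABC"), strat4, p, cfg)
  r4b <- realized_rates(genotype("M0:abc", "M0:abc"), strat4, p, cfg)
  expect_equal(unname(r4a[["r0"]]), 0.05) # top fitness -> r0_min
  expect_equal(unname(r4b[["r0"]]), 0.25) # bottom fitness -> r0_max
  expect_equal(unname(r4a[["r1"]]), 0.1)
})

test_that("mutation acts per locus, one way, and conserves probability", {
  cfg <- system_config(n_selected = 3, r_MA = 0.5, u = 0.01)
  M <- mutation_matrix(cfg)
  expect_equal(unname(M["M0:abc", "M0:ABC"]), 0.01^3)
  expect_equal(unname(M["M0:ABC", "M0:ABC"]), 0.99^3)
  expect_equal(unname(M["M0:ABC", "M0:aBC"]), 0) # no back mutation
  expect_equal(unname(M["M1:aBC", "M0:aBC"]), 0) # modifier never mutates
  expect_equal(unname(colSums(M)), rep(1, ncol(M)))

  tab <- haplotype_table(cfg)
  set.seed(7)
  pool <- runif(nrow(tab))
  pool <- pool / sum(pool)
  names(pool) <- tab$label
  out <- mutate_pool(pool, cfg)
  expect_equal(sum(out), 1)
  # mutant-allele frequency never decreases at any selected locus
  for (locus in c("A", "B", "C")) {
    expect_gte(sum(out[tab[[locus]] == 1]), sum(pool[tab[[locus]] == 1]))
  }
  # u = 0 is the identity
  cfg0 <- system_config(n_selected = 3, r_MA = 0.5, u = 0)
  expect_equal(mutate_pool(pool, cfg0), pool)
})

test_that("the transmission table dumps one row per unordered genotype", {
  cfg <- system_config(n_selected = 2, r_MA = 0.5)
  m <- modifier_model(cfg, fitness_params(0.2, 0.5), constant_strategy(0.1))
  tmp <- tempfile(fileext = ".tsv")
  tab <- transmission_table(m, tmp)
  expect_equal(nrow(tab), m$H * (m$H + 1) / 2)
  back <- read.delim(tmp, check.names = FALSE)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(unname(rowSums(back[, -1])), rep(1, nrow(back)))
})
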