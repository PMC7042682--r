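make_model <- function(s = 0.2, h = 0.5, e_axa = 0, n = 3, r_MA = 0.5,
                       u = 1e-4, cc = 1, strat0 = constant_strategy(0.1),
                       strat1 = strat0) {
  modifier_model(system_config(n, r_MA, u, cc),
                 fitness_params(s, h, e_axa), strat0, strat1)
}

test_that("selection reweights genotype frequencies by fitness", {
  m <- make_model()
  # flat fitness leaves zygotes unchanged
  m_flat <- make_model(s = 0)
  z <- initial_population(m_flat)
  a <- selection_step(z, m_flat)
  expect_equal(a$freqs, z$freqs)

  # two-genotype arithmetic: p = (1/2, 1/2), W = (1, 0.5) -> (2/3, 1/3)
  H <- m$H
  X <- matrix(0, H, H)
  iw <- which(m$hap_table$label == "M0:ABC")
  im <- which(m$hap_table$label == "M0:abc")
  X[iw, iw] <- 0.5
  X[im, im] <- 0.5
  mh <- make_model(s = 0.5, h = 0) # W(abc/abc) = 0.5^3? no: use custom
  # build a params set with W(hom mutant triple) = 0.5: s chosen so (1-s)^3 = 0.5
  s3 <- 1 - 0.5^(1 / 3)
  m2 <- make_model(s = s3, h = 0.5)
  a2 <- selection_step(population_state(X, "zygote"), m2)
  expect_equal(a2$freqs[iw, iw], 2 / 3)
  expect_equal(a2$freqs[im, im], 1 / 3)

  # extinction raises
  m_lethal <- make_model(s = 1, h = 1)
  Xl <- matrix(0, H, H)
  Xl[im, im] <- 1
  expect_error(selection_step(population_state(Xl, "zygote"), m_lethal),
               "extinction")
})

test_that("the gamete pool mixes per-genotype meiosis and conserves alleles", {
  # population 100% AB/ab at r = 0.1
  cfg <- system_config(2, r_MA = 0.5, u = 1e-4, c = 1)
  m <- modifier_model(cfg, fitness_params(0.2, 0.5), constant_strategy(0.1))
  H <- m$H
  X <- matrix(0, H, H)
  i1 <- which(m$hap_table$label == "M0:AB")
  i2 <- which(m$hap_table$label == "M0:ab")
  X[i1, i2] <- 0.5
  X[i2, i1] <- 0.5
  pool <- gamete_pool(population_state(X, "adult"), m)
  expect_equal(unname(pool$freqs[c("M0:AB", "M0:ab")]), rep(0.45, 2))
  expect_equal(unname(pool$freqs[c("M0:Ab", "M0:aB")]), rep(0.05, 2))

  # allele frequencies identical in adults and pool
  set.seed(3)
  p <- runif(H); p <- p / sum(p)
  adults <- population_state(outer(p, p), "adult")
  pool2 <- gamete_pool(adults, m)
  expect_equal(allele_frequencies(pool2, m), allele_frequencies(adults, m))
})

test_that("random union is Hardy-Weinberg and conserves haplotype frequencies", {
  m <- make_model(n = 2)
  H <- m$H
  p <- numeric(H)
  p[1] <- 0.9
  p[2] <- 0.1
  z <- random_union(population_state(p, "gamete_pool"))
  expect_equal(z$freqs[1, 1], 0.81)
  expect_equal(z$freqs[1, 2] + z$freqs[2, 1], 0.18)
  expect_equal(z$freqs[2, 2], 0.01)
  expect_equal(rowSums(z$freqs), p)
})

test_that("one composed generation equals the compiled recursion exactly", {
  for (m in list(make_model(e_axa = -0.3, r_MA = 0.05,
                            strat0 = constant_strategy(0),
                            strat1 = fd_strategy(0, 0.05)),
                 make_model(n = 2, cc = 0, strat0 = constant_strategy(0.2)))) {
    H <- m$H
    set.seed(5)
    p0 <- runif(H); p0 <- p0 / sum(p0)
    state <- random_union(population_state(p0, "gamete_pool"))
    for (g in 1:25) state <- advance_generation(state, m)
    fast <- run_generations(m, 25, state = population_state(p0, "gamete_pool"))
    slow_pool <- rowSums(state$freqs)
    expect_equal(unname(fast$state$freqs), unname(slow_pool),
                 tolerance = 1e-14)
    expect_equal(state$generation, 25)
  }
})

test_that("frequencies stay normalised over many generations", {
  m <- make_model(e_axa = -0.4, r_MA = 0.05,
                  strat0 = constant_strategy(0.05),
                  strat1 = fd_strategy(0.05, 0.1))
  eq <- run_generations(m, 10000)
  expect_equal(sum(eq$state$freqs), 1, tolerance = 1e-12)
  expect_true(all(eq$state$freqs >= 0))
})

test_that("mutation-selection balance matches the classical approximations", {
  # u/(hs) with hs >> u (multiplicative three-locus system decouples per locus)
  m <- make_model(s = 0.2, h = 0.5)
  eq <- run_to_equilibrium(m)
  expect_true(eq$report$converged)
  expect_equal(unname(eq$allele_freqs), rep(1e-3, 3), tolerance = 0.05)
  # lethal dominant limit: q ~= u
  m2 <- make_model(s = 1, h = 1)
  eq2 <- run_to_equilibrium(m2)
  expect_equal(unname(eq2$allele_freqs), rep(1e-4, 3), tolerance = 0.05)
})

test_that("u = 0 from a mutation-free state is a fixed point", {
  m <- modifier_model(system_config(3, 0.5, u = 0, c = 1),
                      fitness_params(0.2, 0.5), constant_strategy(0.1))
  eq <- run_to_equilibrium(m)
  expect_true(eq$report$converged)
  expect_equal(eq$report$generations_used, 1)
  expect_equal(unname(eq$allele_freqs), rep(0, 3))
  expect_equal(eq$mean_fitness, 1)
})

test_that("population summaries evaluate as defined", {
  m <- make_model()
  H <- m$H
  iw <- which(m$hap_table$label == "M0:ABC")
  im <- which(m$hap_table$label == "M0:abc")
  s3 <- 1 - 0.5^(1 / 3) # W(abc/abc) = 0.5
  m2 <- make_model(s = s3, h = 0.5)
  X <- matrix(0, H, H)
  X[iw, iw] <- 0.5
  X[im, im] <- 0.5
  st <- population_state(X, "zygote")
  expect_equal(mean_fitness(st, m2), 0.75)
  expect_equal(mean_fitness(initial_population(m2), m2), 1)

  # loci-averaged standard deviation of allele frequencies
  q <- c(0.1, 0.2, 0.3)
  v_expect <- mean(sqrt(q * (1 - q)))
  pool <- numeric(H)
  # build a pool with independent loci at the target frequencies
  tab <- m$hap_table
  for (k in seq_len(H)) {
    if (tab$mod[k] == 1) next
    pr <- prod(ifelse(c(tab$A[k], tab$B[k], tab$C[k]) == 1, q, 1 - q))
    pool[k] <- pr
  }
  stp <- population_state(pool, "gamete_pool")
  expect_equal(genetic_variation(stp, m), v_expect)
  expect_equal(round(v_expect, 4), 0.3861)
})

test_that("mean realized recombination rate weights genotypes correctly", {
  cfg <- system_config(3, r_MA = 0.05, u = 1e-4, c = 1)
  p <- fitness_params(0.2, 0.5, e_axa = -0.2)
  # constant strategy: exactly r everywhere
  m <- modifier_model(cfg, p, constant_strategy(0.07))
  eq <- run_to_equilibrium(m)
  rs <- mean_realized_rs(eq, m)
  expect_equal(unname(rs["all"]), 0.07)
  expect_equal(unname(rs["responsive"]), 0.07)

  # plastic strategy with all mass at top fitness -> r_min
  mfd <- modifier_model(cfg, p, fd_strategy(0.1, 0.3))
  H <- mfd$H
  pool <- numeric(H)
  pool[which(mfd$hap_table$label == "M0:ABC")] <- 1
  st <- population_state(pool, "gamete_pool")
  rs2 <- mean_realized_rs(st, mfd)
  expect_equal(unname(rs2["all"]), 0.1)
  expect_true(is.na(rs2["responsive"])) # no responsive genotypes present

  # hand-weighted toy mixture
  b <- fitness_bounds(p, cfg)
  pool2 <- numeric(H)
  i1 <- which(mfd$hap_table$label == "M0:ABC")
  i2 <- which(mfd$hap_table$label == "M0:abc")
  pool2[i1] <- 0.6
  pool2[i2] <- 0.4
  st2 <- population_state(pool2, "gamete_pool")
  Whet <- genotype_fitness(genotype("ABC", "abc"), p)
  r_het <- fd_rate(Whet, fd_strategy(0.1, 0.3), b)
  r_top <- 0.1   # W = 1 clamps to W_max
  r_bot <- 0.3   # triple homozygote clamps to W_min
  expected_all <- 0.36 * r_top + 2 * 0.24 * r_het + 0.16 * r_bot
  rs3 <- mean_realized_rs(st2, mfd)
  expect_equal(unname(rs3["all"]), expected_all)
  expect_equal(unname(rs3["responsive"]), r_het)
})

test_that("trajectory logging records the requested cadence", {
  m <- make_model(e_axa = -0.3, r_MA = 0.05)
  tmp <- tempfile(fileext = ".csv")
  run <- run_generations(m, 100, track_every = 10, log_file = tmp)
  expect_true(file.exists(tmp))
  traj <- read.csv(tmp)
  expect_equal(nrow(traj), 10)
  expect_equal(traj$generation, seq(10, 100, by = 10))
  expect_true(all(c("modifier_freq", "mean_fitness", "q_A") %in% names(traj)))
})
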