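# Independent brute-force oracles and small fixture builders, written
# deliberately without reusing the package's internal code paths.

# Enumerate all (start strand) x (crossover pattern) outcomes directly from
# allele sequences. Haplotypes are given as 0/1 vectors ordered
# (modifier, A, B[, C]); intervals carry rates r (length = loci - 1) with the
# coefficient of coincidence cc coupling the last two intervals when there
# are three selected loci.
oracle_gamete_dist <- function(hap1, hap2, r, cc) {
  n_loci <- length(hap1)
  n_int <- n_loci - 1L
  out <- numeric(2^n_loci)
  patterns <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  for (row in seq_len(nrow(patterns))) {
    b <- patterns[row, ]
    if (n_int == 3L) {
      # joint probability of the selected-interval pair, M-A independent
      joint <- matrix(c(1 - r[2] - r[3] + cc * r[2] * r[3],  # joint[1,1]: 00
                        r[2] - cc * r[2] * r[3],             # joint[2,1]: 10
                        r[3] - cc * r[2] * r[3],             # joint[1,2]: 01
                        cc * r[2] * r[3]), 2, 2)             # joint[2,2]: 11
      pb <- (if (b[1]) r[1] else 1 - r[1]) * joint[b[2] + 1, b[3] + 1]
    } else {
      pb <- prod(ifelse(b == 1, r, 1 - r))
    }
    if (pb == 0) next
    for (start in 1:2) {
      strands <- rbind(hap1, hap2)
      cur <- start
      gam <- integer(n_loci)
      gam[1] <- strands[cur, 1]
      for (t in seq_len(n_int)) {
        if (b[t] == 1) cur <- 3 - cur
        gam[t + 1] <- strands[cur, t + 1]
      }
      idx <- sum(gam * 2^((n_loci - 1):0)) + 1
      out[idx] <- out[idx] + pb / 2
    }
  }
  out
}

# fitness recomputed from first principles for a pair of 0/1 selected-allele
# vectors (no shared code with the package's count-based formula)
oracle_fitness <- function(sel1, sel2, s, h, eaa = 0, ead = 0, edd = 0) {
  per_locus <- sel1 + sel2
  w <- 1
  for (g in per_locus) {
    w <- w * switch(g + 1L, 1, 1 - h * s, 1 - s)
  }
  nhe <- sum(per_locus == 1)
  nho <- sum(per_locus == 2)
  paa <- choose(nhe, 2) + 2 * nhe * nho + 4 * choose(nho, 2)
  pad <- nhe * nho + 4 * choose(nho, 2)
  pdd <- choose(nho, 2)
  w * (1 + eaa)^paa * (1 + ead)^pad * (1 + edd)^pdd
}

# every diploid selected-genotype as a pair of 0/1 vectors
all_selected_pairs <- function(n) {
  haps <- as.matrix(expand.grid(rep(list(0:1), n)))
  pairs <- list()
  for (i in seq_len(nrow(haps))) {
    for (j in i:nrow(haps)) {
      pairs[[length(pairs) + 1L]] <- list(h1 = haps[i, ], h2 = haps[j, ])
    }
  }
  pairs
}

hap_string <- function(bits, mod = NULL) {
  letters_uc <- c("A", "B", "C")[seq_along(bits)]
  s <- paste0(ifelse(bits == 1, tolower(letters_uc), letters_uc),
              collapse = "")
  if (is.null(mod)) s else paste0("M", mod, ":", s)
}
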