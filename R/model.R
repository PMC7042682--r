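# Assembly of a complete modifier model: all per-genotype quantities
# (fitness, realized rates, gamete distributions) precomputed once, since the
# deterministic recursion reuses them every generation.

#' Build a modifier model
#'
#' Precomputes everything the life-cycle recursion needs for a given
#' configuration, selection parameters and pair of modifier-allele strategies:
#' the diploid fitness matrix, the realized interval rates per genotype (with
#' codominant modifier expression), the meiotic transmission operator and the
#' mutation matrix.
#'
#' @param config A [system_config()].
#' @param params A [fitness_params()].
#' @param strategy0 `recomb_strategy` of modifier allele 0 (the resident in
#'   invasion experiments).
#' @param strategy1 `recomb_strategy` of modifier allele 1; defaults to
#'   `strategy0` (monomorphic modifier).
#' @param allele1_cost Optional multiplicative fitness penalty on carriers of
#'   modifier allele 1: homozygotes are multiplied by `1 - allele1_cost`,
#'   heterozygotes by `1 - allele1_cost/2` (codominant cost). Used by the
#'   selection-strength probe; default 0.
#' @return An object of class `modifier_model` containing the haplotype table
#'   and the precomputed operators.
#' @export
modifier_model <- function(config, params, strategy0, strategy1 = strategy0,
                           allele1_cost = 0) {
  stopifnot(inherits(config, "system_config"),
            inherits(params, "fitness_params"),
            inherits(strategy0, "recomb_strategy"),
            inherits(strategy1, "recomb_strategy"),
            allele1_cost >= 0, allele1_cost <= 1)
  n <- config$n_selected
  H <- n_haplotypes(config)
  tab <- haplotype_table(config)
  selbits <- as.matrix(tab[, c("A", "B", "C")[seq_len(n)], drop = FALSE])
  storage.mode(selbits) <- "integer"
  modbit <- tab$mod
  bounds <- fitness_bounds(params, config)
  strategies <- list(strategy0, strategy1)

  # diploid fitness over ordered haplotype pairs: Wsel is the selected-system
  # fitness (what the plastic reaction norm sees); W additionally carries the
  # optional allele-1 experiment cost and drives selection
  Wsel <- matrix(0, H, H)
  for (i in seq_len(H)) {
    for (j in seq_len(H)) {
      tot <- selbits[i, ] + selbits[j, ]
      Wsel[i, j] <- fitness_from_counts(sum(tot == 1L), sum(tot == 2L), params)
    }
  }
  W <- Wsel
  if (allele1_cost > 0) {
    n1 <- outer(modbit, modbit, "+")
    W <- W * (1 - allele1_cost * n1 / 2)
  }
  dimnames(W) <- list(tab$label, tab$label)

  # transmission operator: row (i + (j-1)*H) is the gamete distribution of
  # ordered genotype (i, j); symmetric in i, j
  Tmat <- matrix(0, H * H, H)
  rates_tab <- matrix(NA_real_, H * H, if (n == 3L) 3L else 2L)
  for (i in seq_len(H)) {
    for (j in i:H) {
      g <- structure(
        list(hap1 = list(mod = modbit[i], sel = selbits[i, ]),
             hap2 = list(mod = modbit[j], sel = selbits[j, ]),
             n_selected = n),
        class = "genotype"
      )
      r <- realized_rates(g, strategies, params, config, bounds = bounds,
                          W = Wsel[i, j])
      dist <- gamete_dist_core(
        rbind(c(modbit[i], selbits[i, ]), c(modbit[j], selbits[j, ])),
        r, config$c, n
      )
      Tmat[(j - 1L) * H + i, ] <- dist
      Tmat[(i - 1L) * H + j, ] <- dist
      rates_tab[(j - 1L) * H + i, ] <- r
      rates_tab[(i - 1L) * H + j, ] <- r
    }
  }
  colnames(Tmat) <- tab$label
  colnames(rates_tab) <- c("r0", "r1", "r2")[seq_len(ncol(rates_tab))]

  structure(
    list(
      config = config, params = params, strategies = strategies,
      allele1_cost = allele1_cost,
      H = H, hap_table = tab, selbits = selbits, modbit = modbit,
      bounds = bounds, W = W, Tmat = Tmat, rates = rates_tab,
      Mmat = mutation_matrix(config)
    ),
    class = "modifier_model"
  )
}

#' @export
print.modifier_model <- function(x, ...) {
  cat(sprintf(
    "<modifier_model> %d selected loci (%d haplotypes); allele 0: %s; allele 1: %s\n",
    x$config$n_selected, x$H, x$strategies[[1]]$label, x$strategies[[2]]$label
  ))
  cat(sprintf("  s = %g, h = %g, e = (%g, %g, %g); r_MA = %g, u = %g, c = %g\n",
              x$params$s, x$params$h, x$params$e_axa, x$params$e_axd,
              x$params$e_dxd, x$config$r_MA, x$config$u, x$config$c))
  if (x$allele1_cost > 0) {
    cat(sprintf("  allele-1 fitness cost: %g\n", x$allele1_cost))
  }
  invisible(x)
}
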