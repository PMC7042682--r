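# Parameter-grid scans: for every cell, locate the optimal constant
# recombination rate and test the requested plastic variants against it;
# aggregate favoured proportions overall and per parameter cell.

#' Define a parameter grid for a scan
#'
#' Defaults mirror the reference experimental design: `s` from almost neutral
#' (0.01) to lethal (1) in steps of 0.1, `h` from 0 to 1 in steps of 0.2,
#' additive-by-additive epistasis from -1 to 1 in steps of 0.1, the
#' additive-by-dominance component on the coarse grid
#' `{-1, -0.5, 0, 0.5, 1}` with dominance-by-dominance fixed at 0 (their
#' effects are one and two orders of magnitude weaker), no interference
#' (`c = 1`) and both modifier linkages. `reduce` coarsens every numeric axis
#' by keeping every `reduce`-th value (always retaining the first), for
#' desk-scale runs; the headline proportions are full-grid quantities.
#'
#' @param s_values,h_values,e_axa_values,e_axd_values,e_dxd_values Selection
#'   parameter axes.
#' @param c_values Coefficients of coincidence.
#' @param r_MA_values Modifier linkages (0.5 unlinked, 0.05 linked).
#' @param delta Plastic magnitude(s) `Delta`.
#' @param variants Plastic variants to test per cell (see
#'   [compare_fd_vs_optimal()]); variants relevant only to intermediate
#'   optima (`"-FD"`, `"fringe"`) are skipped in zero-optimum cells.
#' @param reduce Integer coarsening factor applied to every numeric axis.
#' @return An object of class `scan_grid` (a data frame of cells plus
#'   attributes).
#' @export
scan_grid <- function(s_values = c(0.01, seq(0.1, 1, by = 0.1)),
                      h_values = seq(0, 1, by = 0.2),
                      e_axa_values = seq(-1, 1, by = 0.1),
                      e_axd_values = c(-1, -0.5, 0, 0.5, 1),
                      e_dxd_values = 0,
                      c_values = 1,
                      r_MA_values = c(0.5, 0.05),
                      delta = 0.05,
                      variants = c("+FD", "-FD", "fringe"),
                      reduce = 1L) {
  thin <- function(x) {
    if (reduce <= 1L || length(x) <= 2L) return(x)
    x[unique(c(seq(1, length(x), by = reduce), length(x)))]
  }
  cells <- expand.grid(
    s = thin(s_values), h = thin(h_values), e_axa = thin(e_axa_values),
    e_axd = thin(e_axd_values), e_dxd = thin(e_dxd_values),
    c = c_values, r_MA = r_MA_values, delta = delta,
    KEEP.OUT.ATTRS = FALSE
  )
  structure(cells, variants = variants, class = c("scan_grid", "data.frame"))
}

#' Run a parameter-grid scan
#'
#' For every grid cell: find the optimal constant recombination rate, then
#' compare each requested plastic variant against it with the two-test
#' criterion. Fully deterministic. Optimal-RR searches are cached by
#' parameter key (and shared across variants and across calls that pass the
#' same `cache`), so an interrupted scan can be rerun cheaply. Per-cell
#' failures are recorded in the `error` column and the scan continues.
#'
#' @param grid A [scan_grid()].
#' @param n_selected Number of selected loci (2 or 3).
#' @param u Per-locus mutation rate.
#' @param generations,eps,tol,max_generations Passed to the underlying tests.
#' @param cache Environment used to memoise per-cell optima; pass your own to
#'   make a scan restartable across calls.
#' @param verbose Print per-cell progress to stderr.
#' @return A data frame with one row per cell x variant: the cell parameters,
#'   `r_star`, `classification`, the `invades`/`resists`/`advantageous`
#'   flags, equilibrium deltas and the error field.
#' @export
run_scan <- function(grid, n_selected = 3, u = 1e-4, generations = 10000,
                     eps = 1e-11, tol = 1e-12, max_generations = 1e6,
                     cache = new.env(parent = emptyenv()), verbose = FALSE) {
  variants <- attr(grid, "variants")
  rows <- list()
  for (cell in seq_len(nrow(grid))) {
    g <- grid[cell, ]
    params <- fitness_params(g$s, g$h, g$e_axa, g$e_axd, g$e_dxd)
    config <- system_config(n_selected = n_selected, r_MA = g$r_MA, u = u,
                            c = g$c)
    key <- paste("opt", model_key(params, config), sep = "#")
    base <- data.frame(
      s = g$s, h = g$h, e_axa = g$e_axa, e_axd = g$e_axd, e_dxd = g$e_dxd,
      c = g$c, r_MA = g$r_MA, delta = g$delta
    )
    opt <- cache[[key]]
    if (is.null(opt)) {
      opt <- tryCatch(
        optimal_constant_rr(params, config, generations = generations,
                            eps = eps, tol = tol,
                            max_generations = max_generations),
        error = function(e) e
      )
      cache[[key]] <- opt
    }
    if (inherits(opt, "error")) {
      rows[[length(rows) + 1L]] <- cbind(
        base, variant = NA_character_, r_star = NA_real_,
        classification = NA_character_, invades = NA, resists = NA,
        advantageous = NA, clipped = NA, d_mean_fitness = NA_real_,
        d_v = NA_real_, d_mean_rs = NA_real_,
        error = conditionMessage(opt)
      )
      next
    }
    if (verbose) {
      message(sprintf("[%d/%d] s=%g h=%g e_axa=%g e_axd=%g c=%g r_MA=%g: %s",
                      cell, nrow(grid), g$s, g$h, g$e_axa, g$e_axd, g$c,
                      g$r_MA, opt$classification))
    }
    if (opt$classification == "free/neutral") {
      rows[[length(rows) + 1L]] <- cbind(
        base, variant = NA_character_, r_star = NA_real_,
        classification = "free/neutral", invades = FALSE, resists = TRUE,
        advantageous = FALSE, clipped = FALSE, d_mean_fitness = 0,
        d_v = 0, d_mean_rs = 0, error = NA_character_
      )
      next
    }
    use_variants <- variants
    if (opt$classification == "zero") {
      use_variants <- setdiff(variants, c("-FD", "fringe"))
    }
    for (v in use_variants) {
      out <- tryCatch(
        compare_fd_vs_optimal(params, config, delta = g$delta, variant = v,
                              opt = opt, generations = generations, eps = eps,
                              tol = tol, max_generations = max_generations),
        error = function(e) e
      )
      rows[[length(rows) + 1L]] <- if (inherits(out, "error")) {
        cbind(base, variant = v, r_star = opt$r_star,
              classification = opt$classification, invades = NA, resists = NA,
              advantageous = NA, clipped = NA, d_mean_fitness = NA_real_,
              d_v = NA_real_, d_mean_rs = NA_real_,
              error = conditionMessage(out))
      } else {
        cbind(base, variant = v, r_star = out$r_star,
              classification = out$classification,
              invades = out$s1_invades, resists = out$s1_resists,
              advantageous = out$advantageous, clipped = out$clipped,
              d_mean_fitness = out$deltas[["mean_fitness"]],
              d_v = out$deltas[["v"]],
              d_mean_rs = out$deltas[["mean_rs_all"]],
              error = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise scan results into favoured proportions
#'
#' Aggregates the proportion of cells where each plastic variant was
#' evolutionarily favoured, conditioned on the optimum class of the cell
#' (zero vs intermediate optimal constant rate) and split by modifier
#' linkage, plus a per-`(s, |e_axa|, h)` table suitable for heat maps.
#'
#' @param results Data frame from [run_scan()].
#' @return An object of class `scan_summary`: `overall` (one row per
#'   conditioning set x linkage x variant with `n_cases`, `n_favored`,
#'   `proportion`), `cells` (the heat-map table) and `n_errors`.
#' @export
summarize_scan <- function(results) {
  ok <- results[is.na(results$error) & !is.na(results$variant), , drop = FALSE]
  agg_by <- function(df, by_cols) {
    if (nrow(df) == 0) {
      return(data.frame())
    }
    key <- interaction(df[by_cols], drop = TRUE)
    parts <- split(df, key)
    out <- do.call(rbind, lapply(parts, function(p) {
      cbind(p[1, by_cols, drop = FALSE],
            n_cases = nrow(p),
            n_favored = sum(p$advantageous),
            proportion = mean(p$advantageous))
    }))
    rownames(out) <- NULL
    out
  }
  overall <- agg_by(ok, c("classification", "r_MA", "variant"))
  cells <- within(ok, abs_e_axa <- abs(e_axa))
  cells <- agg_by(cells,
                  c("classification", "r_MA", "variant", "s", "abs_e_axa", "h"))
  structure(
    list(
      overall = overall,
      cells = cells,
      n_results = nrow(results),
      n_errors = sum(!is.na(results$error))
    ),
    class = "scan_summary"
  )
}

#' @export
print.scan_summary <- function(x, ...) {
  cat(sprintf("<scan_summary> %d result rows (%d errors)\n",
              x$n_results, x$n_errors))
  if (nrow(x$overall) > 0) print(x$overall)
  invisible(x)
}

#' Export the per-cell summary as a heat-map-ready table
#'
#' Long-format CSV with one row per populated `(s, |e_axa|, h)` cell per
#' conditioning set, linkage and variant; round-trips through
#' [utils::read.csv()].
#'
#' @param summary A [summarize_scan()] result.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
export_heatmap_table <- function(summary, file) {
  stopifnot(inherits(summary, "scan_summary"))
  cols <- c("classification", "r_MA", "variant", "s", "abs_e_axa", "h",
            "n_cases", "n_favored", "proportion")
  tab <- summary$cells[, cols, drop = FALSE]
  tab <- tab[do.call(order, tab[, c("classification", "r_MA", "variant", "s",
                                    "abs_e_axa", "h")]), , drop = FALSE]
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}
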