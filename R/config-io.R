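# Flat key-value serialisation of model configurations (YAML or JSON),
# keyed by the conventional parameter symbols.

strategy_to_list <- function(st) {
  out <- list(kind = st$kind, r_min = st$r_min, r_max = st$r_max,
              target_intervals = st$target_intervals)
  if (st$kind == "constant") out$r_const <- st$r_min
  if (!is.null(st$r_nontarget)) out$r_nontarget <- st$r_nontarget
  if (!is.null(st$selfish_rMA)) out$selfish_rMA <- st$selfish_rMA
  out
}

strategy_from_list <- function(x) {
  st <- if (identical(x$kind, "constant")) {
    constant_strategy(if (!is.null(x$r_const)) x$r_const else x$r_min)
  } else {
    fd_strategy(x$r_min, x$r_max,
                target_intervals = unlist(x$target_intervals),
                r_nontarget = x$r_nontarget)
  }
  if (!is.null(x$selfish_rMA)) {
    st <- with_selfish_rMA(st, x$selfish_rMA$r0_min, x$selfish_rMA$r0_max)
  }
  st
}

#' Write a model configuration to YAML or JSON
#'
#' Serialises selection parameters, system configuration and (optionally)
#' strategies into a flat key-value file keyed by the conventional symbols
#' (`s`, `h`, `e_axa`, `e_axd`, `e_dxd`, `n_selected`, `r_MA`, `u`, `c`,
#' `r_min`, `r_max`, ...). The format is chosen by file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param file Output path.
#' @param params A [fitness_params()].
#' @param config A [system_config()].
#' @param strategies Optional list of up to two `recomb_strategy` objects.
#' @return `file`, invisibly.
#' @export
write_model_config <- function(file, params, config, strategies = NULL) {
  x <- list(
    s = params$s, h = params$h, e_axa = params$e_axa, e_axd = params$e_axd,
    e_dxd = params$e_dxd,
    n_selected = config$n_selected, r_MA = config$r_MA, u = config$u,
    c = config$c
  )
  if (!is.null(strategies)) {
    if (inherits(strategies, "recomb_strategy")) strategies <- list(strategies)
    x$strategies <- lapply(strategies, strategy_to_list)
  }
  if (grepl("\\.ya?ml$", file)) {
    yaml::write_yaml(x, file)
  } else if (grepl("\\.json$", file)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stop("unrecognised config extension (use .yaml, .yml or .json): ", file)
  }
  invisible(file)
}

#' Read a model configuration from YAML or JSON
#'
#' @param file Path written by [write_model_config()] (or hand-written with
#'   the same keys; missing keys fall back to the constructors' defaults).
#' @return A list with elements `params`, `config` and (possibly `NULL`)
#'   `strategies`.
#' @export
read_model_config <- function(file) {
  x <- if (grepl("\\.ya?ml$", file)) {
    yaml::read_yaml(file)
  } else if (grepl("\\.json$", file)) {
    jsonlite::read_json(file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("unrecognised config extension (use .yaml, .yml or .json): ", file)
  }
  grab <- function(name, default) if (is.null(x[[name]])) default else x[[name]]
  params <- fitness_params(
    s = x$s, h = x$h, e_axa = grab("e_axa", 0), e_axd = grab("e_axd", 0),
    e_dxd = grab("e_dxd", 0)
  )
  config <- system_config(
    n_selected = grab("n_selected", 3L), r_MA = grab("r_MA", 0.5),
    u = grab("u", 1e-4), c = grab("c", 1)
  )
  strategies <- if (!is.null(x$strategies)) {
    lapply(x$strategies, strategy_from_list)
  }
  list(params = params, config = config, strategies = strategies)
}
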