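#' Read search parameters from a YAML configuration
#'
#' A flat YAML file with optional blocks `ga`, `stage2`, `mosa`, `mots`,
#' each holding the fields of the matching parameter constructor, e.g.
#'
#' ```yaml
#' ga:     {pop: 100, generations: 200, mutation_rate: 0.1, crossover_rate: 0.7}
#' stage2: {pop: 30, generations: 40}
#' mosa:   {start_temp: 1000, end_temp: 1.0e-3, cooling_rate: 0.95}
#' mots:   {tabu_list_size: 50, tabu_tenure: 5, candidate_set_size: 10, iterations: 200}
#' ```
#'
#' Missing blocks and fields fall back to the constructors' defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list with elements `ga`, `stage2`, `mosa`, `mots`.
#' @export
read_params <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading YAML configurations requires the yaml package.")
  }
  x <- yaml::read_yaml(path)
  build <- function(ctor, block) do.call(ctor, x[[block]] %||% list())
  list(
    ga = build(ga_params, "ga"),
    stage2 = do.call(ga_params, utils::modifyList(
      list(pop = 30, generations = 40), x[["stage2"]] %||% list())),
    mosa = build(mosa_params, "mosa"),
    mots = build(mots_params, "mots")
  )
}
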