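#' Published reference variance components for black spruce clonal trials
#'
#' REML variance-component estimates and derived genetic parameters reported
#' for four black spruce breeding populations (labelled A-West, A-East, C, D),
#' each evaluated in two clone trials, for total height (TH, cm), diameter at
#' breast height (DBH, mm), Pilodyn penetration (Dpil, mm), acoustic velocity
#' (Vdir, km/s) and the derived dynamic MoE (GPa). Shipped with the package
#' as an arithmetic-consistency surface: the derived columns (`sigma2P`,
#' `ratio`, `H2`, `rB`, percentage shares) can be recomputed from the raw
#' components with [genetic_parameters()] and compared with the printed,
#' rounded values.
#'
#' `plot` is `NA` where the among-plot stratum was absent from the published
#' model (wood traits measured on one ramet per plot, and both growth traits
#' of population D). `ratio` and `pct_site_clone` are character columns
#' because two cells are printed as upper bounds (`"<0.01"`, `"<0.1"`).
#'
#' @return A tibble with one row per population x trait.
#' @export
reference_components <- function() {
  path <- system.file("extdata", "reference_components.csv",
                      package = "clonegx", mustWork = TRUE)
  readr::read_csv(
    path,
    col_types = readr::cols(
      population = readr::col_character(),
      trait = readr::col_character(),
      ratio = readr::col_character(),
      pct_site_clone = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}
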