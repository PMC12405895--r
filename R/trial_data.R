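#' Read a clonal-trial observation table
#'
#' Reads one-row-per-ramet observation tables from CSV or TSV, maps columns to
#' the canonical identifiers (`population`, `site`, `block`, `clone`, `ramet`,
#' optionally `family`) and trait columns, validates the trial design, and
#' returns a tibble of observations.
#'
#' Identifier columns are read as character and treated as opaque labels except
#' `block`, which must be a positive integer. Empty cells, `"NA"` and `"."` are
#' all accepted as missing-value tokens in trait columns (the latter being the
#' classic SAS convention); they are preserved as `NA`, never as zero.
#'
#' Validation checks that every block label is used consistently within its
#' site (blocks are nested in sites), that no (site, block, clone) plot holds
#' more than `plot_size` ramets, and that every row carries at least one
#' non-missing trait value. Violations are reported with row numbers; plot-size
#' violations name the offending plot.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Named character vector mapping canonical names to file column
#'   names, e.g. `c(site = "SITE", clone = "CLONE_ID", TH = "HT_CM")`.
#'   Canonical identifier names: `population`, `site`, `block`, `clone`,
#'   `ramet`, `family` (optional). Any other canonical name is taken to be a
#'   trait column. Defaults to the identity mapping for the standard names
#'   `population, site, block, clone, family, ramet, TH, DBH, Dpil, Vdir`.
#' @param plot_size Maximum ramets per (site, block, clone) plot; default 2.
#' @param delim Field delimiter; `NULL` (default) chooses by file extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#'
#' @return A tibble with one row per ramet, identifier columns first, trait
#'   columns as doubles. Attribute `"plot_size"` records the design constant.
#' @seealso [write_observations()], [moe_from_pilodyn()], [simulate_clone_trial()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' obs <- simulate_clone_trial(sim_config(n_clones = 10, n_blocks = 2), seed = 1)
#' write_observations(obs, tf)
#' read_observations(tf)
read_observations <- function(path, schema = NULL, plot_size = 2, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "clonegx_io_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE
  )

  schema <- resolve_schema(schema, names(raw))
  id_cols <- intersect(c("population", "site", "block", "clone", "family", "ramet"),
                       names(schema))
  required <- c("population", "site", "block", "clone", "ramet")
  missing_req <- setdiff(required, id_cols)
  if (length(missing_req) > 0) {
    abort(
      paste0("missing required column(s): ", paste(missing_req, collapse = ", ")),
      class = "clonegx_schema_error"
    )
  }
  absent <- setdiff(unname(schema), names(raw))
  if (length(absent) > 0) {
    abort(
      paste0("column(s) named in schema not present in file: ",
             paste(absent, collapse = ", ")),
      class = "clonegx_schema_error"
    )
  }

  out <- raw[unname(schema)]
  names(out) <- names(schema)
  trait_cols <- setdiff(names(schema), id_cols)

  na_tokens <- c("", "NA", ".")
  for (tc in trait_cols) {
    x <- out[[tc]]
    x[x %in% na_tokens] <- NA_character_
    sup <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(sup))
    if (length(bad) > 0) {
      abort(
        paste0("non-numeric value in trait column '", tc, "' at data row(s) ",
               paste(head(bad, 5), collapse = ", ")),
        class = "clonegx_schema_error"
      )
    }
    out[[tc]] <- sup
  }
  out$block <- validate_block(out$block)

  obs <- as_tibble(out[c(id_cols, trait_cols)])
  validate_observations(obs, plot_size = plot_size, trait_cols = trait_cols)
  attr(obs, "plot_size") <- plot_size
  obs
}

resolve_schema <- function(schema, file_cols) {
  default_names <- c("population", "site", "block", "clone", "family", "ramet",
                     "TH", "DBH", "Dpil", "Vdir", "MoE")
  if (is.null(schema)) {
    present <- intersect(default_names, file_cols)
    schema <- setNames(present, present)
  }
  if (is.null(names(schema)) || any(names(schema) == "")) {
    abort("schema must be a fully named character vector",
          class = "clonegx_schema_error")
  }
  schema
}

validate_block <- function(block) {
  b <- suppressWarnings(as.integer(block))
  bad <- which(is.na(b) | b < 1)
  if (length(bad) > 0) {
    abort(
      paste0("block must be a positive integer; offending row(s): ",
             paste(head(bad, 5), collapse = ", ")),
      class = "clonegx_validation_error"
    )
  }
  b
}

#' Validate a clonal-trial observation table
#'
#' Checks the design invariants of an observation table: plot occupancy at most
#' `plot_size` ramets per (site, block, clone), and at least one non-missing
#' trait value per row. Called by [read_observations()]; exported so that
#' programmatically built tables can be checked the same way.
#'
#' @param obs Observation tibble.
#' @param plot_size Maximum ramets per plot.
#' @param trait_cols Character vector of trait column names; default all
#'   numeric non-identifier columns.
#' @return `obs`, invisibly, if valid; otherwise an error describing every
#'   offending plot or row.
#' @export
validate_observations <- function(obs, plot_size = 2, trait_cols = NULL) {
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(names(obs)[vapply(obs, is.numeric, logical(1))], "block")
  }
  occupancy <- obs |>
    group_by(.data$site, .data$block, .data$clone) |>
    summarise(n_ramets = n(), .groups = "drop") |>
    filter(.data$n_ramets > plot_size)
  if (nrow(occupancy) > 0) {
    plots <- paste0("(site=", occupancy$site, ", block=", occupancy$block,
                    ", clone=", occupancy$clone, ": ", occupancy$n_ramets,
                    " ramets)")
    abort(
      paste0("plot occupancy exceeds plot_size=", plot_size, " for plot(s) ",
             paste(head(plots, 5), collapse = "; ")),
      class = "clonegx_validation_error"
    )
  }
  if (length(trait_cols) > 0) {
    all_missing <- which(rowSums(!is.na(obs[trait_cols])) == 0)
    if (length(all_missing) > 0) {
      abort(
        paste0("row(s) with no non-missing trait value: ",
               paste(head(all_missing, 5), collapse = ", ")),
        class = "clonegx_validation_error"
      )
    }
  }
  invisible(obs)
}

#' Write a clonal-trial observation table
#'
#' Inverse of [read_observations()]: writes CSV/TSV with missing trait cells as
#' empty fields, so a read/write/read round trip reproduces the table
#' cell-for-cell including missingness.
#'
#' @param obs Observation tibble.
#' @param path Output path; extension `.tsv`/`.txt` selects tab delimiting.
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  readr::write_delim(obs, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}

#' Dynamic modulus of elasticity from Pilodyn penetration and acoustic velocity
#'
#' Computes the indirect (dynamic) modulus of elasticity from the Pilodyn
#' penetration depth, an inverse proxy of wood density, and the stem acoustic
#' wave velocity: `MoE = (10 / Dpil) * Vdir^2`, giving GPa when `Dpil` is in mm
#' and `Vdir` in km/s. The formula is unit-bound; no unit detection is
#' attempted. Vectorized; `NA` in either input yields `NA` (no imputation).
#'
#' @param Dpil Pilodyn penetration depth, mm, strictly positive.
#' @param Vdir Acoustic velocity, km/s, strictly positive.
#' @return Dynamic MoE in GPa, same length as the inputs.
#' @export
#' @examples
#' moe_from_pilodyn(Dpil = 10, Vdir = 3) # 9 GPa
moe_from_pilodyn <- function(Dpil, Vdir) {
  bad <- which(!is.na(Dpil) & Dpil <= 0 | !is.na(Vdir) & Vdir < 0)
  if (length(bad) > 0) {
    abort(paste0("Dpil must be > 0 and Vdir >= 0; offending element(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "clonegx_domain_error")
  }
  (10 / Dpil) * Vdir^2
}

#' Add the derived MoE trait to an observation table
#'
#' Computes `MoE` via [moe_from_pilodyn()] wherever both `Dpil` and `Vdir` are
#' present; other rows get `NA`.
#'
#' @param obs Observation tibble with `Dpil` and `Vdir` columns.
#' @return `obs` with an added (or overwritten) `MoE` column.
#' @export
add_moe <- function(obs) {
  if (!all(c("Dpil", "Vdir") %in% names(obs))) {
    abort("columns 'Dpil' and 'Vdir' are required to derive MoE",
          class = "clonegx_schema_error")
  }
  mutate(obs, MoE = moe_from_pilodyn(.data$Dpil, .data$Vdir))
}

#' Phenotypic summary of a trait
#'
#' Mean, standard deviation and coefficient of variation of a trait across all
#' measured ramets, with the usual agronomic homogeneity classification of the
#' CV: homogeneous (CV <= 15%), moderately heterogeneous (15% < CV <= 30%),
#' heterogeneous (CV > 30%).
#'
#' @param obs Observation tibble.
#' @param trait Trait column name.
#' @return One-row tibble: `trait`, `n`, `mean`, `sd`, `cv_pct`, `homogeneity`.
#' @export
phenotypic_summary <- function(obs, trait) {
  x <- obs[[trait]]
  if (is.null(x)) {
    abort(paste0("no trait column '", trait, "'"), class = "clonegx_schema_error")
  }
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    abort(paste0("trait '", trait, "' has fewer than 2 non-missing values"),
          class = "clonegx_domain_error")
  }
  m <- mean(x)
  s <- sd(x)
  cv <- 100 * s / m
  cls <- if (cv <= 15) "homogeneous" else if (cv <= 30) {
    "moderately heterogeneous"
  } else "heterogeneous"
  tibble(trait = trait, n = length(x), mean = m, sd = s,
         cv_pct = cv, homogeneity = cls)
}
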