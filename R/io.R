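#' Read raw fruit assay tables
#'
#' Reads the three delimited (comma-separated) raw tables the pipeline
#' consumes and validates them row by row:
#' \itemize{
#'   \item fruit table: `fruit_id`, `genotype`, `mass_g`, `tss_brix`,
#'     optional `collection`, `season`, `firmness_score`, `achene_score`;
#'   \item uptake table (long): `fruit_id`, `time_h`, `mass_g`;
#'   \item water-soaking table (long): `fruit_id`, `time_h`, `rating`.
#' }
#' Files carry hours and grams; conversion to seconds and kilograms
#' happens inside the derivation functions. Rows violating validity rules
#' (negative mass, TSS < 0, rating outside 0..4, unknown fruit ids) are
#' dropped and collected, with line numbers, in the `"violations"`
#' attribute; a missing required column is an error naming the column.
#'
#' @param fruit_path,uptake_path,ws_path File paths; `ws_path` may be
#'   `NULL` when only uptake phenotyping is run.
#' @return A list with tibbles `fruit`, `uptake`, `ws` (possibly `NULL`)
#'   and a `violations` tibble attribute (`table`, `line`, `fruit_id`,
#'   `problem`).
#' @export
read_fruit_tables <- function(fruit_path, uptake_path, ws_path = NULL) {
  violations <- list()
  note <- function(table, line, fruit_id, problem) {
    violations[[length(violations) + 1L]] <<- tibble::tibble(
      table = table, line = line, fruit_id = as.character(fruit_id),
      problem = problem)
  }
  read_one <- function(path, required, table) {
    if (!file.exists(path)) abort(paste0("File not found: ", path))
    d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    miss <- setdiff(required, names(d))
    if (length(miss)) {
      abort(paste0(table, " table '", path, "' is missing required column(s): ",
                   paste(miss, collapse = ", ")))
    }
    d
  }

  fruit <- read_one(fruit_path, c("fruit_id", "genotype", "mass_g", "tss_brix"), "fruit")
  bad <- which(is.na(fruit$mass_g) | fruit$mass_g < 0 |
                 is.na(fruit$tss_brix) | fruit$tss_brix < 0)
  for (i in bad) note("fruit", i + 1L, fruit$fruit_id[i], "invalid mass_g or tss_brix")
  if (length(bad)) fruit <- fruit[-bad, ]

  uptake <- read_one(uptake_path, c("fruit_id", "time_h", "mass_g"), "uptake")
  bad <- which(is.na(uptake$time_h) | uptake$time_h < 0 |
                 is.na(uptake$mass_g) | uptake$mass_g <= 0 |
                 !(uptake$fruit_id %in% fruit$fruit_id))
  for (i in bad) note("uptake", i + 1L, uptake$fruit_id[i], "invalid time/mass or unknown fruit_id")
  if (length(bad)) uptake <- uptake[-bad, ]

  ws <- NULL
  if (!is.null(ws_path)) {
    ws <- read_one(ws_path, c("fruit_id", "time_h", "rating"), "ws")
    bad <- which(is.na(ws$time_h) | ws$time_h < 0 | ws$time_h > 24 |
                   is.na(ws$rating) | ws$rating < 0 | ws$rating > 4 |
                   !(ws$fruit_id %in% fruit$fruit_id))
    for (i in bad) note("ws", i + 1L, ws$fruit_id[i], "invalid time/rating or unknown fruit_id")
    if (length(bad)) ws <- ws[-bad, ]
  }

  out <- list(fruit = fruit, uptake = uptake, ws = ws)
  attr(out, "violations") <- if (length(violations)) {
    dplyr::bind_rows(violations)
  } else {
    tibble::tibble(table = character(), line = integer(),
                   fruit_id = character(), problem = character())
  }
  out
}

#' Write panel tables as plain CSV
#'
#' Writes the raw tables of a synthetic panel (and its latent truth) in
#' the same schema [read_fruit_tables()] consumes, so generated panels
#' round-trip through the readers.
#'
#' @param panel A [generate_panel()] object.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "ws_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fruit = file.path(dir, "fruit.csv"),
    uptake = file.path(dir, "uptake.csv"),
    ws = file.path(dir, "ws.csv"),
    latents = file.path(dir, "latents.csv")
  )
  readr::write_csv(panel$fruit |>
                     dplyr::select(-dplyr::any_of(c("permeance_true", "lag_true",
                                                    "rate_true", "asymptote_true"))),
                   paths["fruit"])
  readr::write_csv(panel$uptake, paths["uptake"])
  readr::write_csv(panel$ws, paths["ws"])
  readr::write_csv(panel$latents, paths["latents"])
  invisible(paths)
}

#' Run the full phenotyping study on a panel or on raw tables
#'
#' Chains the pipeline end to end: derive per-fruit uptake traits, fit
#' water-soaking kinetics, summarise per genotype, and compute the
#' statistical layer (correlation tables per collection and pooled, the
#' water-soaking versus log-permeance regression, distribution reports,
#' and between-collection comparisons). Deterministic given the input
#' tables.
#'
#' @param tables A list with `fruit`, `uptake`, `ws` tibbles — either
#'   from [read_fruit_tables()] or a [generate_panel()] object.
#' @param constants A [physical_constants()] object.
#' @param index_time_h Water-soaking index time, hours.
#' @param fit_kinetics Fit the per-fruit Gompertz kinetics (time lag and
#'   rate). When `FALSE` the study runs on the observed water-soaking
#'   index alone — the 4-h score is read directly off the schedule, so
#'   uptake- and index-level results are identical and much faster.
#' @param out_dir Optional directory; when given, all result tables are
#'   written there as CSV plus a plain-text provenance file recording the
#'   constants and options used.
#' @return A list of class `ws_study`: `per_fruit`, `genotype_summary`
#'   (long), `trait_means` (wide), `correlations`, `ws_regression`,
#'   `collection_comparison`, `distributions`.
#' @export
run_study <- function(tables, constants = physical_constants(),
                      index_time_h = 4, fit_kinetics = TRUE, out_dir = NULL) {
  if (inherits(tables, "ws_panel")) {
    constants <- tables$config$constants
    index_time_h <- tables$config$index_time_h
  }
  fruit <- tables$fruit; uptake <- tables$uptake; ws <- tables$ws
  if (is.null(ws)) abort("run_study needs a water-soaking table ('ws'); none was provided.")

  derived <- derive_uptake(fruit, uptake, constants)
  kinetics <- if (fit_kinetics) {
    fit_ws_courses(ws, index_time_h = index_time_h)
  } else {
    idx <- ws |>
      dplyr::filter(abs(.data$time_h - index_time_h) < 1e-8) |>
      dplyr::distinct(.data$fruit_id, .keep_all = TRUE) |>
      dplyr::select("fruit_id", ws_index = "rating")
    if (nrow(idx) == 0L) {
      abort(paste0("No water-soaking observation at the index time (",
                   index_time_h, " h); fit the kinetics instead."))
    }
    idx
  }
  per_fruit <- derived |>
    dplyr::left_join(kinetics, by = "fruit_id") |>
    dplyr::left_join(fruit |>
                       dplyr::select(dplyr::any_of(c("fruit_id", "firmness_score",
                                                     "achene_score"))),
                     by = "fruit_id")

  trait_cols <- intersect(
    c("ws_index", "lag_h", "rate_per_h", "flow_rate_mg_h", "flux_kg_m2_s",
      "permeance_m_s", "psi_pi_mpa", "mass_g", "area_cm2", "firmness_score",
      "achene_score"),
    names(per_fruit))
  summary_long <- summarize_genotypes(per_fruit, traits = trait_cols)
  means <- genotype_trait_matrix(summary_long)

  cor_traits <- intersect(c("ws_index", "flow_rate_mg_h", "flux_kg_m2_s",
                            "permeance_m_s", "log10_permeance", "area_cm2",
                            "firmness_score", "psi_pi_mpa"), names(means))
  by_cols <- intersect(c("collection", "season"), names(means))
  correlations <- correlation_matrix(means, cor_traits,
                                     by = if (length(by_cols)) by_cols else NULL)
  regression <- regress_ws_on_log_permeance(means)

  comparison <- NULL
  if ("collection" %in% names(means) &&
      dplyr::n_distinct(means$collection) >= 2) {
    grp <- means |>
      dplyr::mutate(group = paste(.data$collection, .data$season, sep = "/"))
    comparison <- list(
      ws_index = compare_groups(grp, "ws_index", "group", method = "mann_whitney")
    )
    if ("lag_h" %in% names(grp)) {
      comparison$lag_h <- compare_groups(grp, "lag_h", "group", method = "tukey")
      comparison$rate_per_h <- compare_groups(grp, "rate_per_h", "group", method = "tukey")
    }
  }

  distributions <- list(
    ws_index = distribution_report(means$ws_index),
    log10_permeance = distribution_report(means$log10_permeance)
  )

  out <- structure(list(per_fruit = per_fruit, genotype_summary = summary_long,
                        trait_means = means, correlations = correlations,
                        ws_regression = regression,
                        collection_comparison = comparison,
                        distributions = distributions,
                        constants = constants, index_time_h = index_time_h),
                   class = "ws_study")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(per_fruit, file.path(out_dir, "per_fruit_traits.csv"))
    readr::write_csv(summary_long, file.path(out_dir, "genotype_summary.csv"))
    readr::write_csv(means, file.path(out_dir, "genotype_trait_means.csv"))
    readr::write_csv(correlations, file.path(out_dir, "correlations.csv"))
    readr::write_csv(glance(regression), file.path(out_dir, "ws_regression.csv"))
    writeLines(c(
      "permeaphen provenance",
      sprintf("package version: %s", as.character(utils::packageVersion("permeaphen"))),
      sprintf("R version: %s", R.version.string),
      sprintf("constants: R=%g T=%g rho=%g Vw=%g", constants$R, constants$T_K,
              constants$rho, constants$Vw),
      sprintf("index time (h): %g", index_time_h)
    ), file.path(out_dir, "provenance.txt"))
  }
  out
}

#' @export
print.ws_study <- function(x, ...) {
  cat("Water-soaking phenotyping study\n")
  cat(sprintf("  %d fruit, %d genotypes\n", nrow(x$per_fruit),
              nrow(x$trait_means)))
  cat(sprintf("  WS ~ log10(permeance): R^2 = %.1f%% (p = %.2g)\n",
              x$ws_regression$r_squared_pct, x$ws_regression$p_value))
  invisible(x)
}
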