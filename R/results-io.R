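#' Assemble the result bundle of a fitted model
#'
#' Collects everything the analysis reports into named tibbles: coefficient
#' posterior summaries, species/site/cell affinity classifications, the
#' absent/present subset comparison and the convergence diagnostics.
#'
#' @param fit a [dda_fit()] object.
#' @param level credible level for all summaries.
#' @return a list of class `dda_results` holding tibbles plus a `metadata`
#'   list (seed, schedule, priors, delta, dimensions).
#' @export
dda_results <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dda_fit"))
  structure(
    list(
      coefficients = coefficient_table(fit, level),
      species_affinity = posterior_affinity(fit, "species", level),
      site_affinity = posterior_affinity(fit, "site", level),
      cell_affinity = posterior_affinity(fit, "cell", level),
      subset_comparison = compare_subsets(fit),
      diagnostics = fit$diagnostics$rhat,
      metadata = list(
        seed = fit$seed, level = level,
        chains = fit$control$chains, samples = fit$control$samples,
        burnin = fit$diagnostics$burnin, thin = fit$diagnostics$thin,
        escalations = fit$diagnostics$escalations,
        converged = fit$diagnostics$converged,
        delta = fit$data$delta,
        n_species = nrow(fit$data$prab), n_sites = ncol(fit$data$prab),
        priors = unclass(fit$priors),
        package_version = as.character(utils::packageVersion("darkaffinity"))
      )
    ),
    class = "dda_results"
  )
}

#' Write a result bundle to delimited files
#'
#' Each tibble becomes one CSV; the metadata (configuration, seed, schedule)
#' is written as `run_metadata.json`. Re-running the same seeded analysis
#' and writing again reproduces byte-identical files.
#'
#' @param results a [dda_results()] object, or any named list of data frames
#'   (optionally with a `metadata` element).
#' @param dir output directory (created if absent).
#' @return a tibble manifest with `file` and `rows` per written table.
#' @export
write_dda_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- results[vapply(results, is.data.frame, logical(1))]
  manifest <- purrr::map_dfr(names(tables), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], path)
    tibble(file = paste0(nm, ".csv"), rows = nrow(tables[[nm]]))
  })
  meta <- results$metadata %||% list()
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (nrow(manifest) == 0) {
    manifest <- tibble(file = character(), rows = integer())
  }
  manifest
}
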