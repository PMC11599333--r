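#' Tidy a fitted affinity model
#'
#' One row per coefficient with posterior mean, median, credible bounds,
#' significance flag and R-hat.
#'
#' @param x a [dda_fit()] object.
#' @param level credible level.
#' @param ... unused.
#' @return a tibble; see [coefficient_table()].
#' @export
tidy.dda_fit <- function(x, level = 0.95, ...) {
  coefficient_table(x, level)
}

#' One-row summary of a fitted affinity model
#'
#' @param x a [dda_fit()] object.
#' @param ... unused.
#' @return tibble with dimensions, draw counts, schedule, max R-hat,
#'   convergence flag and delta.
#' @export
glance.dda_fit <- function(x, ...) {
  tibble(
    n_species = nrow(x$data$prab),
    n_sites = ncol(x$data$prab),
    n_coefficients = length(x$par_names),
    chains = x$control$chains,
    draws = x$control$chains * x$control$samples,
    burnin = x$diagnostics$burnin,
    thin = x$diagnostics$thin,
    escalations = x$diagnostics$escalations,
    max_rhat = max(x$diagnostics$rhat$rhat),
    converged = x$diagnostics$converged,
    delta = x$data$delta
  )
}

#' Tidy a recovery experiment
#'
#' @param x a [recovery_experiment()] result.
#' @param ... unused.
#' @return the per-replicate, per-coefficient tibble.
#' @export
tidy.dda_recovery <- function(x, ...) x$coefficients

#' One-row summary of a recovery experiment
#'
#' @param x a [recovery_experiment()] result.
#' @param ... unused.
#' @return tibble with pooled credible-interval coverage of all true
#'   coefficients, the correct-sign significance rate of the injected
#'   (non-zero) coefficients, the false-significance rate among true-zero
#'   slope coefficients, mean classification accuracy, and the fraction of
#'   converged fits.
#' @export
glance.dda_recovery <- function(x, ...) {
  co <- x$coefficients
  slopes <- co[grepl("^b_", co$term), ]
  injected <- slopes[slopes$truth != 0, ]
  nulls <- slopes[slopes$truth == 0, ]
  tibble(
    n_replicates = max(co$replicate),
    coverage = mean(co$covered),
    injected_sign_rate = if (nrow(injected) > 0) {
      mean(injected$significant & injected$sign_correct)
    } else NA_real_,
    null_significance_rate = if (nrow(nulls) > 0) {
      mean(nulls$significant)
    } else NA_real_,
    classification_accuracy = mean(x$classification$accuracy, na.rm = TRUE),
    prop_converged = mean(x$fits_converged$converged)
  )
}

#' Coefficient interval plot for a fitted affinity model
#'
#' Posterior means with credible intervals per coefficient, split by model
#' side; significant coefficients (interval excluding 0) are filled.
#'
#' @param object a [dda_fit()] object.
#' @param level credible level.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dda_fit <- function(object, level = 0.95, ...) {
  ct <- coefficient_table(object, level)
  ggplot(ct, aes(x = .data$mean, y = .data$term,
                 xmin = .data$lower, xmax = .data$upper,
                 colour = .data$side, shape = .data$significant)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_pointrange() +
    scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    labs(x = "posterior mean (credible interval)", y = NULL,
         colour = "side", shape = "CI excludes 0") +
    theme_minimal()
}

#' Affinity classification plot
#'
#' Medians and credible intervals of per-entity affinity against the 0.5
#' threshold, coloured by classification label.
#'
#' @param affinity a tibble from [posterior_affinity()] (species or site).
#' @return a ggplot object.
#' @export
plot_affinity <- function(affinity) {
  id_col <- intersect(c("species", "site"), names(affinity))[1]
  ggplot(affinity, aes(x = .data$median,
                       y = stats::reorder(.data[[id_col]], .data$median),
                       xmin = .data$lower, xmax = .data$upper,
                       colour = .data$label)) +
    geom_vline(xintercept = 0.5, linetype = 2, colour = "grey40") +
    geom_pointrange(linewidth = 0.3, size = 0.3) +
    scale_colour_manual(values = c(`dark-affine` = "black",
                                   `presence-affine` = "steelblue",
                                   unresolved = "grey60")) +
    labs(x = "dark diversity affinity", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Recovery plot: posterior estimates against truth
#'
#' @param object a [recovery_experiment()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dda_recovery <- function(object, ...) {
  co <- object$coefficients
  ggplot(co, aes(x = .data$truth, y = .data$mean,
                 ymin = .data$lower, ymax = .data$upper,
                 colour = .data$covered)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2,
                colour = "grey50") +
    geom_pointrange(position = position_jitter(width = 0.04, seed = 1),
                    alpha = 0.6, size = 0.2) +
    facet_wrap(~term) +
    labs(x = "true coefficient", y = "posterior mean (CI)",
         colour = "CI covers truth") +
    theme_minimal()
}
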