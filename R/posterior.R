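#' Median and central credible interval of posterior draws
#'
#' Quantiles use linear interpolation (type 7); the default 95% level takes
#' the 2.5% and 97.5% quantiles.
#'
#' @param draws numeric vector of posterior draws, or a matrix with one
#'   column per entity.
#' @param level credible level in (0, 1).
#' @return a tibble with columns `median`, `lower`, `upper` (one row per
#'   entity for matrix input).
#' @export
summarize_draws <- function(draws, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1)
  if (nrow(draws) < 1) abort("no draws to summarise.")
  a <- (1 - level) / 2
  qs <- apply(draws, 2, quantile, probs = c(a, 0.5, 1 - a), names = FALSE,
              type = 7)
  tibble(median = qs[2, ], lower = qs[1, ], upper = qs[3, ])
}

#' Classify affinity against the 0.5 threshold
#'
#' An entity (or cell) is `dark-affine` when the lower credible bound
#' exceeds 0.5 (credibly more absent than present from suitable
#' sites), `presence-affine` when the upper bound is below 0.5, and
#' `unresolved` otherwise.
#'
#' @param summary a tibble with `lower` and `upper` columns (e.g. from
#'   [summarize_draws()]).
#' @return the tibble with a `label` column added.
#' @export
classify_affinity <- function(summary) {
  stopifnot(all(c("lower", "upper") %in% names(summary)))
  mutate(summary, label = dplyr::case_when(
    .data$lower > 0.5 ~ "dark-affine",
    .data$upper < 0.5 ~ "presence-affine",
    TRUE ~ "unresolved"
  ))
}

# Per-draw logit-scale linear predictors for each entity (draws x entities).
draw_eta <- function(fit, side = c("sp", "site")) {
  side <- match.arg(side)
  X <- fit$designs[[side]]$X
  dm <- as.matrix(fit$draws[, fit$par_names, drop = FALSE])
  a <- dm[, paste0("a_", side)]
  bcols <- grep(paste0("^b_", side, ":"), colnames(dm))
  eta <- matrix(a, nrow(dm), nrow(X))
  if (length(bcols) > 0) {
    eta <- eta + dm[, bcols, drop = FALSE] %*% t(X)
  }
  colnames(eta) <- rownames(X)
  eta
}

#' Posterior affinity summaries per species, site or cell
#'
#' Recomputes the derived quantities from the coefficient draws: `dda_sp`
#' per species, `dda_site` per site, and unified `DDA` and presence
#' likelihood `p` per species-site cell, then summarises each with
#' [summarize_draws()] and labels it with [classify_affinity()] (the `p`
#' quantity is reported without a label; 0.5 is not a threshold for it).
#'
#' @param fit a [dda_fit()] object.
#' @param what which quantity to summarise: `"species"` (dda_sp), `"site"`
#'   (dda_site), or `"cell"` (DDA and p).
#' @param level credible level.
#' @return a tibble keyed by species/site (and `quantity` for cells).
#' @export
posterior_affinity <- function(fit, what = c("species", "site", "cell"),
                               level = 0.95) {
  stopifnot(inherits(fit, "dda_fit"))
  what <- match.arg(what)
  if (what == "species") {
    s <- classify_affinity(summarize_draws(plogis(draw_eta(fit, "sp")),
                                           level))
    return(dplyr::bind_cols(tibble(species = fit$designs$sp$ids), s))
  }
  if (what == "site") {
    s <- classify_affinity(summarize_draws(plogis(draw_eta(fit, "site")),
                                           level))
    return(dplyr::bind_cols(tibble(site = fit$designs$site$ids), s))
  }
  cd <- cell_draws(fit)
  ids <- cells_tbl(fit$data$prab, "prab")[, c("species", "site")]
  dda_s <- dplyr::bind_cols(ids, quantity = "DDA",
                            classify_affinity(summarize_draws(cd$dda, level)))
  p_s <- dplyr::bind_cols(ids, quantity = "p", summarize_draws(cd$p, level))
  bind_rows(dda_s, p_s)
}

# Draws of the cellwise unified DDA and presence likelihood
# (draws x cells matrices, cells in column-major prab order).
cell_draws <- function(fit) {
  eta_sp <- draw_eta(fit, "sp")
  eta_site <- draw_eta(fit, "site")
  S <- ncol(eta_sp)
  N <- ncol(eta_site)
  l_dda <- (eta_sp[, rep(seq_len(S), times = N), drop = FALSE] +
              eta_site[, rep(seq_len(N), each = S), drop = FALSE]) / 2
  dda <- plogis(l_dda)
  suit <- rep(as.vector(fit$data$suit), each = nrow(dda))
  q <- clamp_unit((1 - dda) * suit, fit$data$eps)
  p <- plogis(qlogis(q) + fit$data$delta)
  list(dda = dda, p = p)
}

#' Coefficient posterior summary table
#'
#' Posterior mean, median and central credible bounds per coefficient; a
#' coefficient is flagged significant when its credible interval excludes 0.
#'
#' @param fit a [dda_fit()] object.
#' @param level credible level.
#' @return a tibble with columns `term`, `side`, `mean`, `median`, `lower`,
#'   `upper`, `significant`, `rhat`.
#' @export
coefficient_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "dda_fit"))
  dm <- as.matrix(fit$draws[, fit$par_names, drop = FALSE])
  s <- summarize_draws(dm, level)
  out <- dplyr::bind_cols(
    tibble(
      term = fit$par_names,
      side = ifelse(grepl("(^a_sp$)|(^b_sp:)", fit$par_names),
                    "species", "site"),
      mean = colMeans(dm)
    ),
    s
  )
  out <- mutate(out, significant = .data$lower > 0 | .data$upper < 0)
  left_join(out, fit$diagnostics$rhat, by = "term")
}

#' Partition cells into absent and present subsets
#'
#' @param m a [metacommunity()] object or binary matrix.
#' @return a tibble with `species`, `site`, `prab` and `subset`
#'   (`"absent"`/`"present"`); warns when one subset is empty.
#' @export
split_subsets <- function(m) {
  prab <- if (inherits(m, "metacommunity")) m$prab else m
  out <- cells_tbl(prab, "prab")
  out <- mutate(out, subset = ifelse(.data$prab == 1, "present", "absent"))
  if (all(prab == 1) || all(prab == 0)) {
    warn("one subset is empty; absent/present comparisons will be skipped.")
  }
  out
}

#' Kruskal-Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H, chi-squared
#' p-value with k - 1 degrees of freedom) returning a one-row tibble. The
#' degenerate all-tied case is defined as H = 0, p = 1.
#'
#' @param values numeric observations.
#' @param groups group membership, same length; every group must be
#'   non-empty and at least two groups must be present.
#' @return tibble with `H`, `df`, `p_value`.
#' @export
kw_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    abort("kw_test needs at least two non-empty groups.")
  }
  if (length(values) != length(groups)) abort("length mismatch.")
  if (length(unique(values)) == 1) {
    return(tibble(H = 0, df = nlevels(droplevels(groups)) - 1, p_value = 1))
  }
  kt <- kruskal.test(values, droplevels(groups))
  tibble(H = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}

#' Compare absent and present subsets
#'
#' For each model quantity — presence likelihood `p`, suitability `suit`,
#' unified `DDA`, `dda_sp` and `dda_site` — assembles one value per cell
#' (suitability as computed; `p` and `DDA` as cellwise posterior medians;
#' `dda_sp` / `dda_site` as entity posterior medians broadcast over the
#' entity's cells) and tests the absent-cell values against the present-cell
#' values with a Kruskal-Wallis rank test. With `pool_draws = TRUE` every
#' retained posterior draw of every cell becomes an observation instead (a
#' sensitivity mode; it inflates the nominal sample size).
#'
#' @param fit a [dda_fit()] object.
#' @param pool_draws use pooled posterior draws instead of per-cell medians.
#' @return a tibble with one row per quantity: `quantity`, `median_absent`,
#'   `median_present`, `H`, `p_value`, `n_absent`, `n_present`.
#' @export
compare_subsets <- function(fit, pool_draws = FALSE) {
  stopifnot(inherits(fit, "dda_fit"))
  prab_vec <- as.vector(fit$data$prab)
  if (all(prab_vec == 1) || all(prab_vec == 0)) {
    warn("one subset empty; returning empty comparison.")
    return(tibble(quantity = character(), median_absent = numeric(),
                  median_present = numeric(), H = numeric(),
                  p_value = numeric(), n_absent = integer(),
                  n_present = integer()))
  }
  cd <- cell_draws(fit)
  sp_med <- apply(plogis(draw_eta(fit, "sp")), 2, median)
  site_med <- apply(plogis(draw_eta(fit, "site")), 2, median)
  S <- nrow(fit$data$prab)
  N <- ncol(fit$data$prab)

  per_cell <- list(
    p = apply(cd$p, 2, median),
    suit = as.vector(fit$data$suit),
    DDA = apply(cd$dda, 2, median),
    dda_sp = rep(sp_med, times = N),
    dda_site = rep(site_med, each = S)
  )
  pooled <- if (pool_draws) {
    n_draw <- nrow(cd$dda)
    list(
      p = as.vector(cd$p),
      suit = as.vector(fit$data$suit),
      DDA = as.vector(cd$dda),
      dda_sp = as.vector(plogis(draw_eta(fit, "sp"))[, rep(seq_len(S),
                                                           times = N)]),
      dda_site = as.vector(plogis(draw_eta(fit, "site"))[, rep(seq_len(N),
                                                               each = S)])
    )
  }
  purrr::map_dfr(names(per_cell), function(qt) {
    vals <- per_cell[[qt]]
    grp <- ifelse(prab_vec == 1, "present", "absent")
    test_vals <- vals
    test_grp <- grp
    if (pool_draws && qt != "suit") {
      test_vals <- pooled[[qt]]
      test_grp <- rep(grp, each = nrow(cd$dda))
    }
    kt <- kw_test(test_vals, test_grp)
    tibble(
      quantity = qt,
      median_absent = median(vals[prab_vec == 0]),
      median_present = median(vals[prab_vec == 1]),
      H = kt$H, p_value = kt$p_value,
      n_absent = sum(prab_vec == 0), n_present = sum(prab_vec == 1)
    )
  })
}
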