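#' Define a synthetic metacommunity scenario
#'
#' Describes a generating model for metacommunities with known affinity
#' structure: trait/attribute tables, true submodel coefficients, a
#' suitability source and the balancing constant. Defaults describe the
#' strong-signal study condition used throughout the package's calibration
#' checks: 60 species by 40 sites, two quantitative plus one three-level
#' categorical trait per side, an injected effect of +2 on the first species
#' trait and -2 on the first site attribute (all other coefficients 0), and
#' i.i.d. Beta(2, 2) suitability.
#'
#' @param n_species,n_sites matrix dimensions (>= 2).
#' @param n_quant_traits,n_cat_traits,cat_levels species trait schema:
#'   number of quantitative traits, of categorical traits, and levels per
#'   categorical trait.
#' @param n_quant_attrs,n_cat_attrs,attr_cat_levels site attribute schema.
#' @param a_sp,a_site true intercepts.
#' @param b_sp,b_site true coefficient vectors, one entry per design column
#'   (quantitative columns first, then `cat_levels` indicator columns per
#'   categorical variable). `NULL` means the default: +2 (`b_sp`) or -2
#'   (`b_site`) on the first quantitative column, 0 elsewhere.
#' @param suit_source `"beta"` for i.i.d. Beta draws, `"niche"` for a
#'   Gaussian niche kernel on a one-dimensional latent gradient.
#' @param beta_shape1,beta_shape2 Beta parameters (suit source `"beta"`).
#' @param niche_breadth niche breadth on the unit gradient (suit source
#'   `"niche"`).
#' @param delta balancing constant used at generation (the analysis path
#'   always recomputes it from the data).
#' @return a list of class `dda_scenario`.
#' @export
dda_scenario <- function(n_species = 60, n_sites = 40,
                         n_quant_traits = 2, n_cat_traits = 1,
                         cat_levels = 3,
                         n_quant_attrs = 2, n_cat_attrs = 1,
                         attr_cat_levels = 3,
                         a_sp = 0, a_site = 0,
                         b_sp = NULL, b_site = NULL,
                         suit_source = c("beta", "niche"),
                         beta_shape1 = 2, beta_shape2 = 2,
                         niche_breadth = 0.25, delta = 0) {
  stopifnot(n_species >= 2, n_sites >= 2,
            beta_shape1 > 0, beta_shape2 > 0, niche_breadth > 0)
  k_sp <- n_quant_traits + n_cat_traits * cat_levels
  k_site <- n_quant_attrs + n_cat_attrs * attr_cat_levels
  default_b <- function(k, val) {
    b <- numeric(k)
    if (k > 0) b[1] <- val
    b
  }
  b_sp <- b_sp %||% default_b(k_sp, 2)
  b_site <- b_site %||% default_b(k_site, -2)
  stopifnot(length(b_sp) == k_sp, length(b_site) == k_site)
  structure(
    list(n_species = n_species, n_sites = n_sites,
         n_quant_traits = n_quant_traits, n_cat_traits = n_cat_traits,
         cat_levels = cat_levels, n_quant_attrs = n_quant_attrs,
         n_cat_attrs = n_cat_attrs, attr_cat_levels = attr_cat_levels,
         a_sp = a_sp, a_site = a_site, b_sp = b_sp, b_site = b_site,
         suit_source = match.arg(suit_source),
         beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
         niche_breadth = niche_breadth, delta = delta),
    class = "dda_scenario"
  )
}

synth_table <- function(ids, id_name, n_quant, n_cat, levels, prefix) {
  out <- tibble(id = ids)
  names(out) <- id_name
  for (i in seq_len(n_quant)) {
    out[[sprintf("%s_q%d", prefix, i)]] <- rnorm(length(ids))
  }
  for (i in seq_len(n_cat)) {
    out[[sprintf("%s_c%d", prefix, i)]] <-
      sample(paste0("L", seq_len(levels)), length(ids), replace = TRUE)
  }
  out
}

#' Generate synthetic trait and attribute tables
#'
#' Quantitative values are drawn standard normal (so the sd-0.5
#' standardization is a near-identity up to scale) and categorical levels
#' uniformly over the declared level set.
#'
#' @param scn a [dda_scenario()].
#' @param seed integer seed.
#' @return a list with tibbles `traits` and `sites`.
#' @export
simulate_traits <- function(scn, seed = 1L) {
  stopifnot(inherits(scn, "dda_scenario"))
  withr::with_seed(seed, {
    sp_ids <- sprintf("sp%03d", seq_len(scn$n_species))
    st_ids <- sprintf("st%03d", seq_len(scn$n_sites))
    list(
      traits = synth_table(sp_ids, "species", scn$n_quant_traits,
                           scn$n_cat_traits, scn$cat_levels, "trait"),
      sites = synth_table(st_ids, "site", scn$n_quant_attrs,
                          scn$n_cat_attrs, scn$attr_cat_levels, "attr")
    )
  })
}

#' Generate a synthetic suitability matrix
#'
#' `"beta"` mode draws each cell i.i.d. Beta(shape1, shape2). `"niche"` mode
#' places species and sites uniformly on a unit gradient and sets
#' `suit = exp(-(pos_sp - pos_site)^2 / (2 * breadth^2))`, a Gaussian niche
#' kernel in (0, 1].
#'
#' @param scn a [dda_scenario()].
#' @param seed integer seed.
#' @return species-by-site suitability matrix (with attribute `positions`
#'   in niche mode).
#' @export
simulate_suitability <- function(scn, seed = 1L) {
  stopifnot(inherits(scn, "dda_scenario"))
  withr::with_seed(seed, {
    dn <- list(sprintf("sp%03d", seq_len(scn$n_species)),
               sprintf("st%03d", seq_len(scn$n_sites)))
    if (scn$suit_source == "beta") {
      matrix(rbeta(scn$n_species * scn$n_sites, scn$beta_shape1,
                   scn$beta_shape2),
             scn$n_species, scn$n_sites, dimnames = dn)
    } else {
      pos_sp <- runif(scn$n_species)
      pos_st <- runif(scn$n_sites)
      suit <- exp(-outer(pos_sp, pos_st, `-`)^2 /
                    (2 * scn$niche_breadth^2))
      dimnames(suit) <- dn
      attr(suit, "positions") <- list(species = pos_sp, sites = pos_st)
      suit
    }
  })
}

#' Simulate a metacommunity with known affinity structure
#'
#' Generative inversion of the unified model: trait/attribute tables are
#' drawn, design matrices built, true `dda_sp`/`dda_site` computed from the
#' scenario's coefficients, unified into cellwise DDA, combined with the
#' generated suitability and the scenario's `delta` into presence
#' likelihoods, and the binary matrix drawn cellwise Bernoulli. Degenerate
#' draws (all-present or all-absent) are resampled up to 20 times.
#'
#' @param scn a [dda_scenario()].
#' @param seed integer seed; all latents and the matrix are reproducible
#'   under it.
#' @param eps clamp width for the likelihood composition.
#' @return a list of class `dda_simulation`: `mc` (a [metacommunity()] with
#'   trait/attribute tables), `suit`, and `truth` (true coefficients, true
#'   `dda_sp`, `dda_site`, `DDA`, `p`, `delta`, `seed`, scenario).
#' @export
simulate_metacommunity <- function(scn, seed = 1L, eps = 1e-6) {
  stopifnot(inherits(scn, "dda_scenario"))
  tabs <- simulate_traits(scn, seed)
  suit <- simulate_suitability(scn, seed + 1L)
  des_sp <- design_or_null(tabs$traits, tabs$traits$species,
                           levels = declared_levels(scn, "trait"))
  des_site <- design_or_null(tabs$sites, tabs$sites$site,
                             levels = declared_levels(scn, "attr"))
  dda_sp <- dda_probability(des_sp$X, scn$a_sp, scn$b_sp)
  dda_site <- dda_probability(des_site$X, scn$a_site, scn$b_site)
  dda <- outer(qlogis(dda_sp), qlogis(dda_site), `+`) / 2
  dda <- plogis(dda)
  p <- presence_likelihood(dda, suit, scn$delta, eps)
  prab <- NULL
  for (try in seq_len(20)) {
    prab_try <- withr::with_seed(seed + 100L + try, {
      matrix(rbinom(length(p), 1L, as.vector(p)), nrow(p), ncol(p),
             dimnames = dimnames(suit))
    })
    if (any(prab_try == 1) && any(prab_try == 0)) {
      prab <- prab_try
      break
    }
  }
  if (is.null(prab)) {
    abort("degenerate scenario: all-present/all-absent after 20 resamples.")
  }
  names(dda_sp) <- rownames(suit)
  names(dda_site) <- colnames(suit)
  structure(
    list(
      mc = metacommunity(prab, traits = tabs$traits, sites = tabs$sites),
      suit = suit,
      truth = list(
        coefficients = stats::setNames(
          c(scn$a_sp, scn$a_site, scn$b_sp, scn$b_site),
          c("a_sp", "a_site",
            if (ncol(des_sp$X) > 0) paste0("b_sp:", colnames(des_sp$X)),
            if (ncol(des_site$X) > 0) {
              paste0("b_site:", colnames(des_site$X))
            })
        ),
        dda_sp = dda_sp, dda_site = dda_site, DDA = dda, p = p,
        delta = scn$delta, seed = seed, scenario = scn
      )
    ),
    class = "dda_simulation"
  )
}

declared_levels <- function(scn, prefix) {
  n_cat <- if (prefix == "trait") scn$n_cat_traits else scn$n_cat_attrs
  lev <- if (prefix == "trait") scn$cat_levels else scn$attr_cat_levels
  if (n_cat == 0) return(NULL)
  stats::setNames(
    rep(list(paste0("L", seq_len(lev))), n_cat),
    sprintf("%s_c%d", prefix, seq_len(n_cat))
  )
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a scenario, fits the unified model to each replicate
#' (using the replicate's generated suitability matrix as input, or
#' re-estimating it from the binary matrix when `estimate_suit = TRUE`), and
#' records per-coefficient posterior summaries, sign correctness,
#' credible-interval coverage of the truth, dark-affinity classification
#' accuracy, and the absent/present subset comparison. Non-converged fits
#' are kept and flagged, never dropped.
#'
#' @param scn a [dda_scenario()].
#' @param n_replicates number of independent replicates.
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param control a [dda_control()]; the default uses the reduced schedule
#'   (burn-in 2000, thinning 6) that keeps a replicate fit to a few seconds.
#' @param priors a [dda_priors()].
#' @param level credible level for intervals and classification.
#' @param dark_margin half-width of the indifference band around 0.5 within
#'   which a species' true affinity is not scored for classification.
#' @param estimate_suit estimate suitability from each replicate's matrix
#'   instead of using the generated (true) suitability.
#' @return a list of class `dda_recovery` with tibbles `coefficients`
#'   (one row per replicate x coefficient), `subsets` (replicate x quantity),
#'   `classification` (replicate-level accuracy) and `fits_converged`.
#' @export
recovery_experiment <- function(scn, n_replicates = 10, seed = 1L,
                                control = dda_control(burnin = 2000,
                                                      thin = 6),
                                priors = dda_priors(), level = 0.95,
                                dark_margin = 0.1, estimate_suit = FALSE) {
  stopifnot(inherits(scn, "dda_scenario"), n_replicates >= 1)
  reps <- purrr::map(seq_len(n_replicates), function(r) {
    sim <- simulate_metacommunity(scn, seed = seed + r)
    if (estimate_suit) {
      mc_fit <- validate_metacommunity(sim$mc, strict = TRUE)
      suit <- suitability(mc_fit)
    } else {
      mc_fit <- sim$mc
      suit <- sim$suit
    }
    fit <- dda_fit(mc_fit, suit = suit, priors = priors, control = control,
                   seed = seed + r)
    ct <- coefficient_table(fit, level)
    truth <- sim$truth$coefficients[ct$term]
    coef_tbl <- mutate(
      ct,
      replicate = r, truth = unname(truth),
      covered = .data$lower <= .data$truth & .data$truth <= .data$upper,
      sign_correct = sign(.data$mean) == sign(.data$truth) |
        .data$truth == 0,
      converged = fit$diagnostics$converged
    )
    aff <- posterior_affinity(fit, "species", level)
    keep <- abs(sim$truth$dda_sp[aff$species] - 0.5) > dark_margin
    truth_dark <- sim$truth$dda_sp[aff$species] > 0.5
    pred_dark <- aff$median > 0.5
    cls <- tibble(
      replicate = r,
      n_scored = sum(keep),
      accuracy = if (any(keep)) mean(truth_dark[keep] == pred_dark[keep])
                 else NA_real_,
      dark_sensitivity = if (any(keep & truth_dark)) {
        mean(aff$label[keep & truth_dark] == "dark-affine")
      } else NA_real_
    )
    subs <- mutate(compare_subsets(fit), replicate = r)
    list(coef = coef_tbl, cls = cls, subs = subs,
         converged = fit$diagnostics$converged)
  })
  structure(
    list(
      coefficients = bind_rows(purrr::map(reps, "coef")),
      subsets = bind_rows(purrr::map(reps, "subs")),
      classification = bind_rows(purrr::map(reps, "cls")),
      fits_converged = tibble(
        replicate = seq_len(n_replicates),
        converged = purrr::map_lgl(reps, "converged")
      ),
      scenario = scn, seed = seed, level = level
    ),
    class = "dda_recovery"
  )
}

#' @export
print.dda_recovery <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<dda_recovery> %d replicates; coverage %.3f; injected sign-sig %.3f\n",
    max(x$coefficients$replicate), g$coverage, g$injected_sign_rate
  ))
  invisible(x)
}
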