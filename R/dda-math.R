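#' Affinity probability from a design row
#'
#' The species-side and site-side affinity submodels are logit-linear:
#' `logit(dda) = a + x . b`, with `x` a (standardized) design row. A positive
#' coefficient means the trait or attribute increases the probability of the
#' species being absent from suitable sites (or of the site lacking suitable
#' species).
#'
#' @param x design row vector, or a design matrix (entities x columns).
#' @param a intercept.
#' @param b coefficient vector, one per design column.
#' @return probability (or vector of probabilities, one per entity).
#' @export
dda_probability <- function(x, a, b) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(b)) {
    abort(sprintf("design has %d columns but %d coefficients supplied.",
                  ncol(x), length(b)))
  }
  eta <- a + if (length(b) > 0) drop(x %*% b) else rep(0, nrow(x))
  plogis(eta)
}

#' Unify species-side and site-side affinity
#'
#' The cellwise dark diversity affinity is the logit-scale mean of the two
#' components, i.e. the DDA odds are the geometric mean of the species-side
#' and site-side odds.
#'
#' @param dda_sp,dda_site probabilities in (0, 1); values at or beyond the
#'   boundary are clamped to `[eps, 1 - eps]` with a warning.
#' @param eps clamp width.
#' @return the unified affinity, same length as the inputs (recycled).
#' @export
unified_dda <- function(dda_sp, dda_site, eps = 1e-6) {
  if (any(dda_sp <= 0 | dda_sp >= 1 | dda_site <= 0 | dda_site >= 1)) {
    warn("unified_dda: boundary inputs clamped to (eps, 1 - eps).")
    dda_sp <- clamp_unit(dda_sp, eps)
    dda_site <- clamp_unit(dda_site, eps)
  }
  plogis((qlogis(dda_sp) + qlogis(dda_site)) / 2)
}

clamp_unit <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

#' Metacommunity balancing constant
#'
#' The constant `delta`, unique to each metacommunity, balances the predicted
#' presence likelihood to the observed occupancy level:
#' `delta = logit(mean(prab)) - logit(0.5 * mean(suit))`. The factor 0.5 is
#' the affinity threshold: at `DDA = 0.5` everywhere and constant
#' suitability, the predicted presence likelihood then equals the observed
#' prevalence exactly.
#'
#' @param prab binary vector or matrix of observed presences.
#' @param suit suitability values over the same cells.
#' @return scalar delta.
#' @export
delta_constant <- function(prab, suit) {
  mp <- mean(prab)
  ms <- mean(suit)
  if (mp <= 0 || mp >= 1) {
    abort("delta undefined: matrix is all-absent or all-present.")
  }
  if (ms <= 0) abort("delta undefined: mean suitability is zero.")
  qlogis(mp) - qlogis(0.5 * ms)
}

#' Presence likelihood of a species in a site
#'
#' Suitability discounted by affinity and balanced to the metacommunity
#' occupancy level: `logit(p) = logit((1 - DDA) * suit) + delta`. The product
#' is clamped to `[eps, 1 - eps]` before the logit so that boundary
#' suitability values stay finite.
#'
#' @param dda unified affinity per cell, in (0, 1).
#' @param suit suitability per cell, in `[0, 1]`.
#' @param delta balancing constant (see [delta_constant()]).
#' @param eps clamp width, in (0, 0.01).
#' @return presence probability per cell.
#' @export
presence_likelihood <- function(dda, suit, delta, eps = 1e-6) {
  stopifnot(eps > 0, eps < 0.01)
  q <- clamp_unit((1 - dda) * suit, eps)
  plogis(qlogis(q) + delta)
}

#' Normal prior scales for the affinity model
#'
#' All coefficients get independent normal priors with mean 0; the scales are
#' standard deviations — 0.5 for the intercepts `a` (keeping baseline
#' affinity near the 0.5 threshold) and 2.5 for the slopes `b`
#' (weakly-informative shrinkage that also identifies the full one-hot
#' categorical coding).
#'
#' @param a_scale prior sd of the intercepts.
#' @param b_scale prior sd of the slope coefficients.
#' @param mean common prior mean.
#' @return a list of class `dda_priors`.
#' @export
dda_priors <- function(a_scale = 0.5, b_scale = 2.5, mean = 0) {
  stopifnot(a_scale > 0, b_scale > 0)
  structure(list(a_scale = a_scale, b_scale = b_scale, mean = mean),
            class = "dda_priors")
}

# Assemble the model data block used by the log posterior and the sampler.
dda_model_data <- function(prab, suit, design_sp, design_site, delta = NULL,
                           eps = 1e-6) {
  stopifnot(all(dim(prab) == dim(suit)))
  stopifnot(nrow(prab) == nrow(design_sp$X),
            ncol(prab) == nrow(design_site$X))
  list(
    prab = prab, suit = suit,
    prab_vec = as.integer(prab), suit_vec = as.vector(suit),
    X_sp = design_sp$X, X_site = design_site$X,
    delta = delta %||% delta_constant(prab, suit),
    eps = eps
  )
}

#' Log joint density of the species-site unified model
#'
#' Sum of the normal log-priors over all coefficients and the Bernoulli
#' log-likelihood `sum(prab * log(p) + (1 - prab) * log(1 - p))` over all
#' cells, with `p` assembled from the full composition: logit-linear
#' submodels, logit-scale unification, suitability discounting and the
#' data-fixed balancing constant.
#'
#' @param theta named coefficient vector: `a_sp`, `a_site`, then one
#'   `b_sp:<column>` per species design column and one `b_site:<column>` per
#'   site design column.
#' @param data model data block from the internal assembler; a list with
#'   `prab`, `suit`, `X_sp`, `X_site`, `delta`, `eps`.
#' @param priors a [dda_priors()] object.
#' @return scalar log density.
#' @export
dda_log_posterior <- function(theta, data, priors = dda_priors()) {
  k_sp <- ncol(data$X_sp)
  k_site <- ncol(data$X_site)
  stopifnot(length(theta) == 2 + k_sp + k_site)
  a_sp <- theta[1]
  a_site <- theta[2]
  b_sp <- theta[seq_len(k_sp) + 2]
  b_site <- theta[seq_len(k_site) + 2 + k_sp]

  S <- nrow(data$prab)
  N <- ncol(data$prab)
  eta_sp <- rep(a_sp, S) + if (k_sp > 0) drop(data$X_sp %*% b_sp) else 0
  eta_site <- rep(a_site, N) +
    if (k_site > 0) drop(data$X_site %*% b_site) else 0
  ll <- cell_loglik(eta_sp, eta_site,
                    data$suit_vec %||% as.vector(data$suit),
                    data$prab_vec %||% as.integer(data$prab),
                    data$delta, data$eps)
  if (!is.finite(ll)) {
    # locate the offending cell for the error message
    l_dda <- outer(eta_sp, eta_site, `+`) / 2
    q <- clamp_unit((1 - plogis(l_dda)) * data$suit, data$eps)
    p <- plogis(qlogis(q) + data$delta)
    ll_cells <- data$prab * log(p) + (1 - data$prab) * log1p(-p)
    i <- arrayInd(which(!is.finite(ll_cells))[1], dim(ll_cells))
    abort(sprintf("non-finite likelihood at cell (%d, %d).", i[1], i[2]))
  }
  lp <- dnorm(a_sp, priors$mean, priors$a_scale, log = TRUE) +
    dnorm(a_site, priors$mean, priors$a_scale, log = TRUE) +
    sum(dnorm(b_sp, priors$mean, priors$b_scale, log = TRUE)) +
    sum(dnorm(b_site, priors$mean, priors$b_scale, log = TRUE))
  ll + lp
}
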