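#' MCMC control settings for the affinity model
#'
#' Defaults follow the schedule used for component metacommunities: 3 chains,
#' 333 retained samples per chain (999 posterior draws total), burn-in 4000
#' and thinning 12, escalating by doubling up to burn-in 25000 / thinning 75
#' whenever any R-hat exceeds 1.1.
#'
#' @param chains number of chains (>= 2).
#' @param samples retained samples per chain.
#' @param burnin burn-in iterations.
#' @param thin thinning interval.
#' @param max_burnin,max_thin escalation ceilings.
#' @param rhat_max convergence threshold on the Gelman-Rubin statistic.
#' @param eps clamp width for logit arguments, in (0, 0.01).
#' @param shared_intercept use one intercept for both submodels instead of
#'   separate `a_sp` / `a_site` (sensitivity switch).
#' @param adapt_batch proposal-scale adaptation batch length during burn-in.
#' @return a list of class `dda_control`.
#' @export
dda_control <- function(chains = 3, samples = 333, burnin = 4000, thin = 12,
                        max_burnin = 25000, max_thin = 75, rhat_max = 1.1,
                        eps = 1e-6, shared_intercept = FALSE,
                        adapt_batch = 50) {
  stopifnot(chains >= 2, samples >= 1, burnin >= 0, thin >= 1,
            eps > 0, eps < 0.01, rhat_max > 1)
  structure(
    list(chains = chains, samples = samples, burnin = burnin, thin = thin,
         max_burnin = max_burnin, max_thin = max_thin, rhat_max = rhat_max,
         eps = eps, shared_intercept = shared_intercept,
         adapt_batch = adapt_batch),
    class = "dda_control"
  )
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic R-hat for one scalar parameter:
#' `sqrt((((n - 1) / n) * W + B / n) / W)` with `W` the mean within-chain
#' variance and `B` the between-chain variance of chain means times `n`.
#' Values at or below 1.1 are taken as converged.
#'
#' @param chains a numeric matrix (iterations x chains) or a list of
#'   equal-length numeric vectors, at least two chains of length >= 2.
#' @return scalar R-hat.
#' @export
gelman_rubin_rhat <- function(chains) {
  if (is.list(chains)) {
    lens <- lengths(chains)
    if (length(unique(lens)) != 1) abort("chains must have equal lengths.")
    chains <- do.call(cbind, chains)
  }
  n <- nrow(chains)
  m <- ncol(chains)
  if (m < 2 || n < 2) abort("need >= 2 chains of length >= 2.")
  W <- mean(apply(chains, 2, var))
  if (W == 0) abort("degenerate chains: zero within-chain variance.")
  B <- n * var(colMeans(chains))
  sqrt((((n - 1) / n) * W + B / n) / W)
}

# One adaptive random-walk Metropolis chain: a componentwise sweep
# (per-parameter proposal scales tuned Robbins-Monro style towards 0.44
# acceptance) followed by one joint proposal whose covariance is learned
# from the burn-in history (Haario-type, scaled 2.38^2/d), which handles
# ridge-shaped posteriors such as the weakly identified intercept pair.
# All adaptation happens during burn-in only, so the retained draws come
# from a fixed kernel.
run_chain <- function(theta0, log_post, burnin, thin, samples, adapt_batch,
                      seed) {
  withr::with_seed(seed, {
    d <- length(theta0)
    theta <- theta0
    lp <- log_post(theta)
    scales <- rep(0.5, d)
    acc <- numeric(d)
    n_iter <- burnin + samples * thin
    draws <- matrix(NA_real_, samples, d)
    kept <- 0L
    mean_vec <- numeric(d)
    m2 <- matrix(0, d, d)
    n_hist <- 0L
    chol_prop <- NULL
    for (it in seq_len(n_iter)) {
      for (j in seq_len(d)) {
        prop <- theta
        prop[j] <- theta[j] + rnorm(1, 0, scales[j])
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
          acc[j] <- acc[j] + 1
        }
      }
      if (!is.null(chol_prop)) {
        prop <- theta + drop(rnorm(d) %*% chol_prop)
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
        }
      }
      if (it <= burnin) {
        n_hist <- n_hist + 1L
        delta <- theta - mean_vec
        mean_vec <- mean_vec + delta / n_hist
        m2 <- m2 + outer(delta, theta - mean_vec)
        if (it %% adapt_batch == 0) {
          scales <- pmin(pmax(scales * exp(acc / adapt_batch - 0.44),
                              1e-3), 10)
          acc[] <- 0
          if (n_hist > max(20, 2 * d)) {
            cov_prop <- (2.38^2 / d) * m2 / (n_hist - 1) +
              1e-8 * diag(d)
            chol_prop <- tryCatch(chol(cov_prop),
                                  error = function(e) NULL)
          }
        }
      }
      if (it > burnin && (it - burnin) %% thin == 0 && kept < samples) {
        kept <- kept + 1L
        draws[kept, ] <- theta
      }
    }
    colnames(draws) <- names(theta0)
    draws
  })
}

chain_seed <- function(seed, chain, escalation) {
  as.integer((abs(seed) * 1009 + chain * 7919 + escalation * 104729) %%
               .Machine$integer.max)
}

#' Fit the Bayesian species-site unified affinity model
#'
#' Samples the joint posterior of the submodel coefficients (intercepts
#' `a_sp`, `a_site` and slopes `b`) given the presence-absence matrix, the
#' suitability matrix and the trait/attribute design matrices, using
#' componentwise adaptive random-walk Metropolis targeting
#' [dda_log_posterior()]. The balancing constant `delta` is computed once
#' from the data and held fixed. After each run R-hat is computed per
#' coefficient; on failure the burn-in and thinning are doubled (up to the
#' configured ceilings) and the model is refitted. A fixed seed yields
#' identical draws.
#'
#' @param mc a [metacommunity()] object carrying trait and site attribute
#'   tables, or `NULL` if `design_sp`/`design_site` are given directly.
#' @param suit suitability matrix (see [suitability()]); computed from `mc`
#'   with the default dialect when omitted.
#' @param design_sp,design_site optional [build_design()] objects; default to
#'   designs built from `mc$traits` and `mc$sites`, or to intercept-only
#'   designs when the tables are absent.
#' @param priors a [dda_priors()] object.
#' @param control a [dda_control()] object.
#' @param seed integer seed driving all chains.
#' @return an object of class `dda_fit` with elements `draws` (tibble:
#'   `chain`, `draw`, one column per coefficient), `data`, `designs`,
#'   `priors`, `control`, `diagnostics` (R-hat table, schedule used,
#'   escalation count, convergence flag) and `seed`.
#' @export
dda_fit <- function(mc = NULL, suit = NULL, design_sp = NULL,
                    design_site = NULL, priors = dda_priors(),
                    control = dda_control(), seed = 1L) {
  if (!is.null(mc)) {
    stopifnot(inherits(mc, "metacommunity"))
    prab <- mc$prab
    design_sp <- design_sp %||% design_or_null(mc$traits, rownames(prab))
    design_site <- design_site %||% design_or_null(mc$sites, colnames(prab))
    suit <- suit %||% suitability(mc)
  } else {
    abort("`mc` is required.")
  }
  data <- dda_model_data(prab, suit, design_sp, design_site,
                         eps = control$eps)
  k_sp <- ncol(design_sp$X)
  k_site <- ncol(design_site$X)
  par_names <- c("a_sp", "a_site",
                 if (k_sp > 0) paste0("b_sp:", colnames(design_sp$X)),
                 if (k_site > 0) paste0("b_site:", colnames(design_site$X)))

  shared <- isTRUE(control$shared_intercept)
  log_post <- if (shared) {
    function(th) {
      th2 <- c(th[1], th[1], th[-1])
      dda_log_posterior(th2, data, priors) -
        dnorm(th[1], priors$mean, priors$a_scale, log = TRUE)
    }
  } else {
    function(th) dda_log_posterior(th, data, priors)
  }
  d <- length(par_names) - shared

  burnin <- control$burnin
  thin <- control$thin
  escalation <- 0L
  repeat {
    chains <- lapply(seq_len(control$chains), function(ch) {
      init_seed <- chain_seed(seed, ch, escalation)
      theta0 <- withr::with_seed(init_seed, {
        c(rnorm(2 - shared, 0, priors$a_scale * 2),
          rnorm(d - 2 + shared, 0, priors$b_scale))
      })
      names(theta0) <- if (shared) {
        c("a", par_names[-(1:2)])
      } else {
        par_names
      }
      run_chain(theta0, log_post, burnin, thin, control$samples,
                control$adapt_batch, init_seed)
    })
    rhats <- vapply(seq_len(d), function(j) {
      gelman_rubin_rhat(lapply(chains, function(m) m[, j]))
    }, numeric(1))
    names(rhats) <- colnames(chains[[1]])
    converged <- all(rhats <= control$rhat_max)
    if (converged ||
        (burnin >= control$max_burnin && thin >= control$max_thin)) break
    burnin <- min(burnin * 2, control$max_burnin)
    thin <- min(thin * 2, control$max_thin)
    escalation <- escalation + 1L
  }
  if (!converged) {
    warn(sprintf(
      "fit did not converge after %d escalation(s): max R-hat %.3f.",
      escalation, max(rhats)))
  }

  draw_mat <- do.call(rbind, chains)
  if (shared) {
    draw_mat <- cbind(a_sp = draw_mat[, 1], a_site = draw_mat[, 1],
                      draw_mat[, -1, drop = FALSE])
    colnames(draw_mat) <- par_names
  }
  draws <- dplyr::bind_cols(
    tibble(
      chain = rep(seq_len(control$chains), each = control$samples),
      draw = rep(seq_len(control$samples), times = control$chains)
    ),
    as_tibble(as.data.frame(draw_mat))
  )

  structure(
    list(
      draws = draws, par_names = par_names, data = data,
      designs = list(sp = design_sp, site = design_site),
      priors = priors, control = control,
      diagnostics = list(
        rhat = tibble(term = names(rhats), rhat = unname(rhats)),
        burnin = burnin, thin = thin, escalations = escalation,
        converged = converged
      ),
      seed = seed, kind = mc$kind
    ),
    class = "dda_fit"
  )
}

#' @export
print.dda_fit <- function(x, ...) {
  cat(sprintf(
    "<dda_fit> %d species x %d sites, %d coefficients\n",
    nrow(x$data$prab), ncol(x$data$prab), length(x$par_names)
  ))
  cat(sprintf(
    "  %d chains x %d draws (burn-in %d, thin %d), max R-hat %.3f%s\n",
    x$control$chains, x$control$samples, x$diagnostics$burnin,
    x$diagnostics$thin, max(x$diagnostics$rhat$rhat),
    if (x$diagnostics$converged) "" else " [NOT CONVERGED]"
  ))
  cat(sprintf("  delta = %.4f\n", x$data$delta))
  invisible(x)
}
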