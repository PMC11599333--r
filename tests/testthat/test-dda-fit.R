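test_that("Gelman-Rubin statistic follows its closed form", {
  expect_equal(gelman_rubin_rhat(list(c(1, 2, 3, 4), c(1, 2, 3, 4))),
               sqrt(3 / 4), tolerance = 1e-12)
  expect_error(gelman_rubin_rhat(list(c(0, 0, 0), c(1, 1, 1))),
               "degenerate")
  expect_error(gelman_rubin_rhat(list(1:3, 1:4)), "equal lengths")
  # same-distribution chains approach 1; separated chains exceed 1.1
  withr::with_seed(31, {
    same <- matrix(rnorm(4000), 1000, 4)
    apart <- cbind(rnorm(200, 0), rnorm(200, 10))
  })
  expect_lt(abs(gelman_rubin_rhat(same) - 1), 0.05)
  expect_gt(gelman_rubin_rhat(apart), 1.1)
})

test_that("R-hat agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  withr::with_seed(77, {
    for (k in 1:10) {
      ch <- matrix(rnorm(600, sd = runif(1, 0.5, 2)), 200, 3)
      ours <- gelman_rubin_rhat(ch)
      ref <- coda::gelman.diag(
        coda::mcmc.list(apply(ch, 2, coda::mcmc, simplify = FALSE)),
        autoburnin = FALSE, transform = FALSE
      )$psrf[1]
      # coda adds the sampling-variability d/(d-2) factor; both must agree
      # closely for long well-mixed chains
      expect_equal(ours, ref, tolerance = 0.02)
    }
  })
})

test_that("seeded fits are reproducible draw for draw", {
  sim <- simulate_metacommunity(dda_scenario(n_species = 12, n_sites = 10),
                                seed = 5)
  ctl <- dda_control(chains = 2, samples = 30, burnin = 200, thin = 2,
                     max_burnin = 800, max_thin = 8)
  f1 <- dda_fit(sim$mc, suit = sim$suit, control = ctl, seed = 99)
  f2 <- dda_fit(sim$mc, suit = sim$suit, control = ctl, seed = 99)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$diagnostics$rhat, f2$diagnostics$rhat)
  f3 <- dda_fit(sim$mc, suit = sim$suit, control = ctl, seed = 100)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("retained draws respect the chains-by-samples contract", {
  sim <- simulate_metacommunity(dda_scenario(n_species = 10, n_sites = 8),
                                seed = 2)
  ctl <- dda_control(chains = 3, samples = 25, burnin = 300, thin = 3,
                     max_burnin = 1200, max_thin = 12)
  fit <- dda_fit(sim$mc, suit = sim$suit, control = ctl, seed = 11)
  expect_equal(nrow(fit$draws), 3 * 25)
  expect_equal(unname(table(fit$draws$chain)), rep(25L, 3),
               ignore_attr = TRUE)
  # derived posterior probabilities stay strictly inside (0, 1)
  aff_sp <- posterior_affinity(fit, "species")
  aff_site <- posterior_affinity(fit, "site")
  expect_true(all(aff_sp$median > 0 & aff_sp$median < 1))
  expect_true(all(aff_site$median > 0 & aff_site$median < 1))
  cells <- posterior_affinity(fit, "cell")
  expect_true(all(cells$median > 0 & cells$median < 1))
})

test_that("non-convergence is flagged, never silently accepted", {
  sim <- simulate_metacommunity(dda_scenario(n_species = 10, n_sites = 8),
                                seed = 6)
  # a schedule far too short to mix, with no room to escalate
  ctl <- dda_control(chains = 3, samples = 5, burnin = 10, thin = 1,
                     max_burnin = 10, max_thin = 1)
  expect_warning(
    fit <- dda_fit(sim$mc, suit = sim$suit, control = ctl, seed = 8),
    "did not converge"
  )
  expect_false(fit$diagnostics$converged)
  expect_true(any(fit$diagnostics$rhat$rhat > 1.1))
})

test_that("escalation doubles the schedule up to its ceiling", {
  sim <- simulate_metacommunity(dda_scenario(n_species = 10, n_sites = 8),
                                seed = 6)
  ctl <- dda_control(chains = 2, samples = 5, burnin = 10, thin = 1,
                     max_burnin = 40, max_thin = 4)
  fit <- suppressWarnings(
    dda_fit(sim$mc, suit = sim$suit, control = ctl, seed = 8)
  )
  if (!fit$diagnostics$converged) {
    expect_equal(fit$diagnostics$burnin, 40)
    expect_equal(fit$diagnostics$thin, 4)
    expect_gte(fit$diagnostics$escalations, 2)
  } else {
    expect_lte(fit$diagnostics$burnin, 40)
  }
})

test_that("the shared-intercept switch ties the two submodel intercepts", {
  sim <- simulate_metacommunity(dda_scenario(n_species = 10, n_sites = 8),
                                seed = 4)
  ctl <- dda_control(chains = 2, samples = 30, burnin = 200, thin = 1,
                     max_burnin = 800, max_thin = 4,
                     shared_intercept = TRUE)
  fit <- suppressWarnings(dda_fit(sim$mc, suit = sim$suit, control = ctl,
                                  seed = 4))
  expect_identical(fit$draws$a_sp, fit$draws$a_site)
  expect_equal(nrow(fit$draws), 60)
})

test_that("a well-behaved fit converges under the R-hat 1.1 rule", {
  sim <- simulate_metacommunity(
    dda_scenario(n_species = 20, n_sites = 15, n_quant_traits = 1,
                 n_cat_traits = 0, n_quant_attrs = 1, n_cat_attrs = 0,
                 b_sp = 2, b_site = -2),
    seed = 44
  )
  fit <- dda_fit(sim$mc, suit = sim$suit,
                 control = dda_control(chains = 3, samples = 150,
                                       burnin = 1000, thin = 3),
                 seed = 44)
  expect_true(fit$diagnostics$converged)
  expect_true(all(fit$diagnostics$rhat$rhat <= 1.1))
})
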