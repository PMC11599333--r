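test_that("posterior summaries use type-7 quantiles", {
  s <- summarize_draws(1:999)
  expect_equal(s$median, 500)
  expect_equal(s$lower, 25.95, tolerance = 1e-10)
  expect_equal(s$upper, 974.05, tolerance = 1e-10)
  expect_equal(summarize_draws(rep(0.7, 10)),
               tibble::tibble(median = 0.7, lower = 0.7, upper = 0.7))
  expect_equal(summarize_draws(c(0.4, 0.6))$median, 0.5)
  expect_error(summarize_draws(numeric(0)), "no draws")
})

test_that("affinity labels follow the credible-bound rule and are monotone", {
  s <- tibble::tibble(
    median = c(0.8, 0.3, 0.55),
    lower = c(0.6, 0.1, 0.45),
    upper = c(0.95, 0.45, 0.65)
  )
  expect_equal(classify_affinity(s)$label,
               c("dark-affine", "presence-affine", "unresolved"))
  # shifting every draw upward never moves a label towards presence-affine
  withr::with_seed(19, draws <- matrix(runif(500, 0.2, 0.6), 100, 5))
  rank_of <- function(l) {
    match(l, c("presence-affine", "unresolved", "dark-affine"))
  }
  base <- classify_affinity(summarize_draws(draws))$label
  shifted <- classify_affinity(summarize_draws(draws + 0.2))$label
  expect_true(all(rank_of(shifted) >= rank_of(base)))
})

test_that("subset splitting partitions all cells", {
  prab <- matrix(c(1, 0, 0, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  ss <- split_subsets(prab)
  expect_equal(nrow(ss), 4)
  expect_equal(sum(ss$subset == "absent"), 2)
  expect_equal(sum(ss$subset == "present"), 2)
  expect_warning(split_subsets(matrix(1, 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("x", "y")))),
                 "empty")
  withr::with_seed(3, m <- random_prab(6, 5))
  expect_equal(nrow(split_subsets(m)), 30)
})

test_that("Kruskal-Wallis wrapper matches hand computation and references", {
  kt <- kw_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kt$H, 27 / 7, tolerance = 1e-10) # = 3.8571
  expect_equal(kw_test(c(1, 2, 1, 2), c("a", "a", "b", "b"))$H, 0,
               tolerance = 1e-12)
  expect_equal(kw_test(rep(5, 6), rep(c("a", "b"), 3))$H, 0)
  expect_error(kw_test(1:3, rep("a", 3)), "two non-empty groups")

  withr::with_seed(55, {
    for (k in 1:100) {
      n <- sample(6:25, 1)
      g <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
      if (length(unique(g)) < 2) next
      v <- sample(1:6, n, replace = TRUE) # heavy ties
      ours <- kw_test(v, g)
      ref <- hand_kw(v, g)
      expect_equal(ours$H, ref$H, tolerance = 1e-10)
      expect_equal(ours$p_value, ref$p, tolerance = 1e-8)
    }
  })
})

test_that("subset comparison is assembled from the right cell values", {
  sim <- simulate_metacommunity(dda_scenario(n_species = 15, n_sites = 10),
                                seed = 12)
  fit <- dda_fit(sim$mc, suit = sim$suit,
                 control = dda_control(chains = 2, samples = 60,
                                       burnin = 400, thin = 2,
                                       max_burnin = 1600, max_thin = 8),
                 seed = 12)
  cmp <- compare_subsets(fit)
  expect_setequal(cmp$quantity, c("p", "suit", "DDA", "dda_sp", "dda_site"))
  expect_equal(unique(cmp$n_absent + cmp$n_present), 150)
  # suitability rows do not depend on the fitting seed
  fit2 <- dda_fit(sim$mc, suit = sim$suit,
                  control = dda_control(chains = 2, samples = 60,
                                        burnin = 400, thin = 2,
                                        max_burnin = 1600, max_thin = 8),
                  seed = 777)
  cmp2 <- compare_subsets(fit2)
  expect_identical(cmp[cmp$quantity == "suit", ],
                   cmp2[cmp2$quantity == "suit", ])
  # identical inputs give identical output
  expect_identical(cmp, compare_subsets(fit))
  # pooled-draw sensitivity mode keeps the same medians
  pooled <- compare_subsets(fit, pool_draws = TRUE)
  expect_equal(pooled$median_absent, cmp$median_absent)
  expect_gte(pooled$H[pooled$quantity == "DDA"], 0)
})

test_that("constant affinity posteriors give H = 0 for DDA", {
  # a fit whose draws we overwrite with a flat intercept posterior
  sim <- simulate_metacommunity(
    dda_scenario(n_species = 8, n_sites = 6, n_quant_traits = 0,
                 n_cat_traits = 0, n_quant_attrs = 0, n_cat_attrs = 0),
    seed = 9
  )
  fit <- dda_fit(sim$mc, suit = sim$suit,
                 control = dda_control(chains = 2, samples = 20,
                                       burnin = 100, thin = 1,
                                       max_burnin = 400, max_thin = 4),
                 seed = 9)
  fit$draws$a_sp <- 0
  fit$draws$a_site <- 0
  cmp <- compare_subsets(fit)
  expect_equal(cmp$H[cmp$quantity == "DDA"], 0)
  expect_equal(cmp$median_absent[cmp$quantity == "DDA"], 0.5)
})

test_that("coefficient significance flags follow the credible interval", {
  sim <- simulate_metacommunity(
    dda_scenario(n_species = 30, n_sites = 20, n_quant_traits = 1,
                 n_cat_traits = 0, n_quant_attrs = 1, n_cat_attrs = 0,
                 b_sp = 3, b_site = 0),
    seed = 27
  )
  fit <- dda_fit(sim$mc, suit = sim$suit,
                 control = dda_control(chains = 3, samples = 150,
                                       burnin = 1000, thin = 3),
                 seed = 27)
  ct <- coefficient_table(fit)
  strong <- ct[ct$term == "b_sp:trait_q1", ]
  expect_true(strong$significant)
  expect_gt(strong$mean, 0)
  expect_equal(ct$significant, ct$lower > 0 | ct$upper < 0)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_affinity(posterior_affinity(fit, "species")),
                  "ggplot")
})
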