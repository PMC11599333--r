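test_that("selection thresholds apply the examined-hosts boundary exactly", {
  records <- tibble::tibble(
    site = c("r1", "r1", "r2", "r2", "r3"),
    host = c("h1", "h2", "h1", "h1", "h1"),
    n_examined = c(20, 14, 15, 20, 16),
    species = c("f1", "f2", "f1", "f2", "f2")
  )
  mc <- apply_selection_thresholds(records, min_examined = 15)
  # the 14-examined record is dropped, so f2 loses its r1 occurrence
  expect_equal(sort(rownames(mc$prab)), c("f1", "f2"))
  expect_equal(mc$prab["f2", "r1"], 0L)
  expect_equal(mc$prab["f1", "r2"], 1L) # exactly 15 examined is retained

  mc2 <- apply_selection_thresholds(records, min_examined = 15,
                                    min_sites_per_species = 2)
  expect_true(all(rowSums(mc2$prab) >= 2))
  expect_error(
    apply_selection_thresholds(records, min_examined = 100),
    "no occurrences left"
  )
})

test_that("occupancy thresholds retain species at the boundary", {
  # a species present in exactly 12 sites passes a min-sites threshold of 12
  records <- tibble::tibble(
    site = paste0("r", 1:12), host = "h", n_examined = 15, species = "m1"
  )
  mc <- apply_selection_thresholds(records, min_sites_per_species = 12)
  expect_equal(unname(rowSums(mc$prab)["m1"]), 12)
  expect_error(
    apply_selection_thresholds(records, min_sites_per_species = 13),
    "no occurrences"
  )
})

test_that("standardization hits mean 0 / sd 0.5 and is idempotent", {
  expect_equal(standardize_half_sd(c(1, 2, 3)), c(-0.5, 0, 0.5))
  expect_equal(standardize_half_sd(c(10, 20)),
               c(-0.3535534, 0.3535534), tolerance = 1e-6)
  expect_error(standardize_half_sd(c(4, 4, 4)), "constant")
  withr::with_seed(5, x <- rexp(50))
  z <- standardize_half_sd(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 0.5, tolerance = 1e-12)
  expect_equal(standardize_half_sd(z), z, tolerance = 1e-12)
})

test_that("first-PC scores align positively and ignore per-variable scale", {
  withr::with_seed(8, {
    base <- rnorm(30)
    block <- data.frame(v1 = base + rnorm(30, sd = 0.1),
                        v2 = base + rnorm(30, sd = 0.1))
  })
  sc <- first_pc_scores(block)
  expect_true(all(cor(sc, block) > 0.9))
  # duplicated variable: scores proportional to the standardized variable
  dup <- data.frame(a = base, b = base)
  sc_dup <- first_pc_scores(dup)
  expect_equal(cor(sc_dup, base), 1, tolerance = 1e-10)
  # single variable: exactly the standardized variable
  expect_equal(first_pc_scores(data.frame(a = base)),
               as.vector(scale(base)), tolerance = 1e-10)
  # invariance to affine rescaling of the block columns
  resc <- data.frame(v1 = 100 * block$v1 - 7, v2 = -0.01 * block$v2 + 2)
  expect_equal(abs(first_pc_scores(resc)), abs(sc), tolerance = 1e-10)
  # sign alignment: flipping all variables flips the scores back positive
  neg <- -block
  expect_true(sum(cor(first_pc_scores(neg), neg)) > 0)
  expect_error(first_pc_scores(data.frame(a = rep(1, 5))), "constant")
})

test_that("design matrices standardize, one-hot encode, and keep all levels", {
  tbl <- tibble::tibble(
    species = paste0("s", 1:10),
    ab = 1:10, bs = c(2, 4, 1, 7, 3, 8, 6, 9, 5, 10),
    combs = rep(c("none", "one", "two"), length.out = 10)
  )
  d <- build_design(tbl, levels = list(combs = c("none", "one", "two")))
  expect_equal(ncol(d$X), 5) # 2 quantitative + 3 indicator columns
  expect_equal(colMeans(d$X[, 1:2]), c(ab = 0, bs = 0), tolerance = 1e-10)
  expect_equal(apply(d$X[, 1:2], 2, sd), c(ab = 0.5, bs = 0.5),
               tolerance = 1e-10)
  ind <- d$X[, grepl("combs", colnames(d$X))]
  expect_equal(unname(rowSums(ind)), rep(1, 10)) # one-hot partition
  expect_equal(unname(ind[2, ]), c(0, 1, 0)) # species 2 has one comb

  expect_error(build_design(tbl, levels = list(combs = c("none", "one"))),
               "undeclared level")
  expect_warning(
    d2 <- build_design(dplyr::mutate(tbl, const = 5)),
    "constant predictor"
  )
  expect_false("const" %in% colnames(d2$X))
})
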