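# Independent oracles used to cross-check the package implementations.
# These are deliberately naive (enumeration / direct loops / textbook
# formulas) and share no code with the package internals.

# Hypergeometric co-occurrence moments by exhaustive enumeration: fix the
# n_i sites of species i, enumerate every placement of species j's n_j
# occurrences over the N sites, and take moments of the shared-site count.
enum_cooc_moments <- function(n_i, n_j, N) {
  sets_j <- utils::combn(N, n_j, simplify = FALSE)
  occ_i <- seq_len(n_i)
  cooc <- vapply(sets_j, function(s) length(intersect(s, occ_i)), numeric(1))
  m <- mean(cooc)
  list(mean = m, var = mean((cooc - m)^2))
}

# Brute-force pairwise SES matrix via enumeration moments.
brute_ses <- function(prab) {
  S <- nrow(prab)
  N <- ncol(prab)
  n <- rowSums(prab)
  out <- matrix(0, S, S, dimnames = list(rownames(prab), rownames(prab)))
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      mom <- enum_cooc_moments(n[i], n[j], N)
      if (mom$var > 0) {
        C <- sum(prab[i, ] == 1 & prab[j, ] == 1)
        out[i, j] <- (C - mom$mean) / sqrt(mom$var)
      }
    }
  }
  out
}

# Brute-force cellwise suitability: direct double loop over cells and
# co-occurring species, then the configured monotone rescaling.
brute_suitability <- function(prab, dialect = "minmax") {
  ses <- brute_ses(prab)
  S <- nrow(prab)
  N <- ncol(prab)
  raw <- matrix(0, S, N, dimnames = dimnames(prab))
  for (i in seq_len(S)) {
    for (s in seq_len(N)) {
      vals <- c()
      for (j in seq_len(S)) {
        if (j != i && prab[j, s] == 1) vals <- c(vals, ses[i, j])
      }
      raw[i, s] <- if (length(vals) > 0) mean(vals) else 0
    }
  }
  if (dialect == "minmax") {
    rng <- range(raw)
    if (rng[1] == rng[2]) matrix(0.5, S, N) else (raw - rng[1]) / diff(rng)
  } else {
    pnorm(raw)
  }
}

# Textbook tie-corrected Kruskal-Wallis H and chi-squared p-value.
hand_kw <- function(values, groups) {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / corr
  list(H = H, p = pchisq(H, nlevels(groups) - 1, lower.tail = FALSE))
}

# Independent pure-R assembly of the model's log joint density, written
# directly from the displayed composition (logit-scale mean, clamped
# product, balancing constant, Bernoulli cells, normal priors).
ref_log_posterior <- function(theta, prab, suit, X_sp, X_site, delta,
                              a_scale = 0.5, b_scale = 2.5, eps = 1e-6) {
  k_sp <- ncol(X_sp)
  k_site <- ncol(X_site)
  a_sp <- theta[1]
  a_site <- theta[2]
  b_sp <- theta[seq_len(k_sp) + 2]
  b_site <- theta[seq_len(k_site) + 2 + k_sp]
  ll <- 0
  for (i in seq_len(nrow(prab))) {
    for (s in seq_len(ncol(prab))) {
      l_sp <- a_sp + sum(X_sp[i, ] * b_sp)
      l_site <- a_site + sum(X_site[s, ] * b_site)
      dda <- plogis((l_sp + l_site) / 2)
      q <- min(max((1 - dda) * suit[i, s], eps), 1 - eps)
      p <- plogis(qlogis(q) + delta)
      ll <- ll + if (prab[i, s] == 1) log(p) else log(1 - p)
    }
  }
  ll + sum(dnorm(c(a_sp, a_site), 0, a_scale, log = TRUE)) +
    sum(dnorm(c(b_sp, b_site), 0, b_scale, log = TRUE))
}

# Deterministic grid integration of the intercept-only posterior. The
# likelihood depends on the intercepts only through u = (a_sp + a_site) / 2,
# so it is tabulated on the u grid and combined with the two normal priors;
# marginal posterior medians come from the normalized grid CDF.
grid_intercept_medians <- function(prab, suit, delta, a_scale = 0.5,
                                   eps = 1e-6, lim = 3, step = 0.005) {
  g <- seq(-lim, lim, by = step)
  loglik_u <- vapply(g, function(u) {
    dda <- plogis(u)
    q <- pmin(pmax((1 - dda) * suit, eps), 1 - eps)
    p <- plogis(qlogis(q) + delta)
    sum(prab * log(p) + (1 - prab) * log(1 - p))
  }, numeric(1))
  # joint over (a_sp, a_site) on the grid; u index of (i, j) is (i + j) / 2,
  # which lies on the half-step grid covered by interpolation
  lu <- stats::approxfun(g, loglik_u, rule = 2)
  lp1 <- dnorm(g, 0, a_scale, log = TRUE)
  joint <- outer(lp1, lp1, `+`) + outer(g, g, function(x, y) lu((x + y) / 2))
  joint <- exp(joint - max(joint))
  marg1 <- rowSums(joint)
  cdf <- cumsum(marg1) / sum(marg1)
  med1 <- g[which(cdf >= 0.5)[1]]
  marg2 <- colSums(joint)
  cdf2 <- cumsum(marg2) / sum(marg2)
  med2 <- g[which(cdf2 >= 0.5)[1]]
  c(a_sp = med1, a_site = med2)
}

# A random binary matrix guaranteed to have no all-zero / all-one rows or
# columns (resampled until valid).
random_prab <- function(S, N, fill = 0.4) {
  repeat {
    m <- matrix(rbinom(S * N, 1, fill), S, N,
                dimnames = list(sprintf("sp%02d", seq_len(S)),
                                sprintf("st%02d", seq_len(N))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0) &&
        any(m == 0)) {
      return(m)
    }
  }
}
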