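#' Pairwise co-occurrence standardized effect sizes
#'
#' For each species pair, compares the observed number of shared sites with
#' the expectation under random, independent placement of the two species'
#' occurrences across the N sites. Under that null the shared-site count
#' follows a hypergeometric distribution with mean `n_i * n_j / N` and
#' variance `n_i * n_j * (N - n_i) * (N - n_j) / (N^2 * (N - 1))`; the
#' standardized effect size (SES) is the departure of the observed
#' co-occurrence from the mean in units of the null standard deviation. Pairs
#' with zero null variance (a species occupying no or all sites) get SES 0.
#'
#' @param m a [metacommunity()] object or binary species-by-site matrix.
#' @return a symmetric species-by-species SES matrix with attributes
#'   `occupancy` (per-species occupied-site counts) and `n_sites`.
#' @export
cooccurrence_ses <- function(m) {
  prab <- if (inherits(m, "metacommunity")) m$prab else m
  N <- ncol(prab)
  if (N < 2) abort("need at least two sites for co-occurrence SES.")
  n <- rowSums(prab)
  C <- tcrossprod(prab) # observed shared-site counts
  mu <- outer(n, n) / N
  v <- outer(n, n) * outer(N - n, N - n) / (N^2 * (N - 1))
  ses <- matrix(0, nrow(prab), nrow(prab),
                dimnames = list(rownames(prab), rownames(prab)))
  pos <- v > 0
  ses[pos] <- (C[pos] - mu[pos]) / sqrt(v[pos])
  attr(ses, "occupancy") <- n
  attr(ses, "n_sites") <- N
  ses
}

#' Cellwise ecological suitability from co-occurrence
#'
#' Scores the ecological suitability of every site for every species,
#' independently of whether the species is present there. The raw score of
#' species i at site s is the unweighted mean SES of i against the other
#' species present at s (0 when no other species is present). Raw scores are
#' mapped into the unit interval by a monotone dialect:
#' \describe{
#'   \item{`"minmax"`}{per-metacommunity min-max rescaling (default;
#'     guarantees the full 0-1 range is used),}
#'   \item{`"normcdf"`}{the standard-normal CDF of the raw score (an empty
#'     average then maps to 0.5).}
#' }
#' Both dialects preserve the rank order of cells.
#'
#' @param m a [metacommunity()] object or binary matrix.
#' @param ses optional precomputed [cooccurrence_ses()] matrix.
#' @param dialect rescaling dialect, `"minmax"` or `"normcdf"`.
#' @return a numeric species-by-site matrix in `[0, 1]` with attribute
#'   `raw` holding the unscaled scores.
#' @export
suitability <- function(m, ses = NULL, dialect = c("minmax", "normcdf")) {
  dialect <- match.arg(dialect)
  prab <- if (inherits(m, "metacommunity")) m$prab else m
  if (any(rowSums(prab) == 0)) {
    abort(paste("matrix has never-observed species; run",
                "validate_metacommunity(strict = TRUE) first."))
  }
  ses <- ses %||% cooccurrence_ses(prab)
  ses0 <- ses
  diag(ses0) <- 0 # self-indication excluded
  num <- ses0 %*% prab
  cnt <- matrix(colSums(prab), nrow = nrow(prab), ncol = ncol(prab),
                byrow = TRUE) - prab
  raw <- matrix(0, nrow(prab), ncol(prab), dimnames = dimnames(prab))
  ok <- cnt > 0
  raw[ok] <- num[ok] / cnt[ok]
  suit <- switch(dialect,
    minmax = {
      rng <- range(raw)
      if (rng[1] == rng[2]) {
        matrix(0.5, nrow(raw), ncol(raw), dimnames = dimnames(raw))
      } else {
        (raw - rng[1]) / (rng[2] - rng[1])
      }
    },
    normcdf = pnorm(raw)
  )
  attr(suit, "raw") <- raw
  attr(suit, "dialect") <- dialect
  suit
}

#' Long-format view of a species-by-site matrix
#'
#' @param x a matrix with species row names and site column names (e.g. a
#'   suitability matrix or `prab`).
#' @param value name for the value column.
#' @return a tibble with columns `species`, `site`, and the value.
#' @export
cells_tbl <- function(x, value = "value") {
  out <- tibble(
    species = rep(rownames(x), times = ncol(x)),
    site = rep(colnames(x), each = nrow(x)),
    v = as.vector(x)
  )
  names(out)[3] <- value
  out
}
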