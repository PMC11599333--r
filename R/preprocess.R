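#' Build a presence-absence matrix from sampling records
#'
#' Survey records list, per site and host, how many host individuals were
#' parasitologically examined and which parasite species were observed.
#' Records with too few examined hosts are dropped first (small samples
#' underestimate presences because parasites are aggregated among host
#' individuals), then species occupying too few sites and sites holding too
#' few species are dropped, in that order.
#'
#' @param records a data frame with columns `site`, `host`, `n_examined` and
#'   `species` (one row per parasite observation; `species = NA` marks an
#'   examined record with no parasites, which still counts towards site
#'   retention of the record but contributes no presence).
#' @param min_examined minimum examined host individuals per record
#'   (default 15).
#' @param min_sites_per_species minimum occupied sites for a species to be
#'   retained.
#' @param min_species_per_site minimum retained species for a site to be
#'   retained.
#' @param kind passed to [metacommunity()].
#' @return a [metacommunity()] object (without trait/attribute tables).
#' @export
apply_selection_thresholds <- function(records, min_examined = 15,
                                       min_sites_per_species = 1,
                                       min_species_per_site = 1,
                                       kind = c("component", "compound")) {
  stopifnot(all(c("site", "host", "n_examined", "species") %in%
                  names(records)))
  stopifnot(min_examined >= 1, min_sites_per_species >= 1,
            min_species_per_site >= 1)
  records <- as_tibble(records)
  n0 <- nrow(records)
  kept <- filter(records, .data$n_examined >= min_examined)
  occ <- kept %>%
    filter(!is.na(.data$species)) %>%
    distinct(.data$species, .data$site)
  counts <- c(records = n0, examined_ok = nrow(kept),
              occurrences = nrow(occ))
  if (nrow(occ) == 0) {
    abort(paste0("no occurrences left after filtering (",
                 paste(names(counts), counts, sep = "=", collapse = ", "),
                 ")."))
  }
  sp_keep <- occ %>% group_by(.data$species) %>%
    summarise(n = dplyr::n_distinct(.data$site)) %>%
    filter(.data$n >= min_sites_per_species) %>% pull(.data$species)
  occ <- filter(occ, .data$species %in% sp_keep)
  st_keep <- occ %>% group_by(.data$site) %>%
    summarise(n = dplyr::n_distinct(.data$species)) %>%
    filter(.data$n >= min_species_per_site) %>% pull(.data$site)
  occ <- filter(occ, .data$site %in% st_keep)
  if (nrow(occ) == 0) {
    abort(paste0("no occurrences left after occupancy thresholds (",
                 paste(names(counts), counts, sep = "=", collapse = ", "),
                 ")."))
  }
  species <- sort(unique(occ$species))
  sites <- sort(unique(occ$site))
  prab <- matrix(0L, length(species), length(sites),
                 dimnames = list(species, sites))
  prab[cbind(match(occ$species, species), match(occ$site, sites))] <- 1L
  metacommunity(prab, kind = match.arg(kind))
}

#' Standardize a quantitative predictor to mean 0, sd 0.5
#'
#' All quantitative predictors entering the affinity submodels are centred
#' and scaled to a sample standard deviation of 0.5, which puts them on a
#' scale comparable with binary indicator columns and matches the default
#' weakly-informative prior scales.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return numeric vector with mean 0 and sample sd 0.5.
#' @export
standardize_half_sd <- function(x) {
  if (length(x) < 2) abort("need at least two values to standardize.")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("constant predictor cannot be standardized (zero variance).")
  }
  (x - mean(x)) / s * 0.5
}

#' First principal component scores of a variable block
#'
#' Summarises a block of related quantitative variables (e.g. mean, maximal
#' and minimal air temperature) by the scores of the first principal
#' component of their correlation matrix. The sign is chosen so that the
#' scores correlate positively with the block variables (the sum of
#' score-variable correlations is positive).
#'
#' @param block a data frame or matrix of quantitative variables (entities in
#'   rows).
#' @return numeric vector of first-PC scores, one per entity.
#' @export
first_pc_scores <- function(block) {
  block <- as.matrix(block)
  if (nrow(block) < 2) abort("need at least two entities for PCA.")
  sds <- apply(block, 2, sd)
  if (all(sds == 0)) abort("constant block cannot be summarised by PCA.")
  if (any(sds == 0)) {
    warn("dropping constant columns from PCA block.")
    block <- block[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(block, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  if (sum(cor(scores, block)) < 0) scores <- -scores
  unname(scores)
}

#' Build a design matrix from a trait or attribute table
#'
#' Quantitative columns are standardized to mean 0 and sd 0.5 (constant
#' columns are dropped with a warning); each categorical column with L
#' declared levels contributes L indicator columns — no reference level is
#' dropped, identifiability being supplied by the shrinkage priors, so every
#' level carries its own deviation-from-intercept coefficient.
#'
#' @param tbl data frame; first column is the entity label, remaining columns
#'   are numeric (quantitative) or character/factor (categorical).
#' @param levels optional named list declaring the level set of each
#'   categorical column; observed levels outside the declaration are a schema
#'   error. Defaults to the sorted observed levels.
#' @return an object of class `dda_design`: list with `ids`, numeric matrix
#'   `X` (entities x columns) and a `columns` tibble describing each column
#'   (source variable, type, level).
#' @export
build_design <- function(tbl, levels = NULL) {
  tbl <- as_tibble(tbl)
  if (ncol(tbl) < 2) abort("design table needs an id column plus predictors.")
  ids <- as.character(tbl[[1]])
  cols <- list()
  desc <- list()
  for (nm in names(tbl)[-1]) {
    v <- tbl[[nm]]
    if (is.numeric(v)) {
      if (sd(v) == 0) {
        warn(sprintf("dropping constant predictor '%s'.", nm))
        next
      }
      cols[[nm]] <- standardize_half_sd(v)
      desc[[nm]] <- tibble(column = nm, source = nm,
                           type = "quantitative", level = NA_character_)
    } else {
      v <- as.character(v)
      lv <- levels[[nm]] %||% sort(unique(v))
      extra <- setdiff(unique(v), lv)
      if (length(extra) > 0) {
        abort(sprintf("undeclared level(s) for '%s': %s", nm,
                      paste(extra, collapse = ", ")))
      }
      for (k in seq_along(lv)) {
        cn <- sprintf("%s[%d]", nm, k)
        cols[[cn]] <- as.numeric(v == lv[k])
        desc[[cn]] <- tibble(column = cn, source = nm,
                             type = "categorical", level = lv[k])
      }
    }
  }
  if (length(cols) == 0) abort("no usable predictors in design table.")
  X <- do.call(cbind, cols)
  rownames(X) <- ids
  structure(
    list(ids = ids, X = X, columns = bind_rows(desc)),
    class = "dda_design"
  )
}

#' Intercept-only design (no predictors)
#'
#' @param ids entity labels.
#' @return a `dda_design` whose matrix has zero columns; the corresponding
#'   affinity submodel reduces to its intercept.
#' @export
null_design <- function(ids) {
  X <- matrix(numeric(0), nrow = length(ids), ncol = 0,
              dimnames = list(ids, NULL))
  structure(
    list(ids = ids, X = X,
         columns = tibble(column = character(), source = character(),
                          type = character(), level = character())),
    class = "dda_design"
  )
}

# Design from a table, or intercept-only when the table is absent or has no
# predictor columns.
design_or_null <- function(tbl, ids, levels = NULL) {
  if (is.null(tbl) || ncol(tbl) < 2) null_design(ids)
  else build_design(tbl, levels = levels)
}

#' @export
print.dda_design <- function(x, ...) {
  cat(sprintf("<dda_design> %d entities x %d columns\n",
              nrow(x$X), ncol(x$X)))
  print(x$columns)
  invisible(x)
}

#' @export
as_tibble.dda_design <- function(x, ...) {
  bind_cols_safe <- as_tibble(as.data.frame(x$X))
  dplyr::bind_cols(tibble(id = x$ids), bind_cols_safe)
}
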