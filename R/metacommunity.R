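#' Construct a metacommunity object
#'
#' A metacommunity bundles a binary species-by-site presence-absence matrix
#' (`prab`) with an optional species trait table and an optional site
#' attribute table. Sites are regions when parasite assemblages of one host
#' are compared across regions (a component metacommunity) or host species
#' when assemblages are compared within one region (a compound
#' metacommunity).
#'
#' @param prab a binary matrix (species in rows, sites in columns) with row
#'   and column names, or a data frame whose first column holds species
#'   labels and remaining columns hold 0/1 occupancy per site.
#' @param traits optional data frame of species traits; first column must be
#'   the species label and must cover every species in `prab`.
#' @param sites optional data frame of site attributes; first column must be
#'   the site label and must cover every site in `prab`.
#' @param kind `"component"` (sites are regions) or `"compound"` (sites are
#'   host species). Purely descriptive; it does not change any computation.
#'
#' @return an object of class `metacommunity`: a list with elements `prab`
#'   (integer matrix), `traits`, `sites` (tibbles or `NULL`) and `kind`.
#' @export
metacommunity <- function(prab, traits = NULL, sites = NULL,
                          kind = c("component", "compound")) {
  kind <- match.arg(kind)
  if (is.data.frame(prab)) {
    labs <- as.character(prab[[1]])
    m <- as.matrix(prab[, -1, drop = FALSE])
    rownames(m) <- labs
    prab <- m
  }
  if (!is.matrix(prab)) abort("`prab` must be a matrix or data frame.")
  mode(prab) <- "numeric"
  bad <- which(!(prab %in% c(0, 1)) | is.na(prab))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(prab))
    abort(sprintf(
      "`prab` must be binary: cell (%s, %s) has value %s.",
      rownames(prab)[i[1]] %||% i[1], colnames(prab)[i[2]] %||% i[2],
      prab[bad[1]]
    ))
  }
  storage.mode(prab) <- "integer"
  if (is.null(rownames(prab)) || is.null(colnames(prab))) {
    abort("`prab` must carry species row names and site column names.")
  }
  if (anyDuplicated(rownames(prab))) abort("duplicate species labels in `prab`.")
  if (anyDuplicated(colnames(prab))) abort("duplicate site labels in `prab`.")

  traits <- align_entity_table(traits, rownames(prab), "species", "traits")
  sites <- align_entity_table(sites, colnames(prab), "site", "sites")

  structure(
    list(prab = prab, traits = traits, sites = sites, kind = kind),
    class = "metacommunity"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Align a trait/attribute table to the canonical entity order of the matrix;
# error if any entity is missing or any value is NA.
align_entity_table <- function(tbl, ids, entity, what) {
  if (is.null(tbl)) return(NULL)
  tbl <- as_tibble(tbl)
  labs <- as.character(tbl[[1]])
  missing_ids <- setdiff(ids, labs)
  if (length(missing_ids) > 0) {
    abort(sprintf(
      "%s table is missing %s: %s", what, entity,
      paste(missing_ids, collapse = ", ")
    ))
  }
  tbl <- tbl[match(ids, labs), , drop = FALSE]
  if (anyNA(tbl)) {
    abort(sprintf("%s table contains missing values.", what))
  }
  tbl
}

#' @export
print.metacommunity <- function(x, ...) {
  cat(sprintf(
    "<metacommunity (%s)> %d species x %d sites, fill %.3f\n",
    x$kind, nrow(x$prab), ncol(x$prab), mean(x$prab)
  ))
  if (!is.null(x$traits)) {
    cat(sprintf("  traits: %s\n", paste(names(x$traits)[-1], collapse = ", ")))
  }
  if (!is.null(x$sites)) {
    cat(sprintf("  sites:  %s\n", paste(names(x$sites)[-1], collapse = ", ")))
  }
  invisible(x)
}

#' Read a metacommunity from delimited files
#'
#' Files are comma-separated UTF-8 with a mandatory header row and the entity
#' label in the first column. The row and column order of the matrix file
#' defines the canonical species and site order used by every downstream
#' stage.
#'
#' @param matrix_path path to the presence-absence matrix CSV.
#' @param traits_path,sites_path optional paths to the species trait and site
#'   attribute CSVs.
#' @inheritParams metacommunity
#' @return a [metacommunity()] object.
#' @export
read_metacommunity <- function(matrix_path, traits_path = NULL,
                               sites_path = NULL,
                               kind = c("component", "compound")) {
  read1 <- function(p) readr::read_csv(p, show_col_types = FALSE,
                                       progress = FALSE)
  m <- read1(matrix_path)
  traits <- if (!is.null(traits_path)) read1(traits_path)
  sites <- if (!is.null(sites_path)) read1(sites_path)
  metacommunity(m, traits = traits, sites = sites, kind = match.arg(kind))
}

#' Write a metacommunity to delimited files
#'
#' Inverse of [read_metacommunity()]; tables round-trip to full stored
#' precision.
#'
#' @param mc a [metacommunity()] object.
#' @param dir output directory (created if absent).
#' @return invisibly, a tibble manifest of the files written.
#' @export
write_metacommunity <- function(mc, dir) {
  stopifnot(inherits(mc, "metacommunity"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  mt <- as_tibble(as.data.frame(mc$prab), rownames = "species")
  readr::write_csv(mt, file.path(dir, "prab.csv"))
  paths <- c(paths, "prab.csv")
  if (!is.null(mc$traits)) {
    readr::write_csv(mc$traits, file.path(dir, "traits.csv"))
    paths <- c(paths, "traits.csv")
  }
  if (!is.null(mc$sites)) {
    readr::write_csv(mc$sites, file.path(dir, "sites.csv"))
    paths <- c(paths, "sites.csv")
  }
  invisible(tibble(file = paths, path = file.path(dir, paths)))
}

#' Validate a metacommunity matrix
#'
#' Reports per-species prevalence, per-site richness, all-zero rows/columns
#' and degenerate (no absence / no presence) matrices. With `strict = TRUE`
#' all-zero species and sites are removed (a never-observed species has no
#' co-occurrence information and undefined hypergeometric moments) and the
#' removals are messaged.
#'
#' @param mc a [metacommunity()] object.
#' @param strict drop all-zero species/sites instead of only reporting them.
#' @return with `strict = FALSE`, a list of class `mc_validation` with
#'   tibbles `species`, `sites` and `flags`; with `strict = TRUE`, the pruned
#'   metacommunity with the validation report attached as attribute
#'   `"validation"`.
#' @export
validate_metacommunity <- function(mc, strict = FALSE) {
  stopifnot(inherits(mc, "metacommunity"))
  prab <- mc$prab
  sp <- tibble(
    species = rownames(prab),
    n_sites = unname(rowSums(prab)),
    prevalence = unname(rowMeans(prab)),
    all_zero = unname(rowSums(prab) == 0)
  )
  st <- tibble(
    site = colnames(prab),
    richness = unname(colSums(prab)),
    fill = unname(colMeans(prab)),
    all_zero = unname(colSums(prab) == 0)
  )
  flags <- tibble(
    flag = c("all_zero_species", "all_zero_sites", "no_absences",
             "no_presences"),
    value = c(sum(sp$all_zero), sum(st$all_zero),
              all(prab == 1), all(prab == 0))
  )
  report <- structure(list(species = sp, sites = st, flags = flags),
                      class = "mc_validation")
  if (!strict) return(report)

  keep_sp <- !sp$all_zero
  keep_st <- !st$all_zero
  if (!any(keep_sp) || !any(keep_st)) {
    abort("strict validation removed every species or site (empty dataset).")
  }
  if (!all(keep_sp)) {
    inform(sprintf("dropping %d all-zero species: %s", sum(!keep_sp),
                   paste(sp$species[!keep_sp], collapse = ", ")))
  }
  if (!all(keep_st)) {
    inform(sprintf("dropping %d all-zero sites: %s", sum(!keep_st),
                   paste(st$site[!keep_st], collapse = ", ")))
  }
  out <- metacommunity(
    prab[keep_sp, keep_st, drop = FALSE],
    traits = if (!is.null(mc$traits)) mc$traits[keep_sp, , drop = FALSE],
    sites = if (!is.null(mc$sites)) mc$sites[keep_st, , drop = FALSE],
    kind = mc$kind
  )
  attr(out, "validation") <- report
  out
}

#' @export
print.mc_validation <- function(x, ...) {
  cat("<metacommunity validation>\n")
  print(x$flags)
  invisible(x)
}
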