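#' Assemble a study dataset of georeferenced SSR genotypes
#'
#' The central container of the package: multilocus codominant genotypes for
#' adults and seedlings sampled in plots nested within landscape sites, plus
#' a site table carrying the landscape covariate (percent forest cover in a
#' 2-km buffer around the site centroid).
#'
#' @param loci named list; one element per locus, an integer vector of legal
#'   allele labels (nominally fragment sizes in bp). Names must be unique.
#' @param individuals data.frame with columns `id` (unique), `site_id`,
#'   `stage` (`"adult"` or `"seedling"`), `x`, `y` (planar metres).
#' @param genotypes integer matrix, one row per individual (same order as
#'   `individuals`), two columns per locus named `"<locus>.a1"`,
#'   `"<locus>.a2"`. A missing locus call has `NA` in both columns; a
#'   half-missing call is invalid.
#' @param sites data.frame with columns `site_id` (unique), `centroid_x`,
#'   `centroid_y` (metres), `forest_cover` (percent, in \[0, 100\]).
#'   May be `NULL`, in which case placeholder site records with `NA`
#'   centroids and cover are synthesised from the individuals.
#'
#' @return An object of class `study_dataset`: a list with elements
#'   `loci`, `individuals`, `genotypes`, `sites`.
#' @export
study_dataset <- function(loci, individuals, genotypes, sites = NULL) {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (is.null(sites)) {
    sites <- data.frame(site_id = unique(individuals$site_id),
                        centroid_x = NA_real_, centroid_y = NA_real_,
                        forest_cover = NA_real_,
                        stringsAsFactors = FALSE)
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  rownames(genotypes) <- individuals$id
  ds <- structure(list(loci = loci, individuals = individuals,
                       genotypes = genotypes, sites = sites),
                  class = "study_dataset")
  validate_study_dataset(ds)
  ds
}

#' Validate a study dataset
#'
#' Checks the structural invariants: unique individual and site ids, resolved
#' site membership, finite coordinates, atomic locus calls (both alleles
#' present or both missing), allele labels contained in their locus
#' definition, bounded forest cover, and distinct site centroids.
#'
#' @param ds a `study_dataset`.
#' @return `ds`, invisibly. Throws an error on the first violated invariant.
#' @export
validate_study_dataset <- function(ds) {
  stopifnot(inherits(ds, "study_dataset"))
  ind <- ds$individuals
  if (anyDuplicated(ind$id))
    stop("duplicate individual id: ", ind$id[duplicated(ind$id)][1])
  if (anyDuplicated(ds$sites$site_id))
    stop("duplicate site_id: ", ds$sites$site_id[duplicated(ds$sites$site_id)][1])
  if (!all(ind$site_id %in% ds$sites$site_id))
    stop("unresolved site_id: ",
         paste(setdiff(ind$site_id, ds$sites$site_id), collapse = ", "))
  if (!all(ind$stage %in% c("adult", "seedling")))
    stop("stage must be 'adult' or 'seedling'")
  if (!all(is.finite(ind$x)) || !all(is.finite(ind$y)))
    stop("individual coordinates must be finite")
  if (anyDuplicated(length(names(ds$loci))) || anyDuplicated(names(ds$loci)))
    stop("locus names must be unique")
  exp_cols <- as.vector(rbind(paste0(names(ds$loci), ".a1"),
                              paste0(names(ds$loci), ".a2")))
  if (!identical(colnames(ds$genotypes), exp_cols))
    stop("genotype columns must be <locus>.a1, <locus>.a2 in locus order")
  if (nrow(ds$genotypes) != nrow(ind))
    stop("genotype rows must match individuals")
  for (l in names(ds$loci)) {
    a1 <- ds$genotypes[, paste0(l, ".a1")]
    a2 <- ds$genotypes[, paste0(l, ".a2")]
    if (any(is.na(a1) != is.na(a2)))
      stop("half-missing call at locus ", l)
    obs <- unique(c(a1[!is.na(a1)], a2[!is.na(a2)]))
    if (!all(obs %in% ds$loci[[l]]))
      stop("allele label outside locus definition at locus ", l)
  }
  cov <- ds$sites$forest_cover
  if (any(!is.na(cov) & (cov < 0 | cov > 100)))
    stop("forest_cover must lie in [0, 100]")
  cxy <- ds$sites[, c("centroid_x", "centroid_y")]
  if (all(!is.na(cxy)) && anyDuplicated(cxy))
    stop("site centroids must be pairwise distinct")
  invisible(ds)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("study_dataset:", nrow(x$individuals), "individuals (",
      sum(x$individuals$stage == "adult"), "adults,",
      sum(x$individuals$stage == "seedling"), "seedlings ),",
      length(x$loci), "loci,", nrow(x$sites), "sites\n")
  invisible(x)
}

#' Subset a study dataset by individual
#'
#' @param ds a `study_dataset`.
#' @param keep logical or integer index over individuals.
#' @return the subsetted `study_dataset` (sites are retained unchanged).
#' @export
subset_individuals <- function(ds, keep) {
  ds$individuals <- ds$individuals[keep, , drop = FALSE]
  ds$genotypes <- ds$genotypes[keep, , drop = FALSE]
  rownames(ds$individuals) <- NULL
  ds
}

#' Drop sites with too few individuals per ontogenetic stage
#'
#' Sites are retained only when they hold at least `min_per_stage` adults and
#' at least `min_per_stage` seedlings; dropped sites lose their individuals
#' as well. The operation is idempotent because site counts do not change for
#' surviving sites.
#'
#' @param ds a `study_dataset`.
#' @param min_per_stage minimum count per stage (default 5).
#' @return the filtered `study_dataset`; dropped site ids are reported with
#'   [message()].
#' @export
filter_sites_min_count <- function(ds, min_per_stage = 5) {
  ind <- ds$individuals
  keep_site <- vapply(ds$sites$site_id, function(s) {
    sum(ind$site_id == s & ind$stage == "adult") >= min_per_stage &&
      sum(ind$site_id == s & ind$stage == "seedling") >= min_per_stage
  }, logical(1))
  dropped <- ds$sites$site_id[!keep_site]
  if (length(dropped))
    message("filter_sites_min_count: dropping site(s) ",
            paste(dropped, collapse = ", "))
  ds$sites <- ds$sites[keep_site, , drop = FALSE]
  rownames(ds$sites) <- NULL
  subset_individuals(ds, ind$site_id %in% ds$sites$site_id)
}

#' Estimate allele frequencies from a reference set of individuals
#'
#' Relative allele frequencies per locus over the 2N alleles observed in the
#' reference set after removing missing calls. The default reference is all
#' adults, the pool against which both the paternity indices and (optionally)
#' the kinship coefficients are referenced.
#'
#' @param ds a `study_dataset`.
#' @param reference `"all_adults"` (default), `"all_individuals"`, or
#'   `"per_site_adults"` (a list of tables, one per site).
#' @return an `allele_freq_table`: a named list, one element per locus, each
#'   a named numeric vector of relative frequencies summing to 1. For
#'   `"per_site_adults"`, a named list of such tables.
#' @export
allele_frequencies <- function(ds,
                               reference = c("all_adults", "all_individuals",
                                             "per_site_adults")) {
  reference <- match.arg(reference)
  if (reference == "per_site_adults") {
    out <- lapply(ds$sites$site_id, function(s) {
      keep <- ds$individuals$site_id == s & ds$individuals$stage == "adult"
      freqs_from_matrix(ds$genotypes[keep, , drop = FALSE], names(ds$loci))
    })
    names(out) <- ds$sites$site_id
    return(out)
  }
  keep <- if (reference == "all_adults")
    ds$individuals$stage == "adult" else rep(TRUE, nrow(ds$individuals))
  freqs_from_matrix(ds$genotypes[keep, , drop = FALSE], names(ds$loci))
}

#' Allele frequencies from a raw genotype matrix
#'
#' Lower-level worker behind [allele_frequencies()]; also used to build the
#' per-analysis-population reference frequencies of the SGS profile.
#'
#' @param geno genotype matrix in `<locus>.a1`/`<locus>.a2` layout.
#' @param locus_names character vector of locus names.
#' @return an `allele_freq_table`.
#' @export
freqs_from_matrix <- function(geno, locus_names) {
  out <- lapply(locus_names, function(l) {
    al <- c(geno[, paste0(l, ".a1")], geno[, paste0(l, ".a2")])
    al <- al[!is.na(al)]
    if (!length(al))
      stop("no observed alleles at locus ", l)
    tab <- table(al)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    f
  })
  names(out) <- locus_names
  structure(out, class = "allele_freq_table")
}
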