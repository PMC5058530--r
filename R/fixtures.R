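#' Packaged study summaries
#'
#' The published per-landscape counts of the field study: number of adults
#' and seedlings sampled in each of the nine landscapes (ordered by percent
#' forest cover in the 2-km buffer, 19--83%), and the number of seedlings
#' whose parent was assigned within the same landscape, within another
#' landscape, and overall. These nine rows fully determine the forest-cover
#' presence/proportion analyses in [glm_binomial_presence()],
#' [glm_binomial_proportion()] and [mc_glm_deviance_test()].
#'
#' @return data.frame with columns `forest_cover, adults, seedlings,
#'   same_landscape, other_landscape, assigned`.
#' @export
study_counts <- function() {
  utils::read.csv(system.file("extdata", "study_counts.csv",
                              package = "palmflow"))
}

#' Packaged between-landscape gene-flow records
#'
#' The five published seedling-parent pairs assigned across landscapes:
#' progeny and parent landscape covers, the paternity probability under a
#' 0.5 prior, and the between-landscape distance in km.
#'
#' @return data.frame with columns `progeny_id, progeny_cover, parent_id,
#'   parent_cover, pp, distance_km`.
#' @export
geneflow_records <- function() {
  utils::read.csv(system.file("extdata", "geneflow_records.csv",
                              package = "palmflow"),
                  colClasses = c(pp = "numeric"))
}

#' Packaged site table with synthetic centroids
#'
#' The nine study landscapes with their published forest-cover values. The
#' field study does not publish site coordinates, so the centroids here are
#' synthetic stand-ins laid out so that the five published between-landscape
#' distances (2, 5, 8, 10 and 13 km) are honoured; all other pairwise
#' distances are arbitrary. They serve as defaults for the synthetic-data
#' generator and for worked examples, not as geographic fact.
#'
#' @return a site table as returned by [load_site_table()].
#' @export
study_sites_synthetic <- function() {
  load_site_table(system.file("extdata", "sites_synthetic_centroids.csv",
                              package = "palmflow"))
}
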