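# Genotypes enter these functions as named integer vectors in the
# <locus>.a1/<locus>.a2 layout (one row of a study_dataset genotype matrix).

# P(single parent with genotype (c1,c2) transmits allele x)
.transmit_prob <- function(c1, c2, x) {
  (c1 == x) * 0.5 + (c2 == x) * 0.5
}

# Hardy-Weinberg probability of offspring genotype (o1,o2) under freqs p
.hw_prob <- function(o1, o2, p) {
  pa <- unname(p[as.character(o1)]); pb <- unname(p[as.character(o2)])
  if (o1 == o2) pa * pa else 2 * pa * pb
}

# Single-parent transmission probability T(g_o | g_c): the candidate
# transmits one allele, the other comes from the reference pool.
# Vectorized over candidates (c1, c2 vectors).
.single_parent_T <- function(o1, o2, c1, c2, p) {
  pa <- unname(p[as.character(o1)]); pb <- unname(p[as.character(o2)])
  if (o1 == o2) .transmit_prob(c1, c2, o1) * pa
  else .transmit_prob(c1, c2, o1) * pb + .transmit_prob(c1, c2, o2) * pa
}

#' LOD score of a single candidate parent of unknown sex
#'
#' Per locus scored in both individuals, the log-likelihood ratio
#' `LOD_l = ln(T*(g_o | g_c) / P(g_o))` where `T` is the single-parent
#' transmission probability (the candidate transmits one allele, the other
#' is drawn from the reference frequencies), `P(g_o)` the Hardy-Weinberg
#' genotype probability, and the genotyping-error model blends
#' `T* = (1-e)^2 T + (1-(1-e)^2) P(g_o)`. Loci missing in either individual
#' contribute 0. With `e = 0` an excluding locus would give `-Inf`; it is
#' floored at `lod_floor` per locus instead.
#'
#' @param offspring,candidate named integer genotype vectors
#'   (`<locus>.a1`/`<locus>.a2`).
#' @param freqs an `allele_freq_table` covering all observed alleles.
#' @param error_rate per-locus genotyping error probability in \[0, 1).
#' @param lod_floor per-locus floor for `ln(0)` (default -37,
#'   about `log(.Machine$double.xmin)`).
#' @return total LOD (finite numeric).
#' @export
lod_single_parent <- function(offspring, candidate, freqs, error_rate = 0.01,
                              lod_floor = -37) {
  stopifnot(error_rate >= 0, error_rate < 1)
  sum(.lod_per_locus(offspring, candidate, freqs, error_rate, lod_floor))
}

# per-locus LOD vector (NA-> 0 handled; names = loci)
.lod_per_locus <- function(offspring, candidate, freqs, error_rate,
                           lod_floor) {
  loci <- names(freqs)
  out <- numeric(length(loci)); names(out) <- loci
  k2 <- (1 - error_rate)^2
  for (li in seq_along(loci)) {
    l <- loci[li]
    o1 <- offspring[[paste0(l, ".a1")]]; o2 <- offspring[[paste0(l, ".a2")]]
    c1 <- candidate[[paste0(l, ".a1")]]; c2 <- candidate[[paste0(l, ".a2")]]
    if (is.na(o1) || is.na(c1)) next
    p <- freqs[[l]]
    if (!all(as.character(c(o1, o2, c1, c2)) %in% names(p)))
      stop("allele absent from frequency table at locus ", l)
    P0 <- .hw_prob(o1, o2, p)
    Tt <- .single_parent_T(o1, o2, c1, c2, p)
    Tstar <- k2 * Tt + (1 - k2) * P0
    out[li] <- if (Tstar <= 0) lod_floor else max(log(Tstar / P0), lod_floor)
  }
  out
}

# vectorized LOD of one offspring against a candidate genotype matrix
.lod_vs_pool <- function(offspring, cand_geno, freqs, error_rate, lod_floor) {
  n_cand <- nrow(cand_geno)
  lod <- numeric(n_cand)
  k2 <- (1 - error_rate)^2
  for (l in names(freqs)) {
    o1 <- offspring[[paste0(l, ".a1")]]; o2 <- offspring[[paste0(l, ".a2")]]
    if (is.na(o1)) next
    p <- freqs[[l]]
    c1 <- cand_geno[, paste0(l, ".a1")]; c2 <- cand_geno[, paste0(l, ".a2")]
    P0 <- .hw_prob(o1, o2, p)
    Tt <- .single_parent_T(o1, o2, c1, c2, p)
    Tstar <- k2 * Tt + (1 - k2) * P0
    ll <- ifelse(Tstar <= 0, lod_floor, pmax(log(Tstar / P0), lod_floor))
    ll[is.na(c1)] <- 0
    lod <- lod + ll
  }
  lod
}

#' Delta statistic from candidate LOD scores
#'
#' The difference in LOD between the most likely and the second most likely
#' candidate with a positive LOD; when exactly one candidate has a positive
#' LOD, Delta equals that LOD. With no positive-LOD candidate no assignment
#' is possible and `NA` is returned.
#'
#' @param lods numeric vector of candidate LOD scores.
#' @return Delta (>= 0), or `NA_real_` when no candidate has LOD > 0.
#' @export
delta_statistic <- function(lods) {
  pos <- lods[lods > 0]
  if (!length(pos)) return(NA_real_)
  if (length(pos) == 1) return(pos)
  s <- sort(pos, decreasing = TRUE)
  s[1] - s[2]
}

#' Simulate the critical Delta threshold
#'
#' Parentage-simulation calibration of the Delta statistic: for each
#' simulated offspring a true parent and a pool of unrelated candidates are
#' drawn from the reference frequencies, the offspring is built by Mendelian
#' transmission plus per-locus genotyping error, the true parent is present
#' in the pool with probability `prop_sampled`, and the Delta of the best
#' candidate is recorded together with whether that candidate is the true
#' parent. The critical value is the smallest threshold t such that among
#' simulated tests with `Delta > t` the proportion of correct assignments is
#' at least `confidence`.
#'
#' @param freqs an `allele_freq_table`.
#' @param n_candidates candidate pool size (>= 2).
#' @param prop_sampled probability the true parent is in the pool.
#' @param error_rate per-locus genotyping error, used both to corrupt the
#'   simulated offspring and in the LOD scoring.
#' @param n_sim number of simulated offspring (study default 10000).
#' @param confidence target proportion of correct assignments (default 0.95).
#' @param seed optional integer seed.
#' @param lod_floor per-locus LOD floor, as in [lod_single_parent()].
#' @return object of class `critical_delta`: list with `delta_crit`,
#'   `confidence_level`, `n_simulations`, and `sim_params`.
#' @export
simulate_critical_delta <- function(freqs, n_candidates, prop_sampled = 0.5,
                                    error_rate = 0.01, n_sim = 10000,
                                    confidence = 0.95, seed = NULL,
                                    lod_floor = -37) {
  stopifnot(n_candidates >= 2, prop_sampled >= 0, prop_sampled <= 1)
  if (!is.null(seed)) set.seed(seed)
  deltas <- numeric(n_sim); correct <- logical(n_sim); tested <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    parent <- .draw_hw_genotypes(1L, freqs)
    other <- .draw_hw_genotypes(1L, freqs)
    off <- .mendelian_offspring(parent[1, ], other[1, ], freqs, error_rate)
    pool <- .draw_hw_genotypes(n_candidates - 1L, freqs)
    true_in <- stats::runif(1) < prop_sampled
    if (true_in) pool <- rbind(pool, parent)
    lods <- .lod_vs_pool(off, pool, freqs, error_rate, lod_floor)
    pos <- which(lods > 0)
    if (!length(pos)) next
    best <- pos[which.max(lods[pos])]
    tested[s] <- TRUE
    deltas[s] <- delta_statistic(lods)
    correct[s] <- true_in && best == nrow(pool)
  }
  d <- deltas[tested]; ok <- correct[tested]
  delta_crit <- .smallest_threshold(d, ok, confidence)
  structure(list(delta_crit = delta_crit, confidence_level = confidence,
                 n_simulations = n_sim,
                 sim_params = list(n_candidates = n_candidates,
                                   prop_sampled = prop_sampled,
                                   error_rate = error_rate,
                                   lod_floor = lod_floor)),
            class = "critical_delta")
}

.smallest_threshold <- function(deltas, correct, confidence) {
  if (confidence <= 0) return(0)
  if (!length(deltas)) {
    warning("no simulated tests; critical Delta undefined (+Inf)")
    return(Inf)
  }
  cand <- sort(unique(c(0, deltas)))
  for (t in cand) {
    sel <- deltas > t
    if (!any(sel)) break
    if (mean(correct[sel]) >= confidence) return(t)
  }
  warning("no threshold achieves the requested confidence; returning +Inf")
  Inf
}

# n HW genotype draws from freqs -> matrix in <locus>.a1/<locus>.a2 layout
.draw_hw_genotypes <- function(n, freqs) {
  cols <- as.vector(rbind(paste0(names(freqs), ".a1"),
                          paste0(names(freqs), ".a2")))
  g <- matrix(NA_integer_, n, length(cols), dimnames = list(NULL, cols))
  for (l in names(freqs)) {
    p <- freqs[[l]]
    lab <- as.integer(names(p))
    g[, paste0(l, ".a1")] <- sample(lab, n, replace = TRUE, prob = p)
    g[, paste0(l, ".a2")] <- sample(lab, n, replace = TRUE, prob = p)
  }
  g
}

# Mendelian offspring of two genotype vectors, with per-locus mistyping:
# with probability error_rate the recorded call is replaced by a random
# HW genotype drawn from freqs.
.mendelian_offspring <- function(mother, father, freqs, error_rate) {
  off <- mother                     # template with right names
  for (l in names(freqs)) {
    a1c <- paste0(l, ".a1"); a2c <- paste0(l, ".a2")
    m <- c(mother[[a1c]], mother[[a2c]])
    f <- c(father[[a1c]], father[[a2c]])
    if (anyNA(m) || anyNA(f)) { off[a1c] <- NA; off[a2c] <- NA; next }
    off[a1c] <- m[sample.int(2, 1)]
    off[a2c] <- f[sample.int(2, 1)]
    if (error_rate > 0 && stats::runif(1) < error_rate) {
      p <- freqs[[l]]; lab <- as.integer(names(p))
      off[a1c] <- sample(lab, 1, prob = p)
      off[a2c] <- sample(lab, 1, prob = p)
    }
  }
  off
}

#' Count Mendelian exclusion mismatches
#'
#' Number of loci scored in both individuals at which they share no allele,
#' i.e. loci that exclude the candidate as a parent in the absence of
#' genotyping error.
#'
#' @inheritParams lod_single_parent
#' @return integer count.
#' @export
exclusion_mismatches <- function(offspring, candidate) {
  loci <- unique(sub("\\.a[12]$", "", names(offspring)))
  n <- 0L
  for (l in loci) {
    o <- c(offspring[[paste0(l, ".a1")]], offspring[[paste0(l, ".a2")]])
    cc <- c(candidate[[paste0(l, ".a1")]], candidate[[paste0(l, ".a2")]])
    if (anyNA(o) || anyNA(cc)) next
    if (!any(o %in% cc)) n <- n + 1L
  }
  n
}

#' Per-locus paternity index, combined index and paternity probability
#'
#' The per-locus paternity index is `PI = X / Y` where `X` is the
#' probability that the alleged parent transmits an allele compatible with
#' the offspring genotype and `Y` the probability that a random individual
#' from the reference pool does (the sum of the compatible allele
#' frequencies). At a locus excluding the candidate (`X = 0`), a nonzero
#' genotyping error rate keeps the index positive at `error_rate *
#' excl_scale` so the combined index remains usable after exclusion review.
#' `combined_pi` is the product over scored loci, and
#' `paternity_probability` converts it to a posterior probability under the
#' stated prior: `PP = CPI * prior / (CPI * prior + (1 - prior))`; with the
#' conventional prior of 0.5, `PP = CPI / (CPI + 1)`.
#'
#' @inheritParams lod_single_parent
#' @param excl_scale multiplier on `error_rate` for an excluding locus.
#' @return `paternity_index`: named numeric vector of per-locus PI (`NA`
#'   where either genotype is missing).
#' @export
paternity_index <- function(offspring, candidate, freqs, error_rate = 0.01,
                            excl_scale = 1) {
  loci <- names(freqs)
  out <- rep(NA_real_, length(loci)); names(out) <- loci
  for (li in seq_along(loci)) {
    l <- loci[li]
    o1 <- offspring[[paste0(l, ".a1")]]; o2 <- offspring[[paste0(l, ".a2")]]
    c1 <- candidate[[paste0(l, ".a1")]]; c2 <- candidate[[paste0(l, ".a2")]]
    if (is.na(o1) || is.na(c1)) next
    p <- freqs[[l]]
    compat <- unique(c(o1, o2))
    X <- sum(vapply(compat, function(a) .transmit_prob(c1, c2, a),
                    numeric(1)))
    Y <- sum(unname(p[as.character(compat)]))
    out[li] <- if (X <= 0) error_rate * excl_scale else X / Y
  }
  out
}

#' @rdname paternity_index
#' @param pi_per_locus vector of per-locus PI values.
#' @return `combined_pi`: product of the non-missing per-locus indices.
#' @export
combined_pi <- function(pi_per_locus) {
  prod(pi_per_locus[!is.na(pi_per_locus)])
}

#' @rdname paternity_index
#' @param cpi combined paternity index (> 0).
#' @param prior prior probability of parentage (default 0.5).
#' @return `paternity_probability`: PP in (0, 1).
#' @export
paternity_probability <- function(cpi, prior = 0.5) {
  if (cpi <= 0) stop("cpi must be positive")
  cpi * prior / (cpi * prior + (1 - prior))
}

#' Assign a most likely parent to every seedling
#'
#' Scores every seedling against every adult in the dataset (all sites) with
#' the single-parent LOD of unknown sex, forms the Delta statistic over
#' positive-LOD candidates, and assigns the best candidate when
#' `Delta > delta_crit`. Reference allele frequencies default to all adults;
#' alleles carried only by seedlings (immigrant or mistyped alleles absent
#' from the adult pool) are added at a floor frequency of `1/(2N+1)` and the
#' table renormalised, so immigrant offspring remain scoreable. Gene-flow
#' distance is individual-to-individual within a site and centroid-to-
#' centroid across sites.
#'
#' @param ds a `study_dataset` with adults and seedlings.
#' @param crit a `critical_delta` from [simulate_critical_delta()], or a
#'   bare numeric threshold.
#' @param freqs optional `allele_freq_table`; default all-adults with the
#'   seedling-allele augmentation described above.
#' @param error_rate per-locus genotyping error used in scoring (defaults to
#'   the rate stored in `crit`, else 0.01).
#' @param prior prior parentage probability for PP (default 0.5).
#' @param lod_floor per-locus LOD floor.
#' @return data.frame of class `parentage_assignments`: one row per
#'   seedling with `offspring_id, parent_id` (`NA` when unassigned), `lod,
#'   delta, confidence` (`"strict95"`/`"unassigned"`), `mismatches, cpi,
#'   pp, distance_m, same_site`.
#' @export
assign_parents <- function(ds, crit, freqs = NULL, error_rate = NULL,
                           prior = 0.5, lod_floor = -37) {
  delta_crit <- if (inherits(crit, "critical_delta")) crit$delta_crit else crit
  if (is.null(error_rate))
    error_rate <- if (inherits(crit, "critical_delta"))
      crit$sim_params$error_rate else 0.01
  conf_label <- if (inherits(crit, "critical_delta"))
    sprintf("strict%.0f", 100 * crit$confidence_level) else "strict95"
  is_ad <- ds$individuals$stage == "adult"
  is_sd <- ds$individuals$stage == "seedling"
  seedlings <- which(is_sd)
  out <- data.frame(offspring_id = ds$individuals$id[seedlings],
                    parent_id = NA_character_, lod = NA_real_,
                    delta = NA_real_, confidence = "unassigned",
                    mismatches = NA_integer_, cpi = NA_real_, pp = NA_real_,
                    distance_m = NA_real_, same_site = NA,
                    stringsAsFactors = FALSE)
  if (!any(is_ad)) {
    class(out) <- c("parentage_assignments", class(out))
    return(out)
  }
  if (is.null(freqs)) freqs <- .augmented_adult_freqs(ds)
  ad_geno <- ds$genotypes[is_ad, , drop = FALSE]
  ad_info <- ds$individuals[is_ad, ]
  cx <- stats::setNames(ds$sites$centroid_x, ds$sites$site_id)
  cy <- stats::setNames(ds$sites$centroid_y, ds$sites$site_id)
  for (r in seq_along(seedlings)) {
    i <- seedlings[r]
    off <- ds$genotypes[i, ]
    lods <- .lod_vs_pool(off, ad_geno, freqs, error_rate, lod_floor)
    delta <- delta_statistic(lods)
    if (is.na(delta) || !(delta > delta_crit)) next
    pos <- which(lods > 0)
    best <- pos[which.max(lods[pos])]
    pg <- ad_geno[best, ]
    pi_l <- paternity_index(off, pg, freqs, error_rate = error_rate)
    cpi <- combined_pi(pi_l)
    same <- ad_info$site_id[best] == ds$individuals$site_id[i]
    dist_m <- if (same)
      sqrt((ad_info$x[best] - ds$individuals$x[i])^2 +
             (ad_info$y[best] - ds$individuals$y[i])^2)
    else
      sqrt((cx[[ad_info$site_id[best]]] -
              cx[[ds$individuals$site_id[i]]])^2 +
             (cy[[ad_info$site_id[best]]] -
                cy[[ds$individuals$site_id[i]]])^2)
    out$parent_id[r] <- ad_info$id[best]
    out$lod[r] <- lods[best]
    out$delta[r] <- delta
    out$confidence[r] <- conf_label
    out$mismatches[r] <- exclusion_mismatches(off, pg)
    out$cpi[r] <- cpi
    out$pp[r] <- paternity_probability(cpi, prior)
    out$distance_m[r] <- dist_m
    out$same_site[r] <- same
  }
  class(out) <- c("parentage_assignments", class(out))
  out
}

# all-adult frequencies, augmented with seedling-only alleles at a floor
# frequency of 1/(2N+1) so immigrant alleles do not zero out likelihoods
.augmented_adult_freqs <- function(ds) {
  base <- allele_frequencies(ds, reference = "all_adults")
  n2 <- 2 * sum(ds$individuals$stage == "adult")
  for (l in names(base)) {
    all_obs <- unique(c(ds$genotypes[, paste0(l, ".a1")],
                        ds$genotypes[, paste0(l, ".a2")]))
    all_obs <- as.character(all_obs[!is.na(all_obs)])
    extra <- setdiff(all_obs, names(base[[l]]))
    if (length(extra)) {
      f <- c(base[[l]], stats::setNames(rep(1 / (n2 + 1), length(extra)),
                                        extra))
      base[[l]] <- f / sum(f)
    }
  }
  base
}
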