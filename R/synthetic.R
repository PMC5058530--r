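#' Configuration of the synthetic-data generator
#'
#' Describes a simulated field study with the structure the analyses assume:
#' sites on a forest-cover gradient, adults censused in a 15 x 400 m plot
#' and seedlings in a nested 2 x 400 m strip, a fixed panel of SSR loci,
#' Mendelian inheritance with per-locus mistyping, short-range
#' insect-mediated pollen movement, and a heavy-tailed seed-dispersal kernel
#' whose median scales with forest cover:
#' `median_d = exp(a + b * cover)` with a log-normal kernel of log-sd
#' `sdlog`. Defaults mirror the published study design: the nine cover
#' values 19--83%, the published per-site adult and seedling counts, 13
#' loci, and a 0.01 per-locus error rate.
#'
#' @param covers forest-cover percentages, one per site.
#' @param adults_per_site,seedlings_per_site integer vectors, one per site.
#' @param n_loci number of SSR loci.
#' @param alleles_per_locus number of possible alleles per locus.
#' @param founder_alpha Dirichlet concentration for founder allele
#'   frequencies (1 = uniform on the simplex).
#' @param error_rate per-locus probability that a recorded genotype is
#'   replaced by a random one.
#' @param dispersal_a,dispersal_b intercept and slope (per percent cover) of
#'   log median seed-dispersal distance, metres.
#' @param dispersal_sdlog log-sd of the log-normal dispersal kernel.
#' @param lambda_pollen e-folding distance (m) of the pollen-donor weight
#'   `exp(-d / lambda)`.
#' @param prop_parents_sampled probability a true parent is a censused
#'   adult (vs an unsampled "ghost").
#' @param cross_site_threshold kernel draws beyond this distance (m) become
#'   between-site dispersal events.
#' @param cross_capture_prob probability that a between-site seed arrival
#'   lands inside the census strip and is recorded. Within-site events are
#'   censored geometrically by the explicit deposition sampler; between-site
#'   arrivals, whose deposition is not modelled at metre scale, are thinned
#'   by this constant instead so that immigrant seedlings are rare in the
#'   census, as in real nested-plot designs.
#' @param sites optional site table (site_id, centroid_x, centroid_y,
#'   forest_cover); default [study_sites_synthetic()] subset/recycled to
#'   `covers`.
#' @param seed integer seed fixing every downstream draw.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(covers = NULL,
                              adults_per_site = NULL,
                              seedlings_per_site = NULL,
                              n_loci = 13,
                              alleles_per_locus = 8,
                              founder_alpha = 1,
                              error_rate = 0.01,
                              dispersal_a = log(20),
                              dispersal_b = 0.035,
                              dispersal_sdlog = 1.0,
                              lambda_pollen = 200,
                              prop_parents_sampled = 0.5,
                              cross_site_threshold = 1000,
                              cross_capture_prob = 0.02,
                              sites = NULL,
                              seed = 1) {
  counts <- study_counts()
  if (is.null(covers)) covers <- counts$forest_cover
  n_sites <- length(covers)
  if (is.null(adults_per_site))
    adults_per_site <- counts$adults[match(covers, counts$forest_cover)]
  if (is.null(seedlings_per_site))
    seedlings_per_site <- counts$seedlings[match(covers, counts$forest_cover)]
  if (anyNA(adults_per_site) || anyNA(seedlings_per_site))
    stop("covers without default counts: supply adults_per_site and ",
         "seedlings_per_site explicitly")
  if (is.null(sites)) {
    base <- study_sites_synthetic()
    m <- match(covers, base$forest_cover)
    if (anyNA(m))
      stop("covers without default centroids: supply a site table")
    sites <- base[m, ]
    rownames(sites) <- NULL
  }
  if (nrow(sites) != n_sites)
    stop("site table must have one row per cover value")
  stopifnot(all(covers >= 0 & covers <= 100),
            error_rate >= 0, error_rate <= 1,
            prop_parents_sampled >= 0, prop_parents_sampled <= 1,
            length(adults_per_site) == n_sites,
            length(seedlings_per_site) == n_sites)
  structure(list(covers = covers, adults_per_site = adults_per_site,
                 seedlings_per_site = seedlings_per_site, n_loci = n_loci,
                 alleles_per_locus = alleles_per_locus,
                 founder_alpha = founder_alpha, error_rate = error_rate,
                 dispersal_a = dispersal_a, dispersal_b = dispersal_b,
                 dispersal_sdlog = dispersal_sdlog,
                 lambda_pollen = lambda_pollen,
                 prop_parents_sampled = prop_parents_sampled,
                 cross_site_threshold = cross_site_threshold,
                 cross_capture_prob = cross_capture_prob,
                 sites = sites, seed = seed),
            class = "simulation_config")
}

# plot geometry, metres relative to the site centroid:
# adults anywhere in the 15 x 400 m plot, seedlings censused only in the
# central 2 x 400 m strip
.ADULT_PLOT <- c(xmin = -200, xmax = 200, ymin = -7.5, ymax = 7.5)
.SEEDLING_PLOT <- c(xmin = -200, xmax = 200, ymin = -1, ymax = 1)

#' Simulate a study dataset with known pedigree
#'
#' Generates adults and seedlings under the generative model described in
#' [simulation_config()] and records the true pedigree in a truth ledger.
#' For each seedling a dispersal distance is drawn from the cover-dependent
#' log-normal kernel. Draws beyond `cross_site_threshold` become
#' between-site events, retained in the census with probability
#' `cross_capture_prob`: the mother comes from another site (chosen with
#' probability inversely proportional to centroid distance) and the realized
#' gene-flow distance is the centroid distance. Otherwise the mother is
#' local (a censused adult with probability `prop_parents_sampled`, else a
#' ghost), the seed is displaced from her by the drawn distance in a uniform
#' direction, and the seedling is retained only if it lands in the 2 x 400 m
#' census strip (rejection sampling of the deposition event, mirroring the
#' nested-plot census). Fathers are drawn from the mother's site with weight
#' `exp(-d / lambda_pollen)` (ghost with probability
#' `1 - prop_parents_sampled`). Offspring inherit one allele per parent per
#' locus; with probability `error_rate` per locus the recorded call is
#' replaced by a random Hardy-Weinberg draw from the founder frequencies.
#'
#' @param cfg a `simulation_config`.
#' @return list with `dataset` (a `study_dataset`) and `ledger` (data.frame
#'   of class `truth_ledger`: `seedling_id, site_id, mother_id, mother_site,
#'   mother_sampled, father_id, father_site, father_sampled, distance_m,
#'   cross_site`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n_sites <- length(cfg$covers)
  site_ids <- cfg$sites$site_id
  loci <- .simulate_loci(cfg)
  founder <- .simulate_founder_freqs(cfg, loci)
  D_site <- as.matrix(stats::dist(cfg$sites[, c("centroid_x", "centroid_y")]))
  dimnames(D_site) <- list(site_ids, site_ids)

  # adults: uniform positions in the 15 x 400 m plot, HW genotypes
  ad_rows <- list(); ad_geno <- list()
  for (s in seq_len(n_sites)) {
    na <- cfg$adults_per_site[s]
    ad_rows[[s]] <- data.frame(
      id = sprintf("%s_A%03d", site_ids[s], seq_len(na)),
      site_id = site_ids[s], stage = "adult",
      x = cfg$sites$centroid_x[s] +
        stats::runif(na, .ADULT_PLOT["xmin"], .ADULT_PLOT["xmax"]),
      y = cfg$sites$centroid_y[s] +
        stats::runif(na, .ADULT_PLOT["ymin"], .ADULT_PLOT["ymax"]),
      stringsAsFactors = FALSE)
    ad_geno[[s]] <- .draw_hw_genotypes(na, founder)
  }
  adults <- do.call(rbind, ad_rows)
  adult_geno <- do.call(rbind, ad_geno)
  rownames(adult_geno) <- adults$id

  sd_rows <- list(); sd_geno <- list(); ledger <- list()
  ghost_count <- stats::setNames(integer(n_sites), site_ids)
  new_ghost <- function(s) {
    ghost_count[s] <<- ghost_count[s] + 1L
    sprintf("%s_G%03d", s, ghost_count[s])
  }
  for (s in seq_len(n_sites)) {
    sid <- site_ids[s]
    med <- exp(cfg$dispersal_a + cfg$dispersal_b * cfg$covers[s])
    local_adults <- which(adults$site_id == sid)
    ns <- cfg$seedlings_per_site[s]
    k <- 0L
    while (k < ns) {
      d <- stats::rlnorm(1, meanlog = log(med), sdlog = cfg$dispersal_sdlog)
      if (d > cfg$cross_site_threshold && n_sites > 1) {
        # between-site event: thinned by the census capture probability,
        # source site inversely weighted by distance
        if (stats::runif(1) >= cfg$cross_capture_prob) next
        others <- setdiff(seq_len(n_sites), s)
        w <- 1 / D_site[sid, site_ids[others]]
        src <- others[sample.int(length(others), 1, prob = w)]
        ev <- .make_seedling(cfg, founder, adults, adult_geno,
                             src_site = site_ids[src], focal_site = sid,
                             deposition = .uniform_in_strip(cfg, s),
                             distance = D_site[sid, site_ids[src]],
                             cross_site = TRUE, new_ghost = new_ghost)
      } else {
        # local event: displace from the mother, censused only if the seed
        # lands inside the 2 x 400 m strip
        mom <- .pick_mother(cfg, adults, local_adults, sid, new_ghost,
                            site_index = s)
        theta <- stats::runif(1, 0, 2 * pi)
        dep <- c(mom$x + d * cos(theta), mom$y + d * sin(theta))
        if (!.in_strip(cfg, s, dep)) next
        ev <- .make_seedling(cfg, founder, adults, adult_geno,
                             src_site = sid, focal_site = sid,
                             deposition = dep, distance = d,
                             cross_site = FALSE, new_ghost = new_ghost,
                             mother = mom)
      }
      k <- k + 1L
      ev$row$id <- sprintf("%s_S%03d", sid, k)
      ev$ledger$seedling_id <- ev$row$id
      sd_rows[[length(sd_rows) + 1L]] <- ev$row
      sd_geno[[length(sd_geno) + 1L]] <- ev$geno
      ledger[[length(ledger) + 1L]] <- ev$ledger
    }
  }
  seedlings <- do.call(rbind, sd_rows)
  seedling_geno <- do.call(rbind, sd_geno)
  rownames(seedling_geno) <- seedlings$id
  individuals <- rbind(adults, seedlings)
  geno <- rbind(adult_geno, seedling_geno)
  ds <- study_dataset(loci, individuals, geno, cfg$sites)
  led <- do.call(rbind, ledger)
  led <- led[, c("seedling_id", "site_id", "mother_id", "mother_site",
                 "mother_sampled", "father_id", "father_site",
                 "father_sampled", "distance_m", "cross_site")]
  class(led) <- c("truth_ledger", class(led))
  list(dataset = ds, ledger = led)
}

.simulate_loci <- function(cfg) {
  loci <- lapply(seq_len(cfg$n_loci), function(i)
    as.integer(100 + 2 * seq_len(cfg$alleles_per_locus)))
  names(loci) <- sprintf("SSR%02d", seq_len(cfg$n_loci))
  loci
}

# Dirichlet(alpha) founder frequencies via normalized gammas
.simulate_founder_freqs <- function(cfg, loci) {
  out <- lapply(loci, function(a) {
    g <- stats::rgamma(length(a), shape = cfg$founder_alpha)
    f <- g / sum(g)
    names(f) <- a
    f
  })
  structure(out, class = "allele_freq_table")
}

.uniform_in_strip <- function(cfg, s) {
  c(cfg$sites$centroid_x[s] +
      stats::runif(1, .SEEDLING_PLOT["xmin"], .SEEDLING_PLOT["xmax"]),
    cfg$sites$centroid_y[s] +
      stats::runif(1, .SEEDLING_PLOT["ymin"], .SEEDLING_PLOT["ymax"]))
}

.in_strip <- function(cfg, s, xy) {
  lx <- xy[1] - cfg$sites$centroid_x[s]
  ly <- xy[2] - cfg$sites$centroid_y[s]
  lx >= .SEEDLING_PLOT["xmin"] && lx <= .SEEDLING_PLOT["xmax"] &&
    ly >= .SEEDLING_PLOT["ymin"] && ly <= .SEEDLING_PLOT["ymax"]
}

.pick_mother <- function(cfg, adults, local_idx, sid, new_ghost, site_index) {
  if (length(local_idx) && stats::runif(1) < cfg$prop_parents_sampled) {
    i <- local_idx[sample.int(length(local_idx), 1)]
    list(id = adults$id[i], x = adults$x[i], y = adults$y[i],
         sampled = TRUE, index = i)
  } else {
    list(id = new_ghost(sid),
         x = cfg$sites$centroid_x[site_index] +
           stats::runif(1, .ADULT_PLOT["xmin"], .ADULT_PLOT["xmax"]),
         y = cfg$sites$centroid_y[site_index] +
           stats::runif(1, .ADULT_PLOT["ymin"], .ADULT_PLOT["ymax"]),
         sampled = FALSE, index = NA_integer_)
  }
}

# assemble one seedling: mother (given or drawn in src_site), father drawn
# near the mother in src_site, Mendelian genotype with mistyping
.make_seedling <- function(cfg, founder, adults, adult_geno, src_site,
                           focal_site, deposition, distance, cross_site,
                           new_ghost, mother = NULL) {
  src_index <- match(src_site, cfg$sites$site_id)
  local_idx <- which(adults$site_id == src_site)
  if (is.null(mother))
    mother <- .pick_mother(cfg, adults, local_idx, src_site, new_ghost,
                           site_index = src_index)
  mother_geno <- if (mother$sampled) adult_geno[mother$index, ]
  else .draw_hw_genotypes(1L, founder)[1, ]
  # father: same-site pollen, distance-weighted around the mother
  cand <- setdiff(local_idx, mother$index)
  if (length(cand) && stats::runif(1) < cfg$prop_parents_sampled) {
    dd <- sqrt((adults$x[cand] - mother$x)^2 + (adults$y[cand] - mother$y)^2)
    j <- cand[sample.int(length(cand), 1,
                         prob = exp(-dd / cfg$lambda_pollen))]
    father <- list(id = adults$id[j], sampled = TRUE)
    father_geno <- adult_geno[j, ]
  } else {
    father <- list(id = new_ghost(src_site), sampled = FALSE)
    father_geno <- .draw_hw_genotypes(1L, founder)[1, ]
  }
  geno <- .mendelian_offspring(mother_geno, father_geno, founder,
                               cfg$error_rate)
  list(row = data.frame(id = NA_character_, site_id = focal_site,
                        stage = "seedling",
                        x = deposition[1], y = deposition[2],
                        stringsAsFactors = FALSE),
       geno = matrix(geno, nrow = 1,
                     dimnames = list(NULL, names(geno))),
       ledger = data.frame(seedling_id = NA_character_,
                           site_id = focal_site,
                           mother_id = mother$id, mother_site = src_site,
                           mother_sampled = mother$sampled,
                           father_id = father$id, father_site = src_site,
                           father_sampled = father$sampled,
                           distance_m = distance, cross_site = cross_site,
                           stringsAsFactors = FALSE))
}

#' Truth-ledger summary per site
#'
#' The ground-truth analogue of the study's per-landscape count table:
#' numbers of adults and seedlings per site, and of seedlings with at least
#' one sampled true parent in the same site and in another site.
#'
#' @param ledger a `truth_ledger` from [simulate_dataset()].
#' @param ds the matching `study_dataset`.
#' @return data.frame: `site_id, forest_cover, adults, seedlings,
#'   same_site_parent, other_site_parent`.
#' @export
ledger_summary <- function(ledger, ds) {
  if (!setequal(ledger$seedling_id,
                ds$individuals$id[ds$individuals$stage == "seedling"]))
    stop("ledger does not match dataset seedlings")
  cov <- stats::setNames(ds$sites$forest_cover, ds$sites$site_id)
  do.call(rbind, lapply(ds$sites$site_id, function(s) {
    led <- ledger[ledger$site_id == s, , drop = FALSE]
    sampled_same <- (led$mother_sampled & led$mother_site == s) |
      (led$father_sampled & led$father_site == s)
    sampled_other <- (led$mother_sampled & led$mother_site != s) |
      (led$father_sampled & led$father_site != s)
    data.frame(site_id = s, forest_cover = unname(cov[s]),
               adults = sum(ds$individuals$site_id == s &
                              ds$individuals$stage == "adult"),
               seedlings = nrow(led),
               same_site_parent = sum(sampled_same),
               other_site_parent = sum(sampled_other),
               stringsAsFactors = FALSE)
  }))
}
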