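#' Pairwise Loiselle kinship coefficients
#'
#' Computes the Loiselle et al. (1995) kinship coefficient F_ij for every
#' pair of individuals, referenced to a stated allele-frequency pool. At one
#' locus,
#' \deqn{f_{ij} = \frac{\sum_a (p_{ia}-\bar p_a)(p_{ja}-\bar p_a) +
#'   \sum_a \bar p_a (1-\bar p_a)/(n-1)}{\sum_a \bar p_a (1-\bar p_a)}}
#' where \eqn{p_{ia} \in \{0, 1/2, 1\}} is individual i's frequency of allele
#' a, \eqn{\bar p_a} the reference frequency and n the number of individuals
#' genotyped at the locus (the \eqn{1/(n-1)} term is the finite-sample
#' bias correction). The multilocus coefficient is the mean over loci scored
#' in both individuals, weighted by the locus polymorphism index
#' \eqn{w_l = \sum_a \bar p_a (1-\bar p_a)}; monomorphic loci carry zero
#' weight and therefore cannot change the multilocus value.
#'
#' @param ds a `study_dataset`, or a genotype matrix in
#'   `<locus>.a1`/`<locus>.a2` layout.
#' @param freqs an `allele_freq_table` covering every observed allele
#'   (e.g. from [allele_frequencies()] or [freqs_from_matrix()]).
#' @return symmetric numeric matrix of F_ij with `NA` on the diagonal and
#'   for pairs sharing no scored polymorphic locus.
#' @export
pairwise_kinship_loiselle <- function(ds, freqs) {
  geno <- if (inherits(ds, "study_dataset")) ds$genotypes else ds
  locus_names <- unique(sub("\\.a[12]$", "", colnames(geno)))
  if (!all(locus_names %in% names(freqs)))
    stop("locus missing from frequency table: ",
         setdiff(locus_names, names(freqs))[1])
  n_ind <- nrow(geno)
  if (n_ind < 2) stop("need at least 2 individuals")
  num <- matrix(0, n_ind, n_ind)
  den <- matrix(0, n_ind, n_ind)
  for (l in locus_names) {
    pbar <- freqs[[l]]
    w <- sum(pbar * (1 - pbar))
    if (w <= 0) next                       # monomorphic: zero weight
    a1 <- geno[, paste0(l, ".a1")]
    a2 <- geno[, paste0(l, ".a2")]
    scored <- !is.na(a1)
    nl <- sum(scored)
    if (nl < 2) next
    obs <- unique(c(a1[scored], a2[scored]))
    if (!all(as.character(obs) %in% names(pbar)))
      stop("allele absent from frequency table at locus ", l)
    # individual allele-frequency matrix (0, 0.5, 1) on the reference alleles
    P <- matrix(0, n_ind, length(pbar),
                dimnames = list(NULL, names(pbar)))
    rows <- which(scored)
    idx1 <- cbind(rows, match(as.character(a1[rows]), names(pbar)))
    P[idx1] <- 0.5
    idx2 <- cbind(rows, match(as.character(a2[rows]), names(pbar)))
    P[idx2] <- P[idx2] + 0.5
    P[!scored, ] <- NA
    C <- sweep(P, 2, pbar)
    S <- tcrossprod(C) + w / (nl - 1)      # numerator = w * f_l where scored
    ok <- outer(scored, scored, "&")
    num[ok] <- num[ok] + S[ok]
    den[ok] <- den[ok] + w
  }
  fij <- num / den
  fij[den == 0] <- NA
  diag(fij) <- NA
  dimnames(fij) <- list(rownames(geno), rownames(geno))
  fij
}

#' Distance-class specification for SGS profiles
#'
#' Contiguous half-open classes `[lo, hi)`; the default is the study design
#' of eight 50-m classes spanning 0--400 m. Pairs at or beyond the last edge
#' fall into an out-of-range bucket that is excluded from the profile but
#' included in the overall mean kinship.
#'
#' @param breaks increasing numeric vector of class edges (metres).
#' @return an object of class `distance_class_spec`.
#' @export
distance_classes <- function(breaks = seq(0, 400, by = 50)) {
  stopifnot(is.numeric(breaks), length(breaks) >= 2, all(diff(breaks) > 0))
  structure(list(breaks = breaks, n_classes = length(breaks) - 1L),
            class = "distance_class_spec")
}

#' Spatial genetic structure profile with permutation envelope
#'
#' Computes the distance-class SGS profile of one analysis population
#' (typically one site x stage): mean pairwise Loiselle kinship per distance
#' class, with a null envelope obtained by shuffling the coordinate tuples
#' among individuals (genotypes fixed) and recording the 2.5% and 97.5%
#' percentiles of the permuted class means. The reference allele frequencies
#' default to the analysis population itself; pass `freqs` to override.
#'
#' @param ds a `study_dataset` restricted to the analysis population (use
#'   [subset_individuals()]), with >= 2 individuals.
#' @param classes a [distance_classes()] specification.
#' @param n_perm number of location permutations (study default 10000).
#' @param seed optional integer seed for the permutation stream.
#' @param freqs optional `allele_freq_table` reference; default is computed
#'   from the analysis population.
#' @return an object of class `sgs_result`: list with `fij` (pair matrix),
#'   `profile` (data.frame: lower, upper, mean_fij, n_pairs, env_lo, env_hi,
#'   degenerate flag for empty classes), `n_pairs_out_of_range`,
#'   `overall_mean` (all defined pairs, out-of-range included),
#'   `overall_mean_classes` (mean of occupied class means), `n_perm`, `n`.
#' @export
sgs_profile <- function(ds, classes = distance_classes(), n_perm = 10000,
                        seed = NULL, freqs = NULL) {
  stopifnot(inherits(ds, "study_dataset"))
  n <- nrow(ds$individuals)
  if (n < 2) stop("need at least 2 individuals with coordinates")
  if (is.null(freqs)) freqs <- freqs_from_matrix(ds$genotypes, names(ds$loci))
  fij <- pairwise_kinship_loiselle(ds, freqs)
  xy <- cbind(ds$individuals$x, ds$individuals$y)
  D <- as.matrix(stats::dist(xy))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  i_idx <- ut[, 1]; j_idx <- ut[, 2]
  fvals <- fij[ut]
  brk <- classes$breaks
  nk <- classes$n_classes
  class_of <- function(d) {
    k <- findInterval(d, brk, left.open = FALSE)   # [lo, hi)
    k[d >= brk[length(brk)]] <- nk + 1L            # out-of-range bucket
    k[d < brk[1]] <- nk + 1L
    k
  }
  cls <- class_of(D[ut])
  class_means <- function(cl) {
    m <- rep(NA_real_, nk)
    ok <- !is.na(fvals) & cl <= nk
    if (any(ok)) {
      s <- rowsum(fvals[ok], cl[ok])
      cnt <- rowsum(rep(1, sum(ok)), cl[ok])
      m[as.integer(rownames(s))] <- s / cnt
    }
    m
  }
  obs_means <- class_means(cls)
  n_pairs <- tabulate(cls[!is.na(fvals)], nbins = nk + 1L)
  if (!is.null(seed)) set.seed(seed)
  perm_means <- matrix(NA_real_, n_perm, nk)
  for (p in seq_len(n_perm)) {
    pr <- sample.int(n)
    dperm <- D[cbind(pr[i_idx], pr[j_idx])]
    perm_means[p, ] <- class_means(class_of(dperm))
  }
  env <- apply(perm_means, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) c(NA_real_, NA_real_)
    else stats::quantile(v, c(0.025, 0.975), names = FALSE)
  })
  profile <- data.frame(lower = brk[-length(brk)], upper = brk[-1],
                        mean_fij = obs_means,
                        n_pairs = n_pairs[seq_len(nk)],
                        env_lo = env[1, ], env_hi = env[2, ],
                        degenerate = n_pairs[seq_len(nk)] == 0)
  structure(list(fij = fij, profile = profile,
                 n_pairs_out_of_range = n_pairs[nk + 1L],
                 overall_mean = mean(fvals, na.rm = TRUE),
                 overall_mean_classes = mean(obs_means, na.rm = TRUE),
                 n_perm = n_perm, n = n),
            class = "sgs_result")
}

#' @export
print.sgs_result <- function(x, ...) {
  cat("SGS profile:", x$n, "individuals,", x$n_perm, "permutations\n")
  cat("overall mean F_ij (all pairs):", format(x$overall_mean), "\n")
  print(x$profile, digits = 4)
  invisible(x)
}

#' Compare mean SGS between ontogenetic stages
#'
#' Two-sided independent-samples Student t-test (pooled variance) on the
#' per-population mean kinship values of the two stages.
#'
#' @param means_seedlings,means_adults numeric vectors (length >= 2) of
#'   per-population mean F_ij.
#' @return list with `t`, `df`, `p`, and the two group means.
#' @export
stage_mean_sgs_ttest <- function(means_seedlings, means_adults) {
  x <- means_seedlings; y <- means_adults
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = n1 + n2 - 2, p = 1,
                  mean_seedlings = mean(x), mean_adults = mean(y)))
    stop("zero variance in both groups with unequal means")
  }
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_seedlings = mean(x), mean_adults = mean(y))
}

#' Regress mean SGS on forest cover
#'
#' Ordinary least squares of per-population mean kinship on the landscape
#' forest-cover percentage, with the usual two-sided t-test on the slope.
#'
#' @param means per-population mean F_ij.
#' @param covers forest-cover percentages, same length (>= 3).
#' @return list with `slope`, `intercept`, `r_squared`, `p`.
#' @export
sgs_vs_cover_regression <- function(means, covers) {
  if (length(means) != length(covers) || length(means) < 3)
    stop("means and covers must have equal length >= 3")
  if (stats::var(covers) == 0) stop("covers are constant")
  if (stats::var(means) == 0)
    return(list(slope = 0, intercept = means[1], r_squared = 0, p = 1))
  fit <- stats::lm(means ~ covers)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2, 4])
}

#' SGS profiles for every site x stage population
#'
#' Convenience wrapper running [sgs_profile()] separately for each stage in
#' each site, the way the study analyses its populations. Populations with
#' fewer than 2 individuals are skipped with a message.
#'
#' @inheritParams sgs_profile
#' @param ds a full `study_dataset`.
#' @return data.frame with one row per site x stage x distance class
#'   (`site_id, stage, lower, upper, mean_fij, n_pairs, env_lo, env_hi`)
#'   plus attribute `"overall"`: per-population overall mean F_ij.
#' @export
sgs_all_populations <- function(ds, classes = distance_classes(),
                                n_perm = 10000, seed = NULL) {
  rows <- list(); overall <- list()
  k <- 0L
  for (s in ds$sites$site_id) for (st in c("seedling", "adult")) {
    keep <- ds$individuals$site_id == s & ds$individuals$stage == st
    if (sum(keep) < 2) {
      message("sgs_all_populations: skipping ", s, "/", st, " (n < 2)")
      next
    }
    k <- k + 1L
    sub <- subset_individuals(ds, keep)
    res <- sgs_profile(sub, classes = classes, n_perm = n_perm,
                       seed = if (is.null(seed)) NULL else seed + k)
    rows[[k]] <- cbind(site_id = s, stage = st, res$profile)
    overall[[k]] <- data.frame(site_id = s, stage = st, n = res$n,
                               overall_mean = res$overall_mean)
  }
  out <- do.call(rbind, rows)
  attr(out, "overall") <- do.call(rbind, overall)
  out
}
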