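# closed-form values below follow from the single-locus estimator
# f = [sum_a (p_i - pbar)(p_j - pbar) + w/(n-1)] / w,  w = sum_a pbar(1-pbar)

test_that("single-locus kinship matches hand evaluation at a biallelic locus", {
  freqs <- structure(list(L = c("1" = 0.5, "2" = 0.5)),
                     class = "allele_freq_table")
  build <- function(g1, g2, n_pad) {
    # two focal individuals plus padding to set the sample size n
    g <- rbind(g1, g2,
               matrix(rep(c(1L, 2L), n_pad), ncol = 2, byrow = TRUE))
    colnames(g) <- c("L.a1", "L.a2")
    g
  }
  for (n_pad in c(0, 8, 400)) {
    n <- n_pad + 2
    f_opp <- pairwise_kinship_loiselle(build(c(1L, 1L), c(2L, 2L), n_pad),
                                       freqs)[1, 2]
    expect_equal(f_opp, -1 + 1 / (n - 1))
    f_same <- pairwise_kinship_loiselle(build(c(1L, 1L), c(1L, 1L), n_pad),
                                        freqs)[1, 2]
    expect_equal(f_same, 1 + 1 / (n - 1))
  }
})

test_that("kinship matrix is symmetric, locus-order invariant, and ignores monomorphic loci", {
  ds <- make_tiny_dataset()
  freqs <- freqs_from_matrix(ds$genotypes, names(ds$loci))
  fij <- pairwise_kinship_loiselle(ds, freqs)
  expect_equal(fij, t(fij))
  expect_true(all(is.na(diag(fij))))
  # permute locus order
  perm <- c("LC", "LA", "LB")
  cols <- as.vector(rbind(paste0(perm, ".a1"), paste0(perm, ".a2")))
  fij2 <- pairwise_kinship_loiselle(ds$genotypes[, cols], freqs[perm])
  expect_equal(fij2, fij)
  # add a monomorphic locus: zero weight, multilocus value unchanged
  g3 <- cbind(ds$genotypes, LM.a1 = 500L, LM.a2 = 500L)
  f3 <- c(freqs, list(LM = c("500" = 1)))
  expect_equal(pairwise_kinship_loiselle(g3, f3), fij)
})

test_that("pairwise kinship equals the brute-force oracle on mixed data", {
  ds <- make_tiny_dataset()
  freqs <- freqs_from_matrix(ds$genotypes, names(ds$loci))
  fij <- pairwise_kinship_loiselle(ds, freqs)
  n <- nrow(ds$genotypes)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    expect_equal(fij[i, j], oracle_loiselle_pair(ds$genotypes, i, j, freqs),
                 tolerance = 1e-12)
})

test_that("SGS class means agree with a naive double loop (n = 6)", {
  set.seed(42)
  sim <- simulate_dataset(small_sim_config(seed = 5))
  sub <- subset_individuals(sim$dataset,
                            which(sim$dataset$individuals$stage == "adult" &
                                    sim$dataset$individuals$site_id == "A20")[1:6])
  spec <- distance_classes(seq(0, 400, by = 50))
  res <- sgs_profile(sub, spec, n_perm = 50, seed = 1)
  # naive recomputation
  freqs <- freqs_from_matrix(sub$genotypes, names(sub$loci))
  fij <- pairwise_kinship_loiselle(sub, freqs)
  sums <- numeric(8); cnt <- numeric(8); allf <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    d <- sqrt((sub$individuals$x[i] - sub$individuals$x[j])^2 +
                (sub$individuals$y[i] - sub$individuals$y[j])^2)
    allf <- c(allf, fij[i, j])
    k <- floor(d / 50) + 1
    if (k <= 8) { sums[k] <- sums[k] + fij[i, j]; cnt[k] <- cnt[k] + 1 }
  }
  naive <- ifelse(cnt > 0, sums / cnt, NA)
  expect_equal(res$profile$mean_fij, naive)
  expect_equal(res$profile$n_pairs, cnt)
  expect_equal(res$overall_mean, mean(allf))
  expect_equal(sum(res$profile$n_pairs) + res$n_pairs_out_of_range,
               choose(6, 2))
})

test_that("colocated individuals give one occupied class and a degenerate envelope", {
  ds <- make_tiny_dataset()
  sub <- subset_individuals(ds, ds$individuals$site_id == "S1" &
                              ds$individuals$stage == "adult")
  sub$individuals$x <- 0; sub$individuals$y <- 0
  res <- sgs_profile(sub, n_perm = 200, seed = 3)
  expect_equal(sum(res$profile$n_pairs > 0), 1)
  occ <- which(res$profile$n_pairs > 0)
  # every permutation reproduces the observed configuration
  expect_equal(res$profile$env_lo[occ], res$profile$mean_fij[occ])
  expect_equal(res$profile$env_hi[occ], res$profile$mean_fij[occ])
  expect_true(all(res$profile$degenerate[-occ]))
})

test_that("permutation envelope has ~95% coverage on exchangeable data", {
  # genotypes independent of location: the observed class mean should fall
  # inside the 95% envelope about 95% of the time (scaled-down replication)
  set.seed(2026)
  n_rep <- 60
  inside <- 0; total <- 0
  sim <- simulate_dataset(small_sim_config(seed = 77))
  base <- subset_individuals(sim$dataset,
                             sim$dataset$individuals$site_id == "A40" &
                               sim$dataset$individuals$stage == "adult")
  for (r in seq_len(n_rep)) {
    shuffled <- base
    ord <- sample(nrow(base$individuals))
    shuffled$individuals$x <- base$individuals$x[ord]
    shuffled$individuals$y <- base$individuals$y[ord]
    res <- sgs_profile(shuffled, n_perm = 199, seed = 1000 + r)
    occ <- which(res$profile$n_pairs > 0)
    k <- occ[1]   # first occupied class per replicate
    total <- total + 1
    if (res$profile$mean_fij[k] >= res$profile$env_lo[k] &&
        res$profile$mean_fij[k] <= res$profile$env_hi[k])
      inside <- inside + 1
  }
  # binomial 99.9% band around 0.95 at 60 replicates
  expect_gte(inside, qbinom(0.0005, total, 0.95))
})

test_that("stage t-test matches the textbook formula and its limits", {
  # identical groups
  expect_equal(stage_mean_sgs_ttest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # complete separation with tiny jitter
  r <- stage_mean_sgs_ttest(c(0, 1e-9, -1e-9), c(1, 1 + 1e-9, 1 - 1e-9))
  expect_lt(r$p, 1e-10)
  # closed form on a constructed 2 x 9 fixture
  x <- c(0.001, 0.004, -0.002, 0.006, 0.003, 0.0, 0.002, 0.005, -0.001)
  y <- c(-0.003, -0.001, -0.005, 0.001, -0.002, -0.004, 0.0, -0.006, -0.002)
  r2 <- stage_mean_sgs_ttest(x, y)
  sp2 <- (8 * var(x) + 8 * var(y)) / 16
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 9))
  expect_equal(r2$t, t_hand)
  expect_equal(r2$df, 16)
  expect_equal(r2$p, 2 * pt(-abs(t_hand), 16))
  # degenerate: zero variance and unequal means
  expect_error(stage_mean_sgs_ttest(c(0, 0), c(1, 1)), "zero variance")
})

test_that("SGS-on-cover regression returns exact R-squared", {
  covers <- c(19, 28, 34, 43, 50, 59, 63, 70, 83)
  # suppress lm's "essentially perfect fit" chatter on the exact-line case
  expect_equal(suppressWarnings(
    sgs_vs_cover_regression(2 * covers, covers)$r_squared), 1)
  r <- sgs_vs_cover_regression(rep(0.005, 9), covers)
  expect_equal(r$r_squared, 0)
  set.seed(8)
  y <- rnorm(9)
  r2 <- sgs_vs_cover_regression(y, covers)
  sse <- sum(resid(lm(y ~ covers))^2); sst <- sum((y - mean(y))^2)
  expect_equal(r2$r_squared, 1 - sse / sst)
  expect_error(sgs_vs_cover_regression(y, rep(50, 9)), "constant")
})
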