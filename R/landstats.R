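#' Binomial GLM of presence/absence on forest cover
#'
#' Logistic regression of a per-landscape binary outcome (e.g. "at least one
#' seedling with an assigned parent") on the forest-cover percentage, with
#' the two-sided Wald z-test on the cover slope. Complete or quasi-complete
#' separation (a cover threshold exactly splitting the 0s and 1s) drives the
#' ML slope to infinity; it is detected from a near-zero residual deviance
#' and flagged, in which case the parametric p is reported as `NA` (the
#' deviance-based Monte Carlo test remains valid).
#'
#' @param presence vector of 0/1 responses.
#' @param covers forest-cover percentages, same length (>= 3).
#' @return object of class `glm_cover_result`: list with `intercept, slope,
#'   null_deviance, deviance, z, p, separation_flag, fit`.
#' @export
glm_binomial_presence <- function(presence, covers) {
  stopifnot(length(presence) == length(covers), length(covers) >= 3,
            all(presence %in% c(0, 1)))
  fit <- suppressWarnings(stats::glm(presence ~ covers, family = stats::binomial()))
  .glm_cover_result(fit, degenerate = length(unique(presence)) == 1)
}

#' Weighted binomial GLM of proportions on forest cover
#'
#' Events/trials logistic regression of per-landscape proportions (e.g.
#' assigned seedlings out of all seedlings) on forest cover, weighting each
#' landscape by its number of trials.
#'
#' @param successes,totals integer vectors, `0 <= successes <= totals`,
#'   `totals >= 1`.
#' @param covers forest-cover percentages, same length (>= 3).
#' @return a `glm_cover_result`, as in [glm_binomial_presence()].
#' @export
glm_binomial_proportion <- function(successes, totals, covers) {
  stopifnot(length(successes) == length(totals),
            length(successes) == length(covers), length(covers) >= 3)
  if (any(totals < 1)) stop("totals must be >= 1")
  if (any(successes < 0 | successes > totals))
    stop("successes must lie in [0, totals]")
  fit <- suppressWarnings(
    stats::glm(cbind(successes, totals - successes) ~ covers,
               family = stats::binomial()))
  degen <- all(successes == 0) || all(successes == totals)
  .glm_cover_result(fit, degenerate = degen)
}

.glm_cover_result <- function(fit, degenerate = FALSE) {
  co <- summary(fit)$coefficients
  sep <- !degenerate && stats::deviance(fit) < 1e-6 &&
    fit$null.deviance > 1e-6
  p <- if (sep || degenerate) NA_real_ else co["covers", "Pr(>|z|)"]
  z <- if (sep || degenerate) NA_real_ else co["covers", "z value"]
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 null_deviance = fit$null.deviance,
                 deviance = stats::deviance(fit),
                 z = z, p = p,
                 separation_flag = sep || degenerate,
                 fit = fit),
            class = "glm_cover_result")
}

#' @export
print.glm_cover_result <- function(x, ...) {
  cat("binomial GLM on forest cover: slope =", format(x$slope),
      " z =", format(x$z), " p =", format(x$p), "\n")
  if (x$separation_flag)
    cat("  [separation/degenerate response: parametric p unavailable]\n")
  invisible(x)
}

#' Monte Carlo randomization test of GLM deviance
#'
#' The study's bespoke significance test for the cover GLMs: (1) record the
#' residual deviance of the observed fit; (2) permute the response against
#' the covers; (3) refit the GLM; (4) record its deviance; significance is
#' the proportion of deviances less than or equal to the observed one, with
#' the observed arrangement counted as one of the possible outcomes (so
#' `p >= 1/(n_rand+1)`). For proportion responses, each proportion keeps its
#' total attached and (success, total) pairs are permuted as units.
#' Comparisons use raw `<=` with no numeric tolerance; near-degenerate
#' separated fits are thus distinguished at machine precision, mirroring the
#' original procedure. Non-converged randomization fits contribute the
#' deviance at their final IRLS iterate and are counted in `n_nonconverged`.
#'
#' @param response 0/1 vector (presence form) or success counts
#'   (proportion form).
#' @param totals `NULL` for the presence form; trial counts for the
#'   proportion form.
#' @param covers forest-cover percentages.
#' @param n_rand number of randomizations (study default 4999).
#' @param seed optional integer seed.
#' @return object of class `mc_test_result`: list with `observed_stat`
#'   (deviance), `p`, `n_randomizations`, `include_observed = TRUE`,
#'   `n_nonconverged`, `seed`.
#' @export
mc_glm_deviance_test <- function(response, totals = NULL, covers,
                                 n_rand = 4999, seed = NULL) {
  fit_dev <- function(y, tt) {
    f <- if (is.null(tt))
      suppressWarnings(stats::glm(y ~ covers, family = stats::binomial()))
    else
      suppressWarnings(stats::glm(cbind(y, tt - y) ~ covers,
                                  family = stats::binomial()))
    c(stats::deviance(f), f$converged)
  }
  obs <- fit_dev(response, totals)
  if (!is.null(seed)) set.seed(seed)
  n <- length(response)
  devs <- numeric(n_rand); nonconv <- !obs[2]
  for (r in seq_len(n_rand)) {
    idx <- sample.int(n)
    fd <- fit_dev(response[idx], if (is.null(totals)) NULL else totals[idx])
    devs[r] <- fd[1]
    if (!fd[2]) nonconv <- nonconv + 1L
  }
  if (nonconv > 0)
    message("mc_glm_deviance_test: ", nonconv,
            " fit(s) stopped at the iteration limit (separated ",
            "arrangements); their final-iterate deviances were used")
  structure(list(observed_stat = obs[1],
                 p = (1 + sum(devs <= obs[1])) / (n_rand + 1),
                 n_randomizations = n_rand, include_observed = TRUE,
                 n_nonconverged = as.integer(nonconv), seed = seed),
            class = "mc_test_result")
}

#' Monte Carlo randomization test of regression R-squared
#'
#' Significance of a simple linear regression of a response (e.g. log
#' gene-flow distance per seedling) on forest cover, by randomly reassigning
#' the landscape cover values: covers are permuted at the landscape level
#' (each landscape, and with it all its observations, receives one of the
#' observed cover values), the regression is refit, and significance is the
#' proportion of randomized R-squared values greater than or equal to the
#' observed one, observed arrangement included.
#'
#' @param y numeric response, one value per observation.
#' @param covers cover value of each observation's landscape.
#' @param landscape_ids optional landscape identifier per observation; when
#'   supplied, randomization permutes covers among landscapes (keeping
#'   within-landscape structure); when `NULL` each observation is its own
#'   landscape.
#' @inheritParams mc_glm_deviance_test
#' @return an `mc_test_result` with `observed_stat` = R-squared.
#' @export
mc_regression_r2_test <- function(y, covers, landscape_ids = NULL,
                                  n_rand = 4999, seed = NULL) {
  stopifnot(length(y) == length(covers), length(y) >= 3)
  if (stats::var(y) == 0) stop("constant response: R-squared undefined")
  if (is.null(landscape_ids)) landscape_ids <- seq_along(y)
  lid <- match(landscape_ids, unique(landscape_ids))
  land_cover <- covers[!duplicated(lid)]
  r2 <- function(cv) stats::cor(y, cv)^2   # R^2 of simple OLS = cor^2
  obs <- r2(covers)
  if (!is.null(seed)) set.seed(seed)
  vals <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    cv <- land_cover[sample.int(length(land_cover))][lid]
    vals[r] <- r2(cv)
  }
  structure(list(observed_stat = obs,
                 p = (1 + sum(vals >= obs)) / (n_rand + 1),
                 n_randomizations = n_rand, include_observed = TRUE,
                 n_nonconverged = 0L, seed = seed),
            class = "mc_test_result")
}

#' @export
print.mc_test_result <- function(x, ...) {
  cat("Monte Carlo test:", x$n_randomizations, "randomizations, observed",
      format(x$observed_stat), " p =", format(x$p), "\n")
  invisible(x)
}

#' Mixed model of log gene-flow distance on forest cover
#'
#' Random-intercept linear mixed model (REML, via \pkg{nlme}) of the natural
#' log of per-seedling gene-flow distance on the forest cover of the
#' seedling's landscape, with landscape identity as the random factor. The
#' fixed slope is tested with a two-sided t-ratio on
#' `df = n_obs - n_landscapes - 1` (an approximation; mixed-model degrees of
#' freedom are not uniquely defined).
#'
#' @param distances_m positive gene-flow distances in metres.
#' @param covers forest cover of each seedling's landscape.
#' @param landscape_ids landscape identifier per seedling (>= 2 distinct).
#' @return object of class `lmm_cover_result`: list with `slope, se, t, df,
#'   p, var_random, var_resid, n, n_landscapes`.
#' @export
lmm_log_distance <- function(distances_m, covers, landscape_ids) {
  stopifnot(length(distances_m) == length(covers),
            length(distances_m) == length(landscape_ids))
  if (any(distances_m <= 0)) stop("distances must be > 0")
  ng <- length(unique(landscape_ids))
  if (ng < 2)
    stop("a single landscape: random effect inestimable; ",
         "use a plain regression instead")
  logd <- log(distances_m)
  n <- length(logd)
  if (stats::var(logd) == 0)
    return(structure(list(slope = 0, se = NA_real_, t = 0, df = n - ng - 1,
                          p = 1, var_random = 0, var_resid = 0, n = n,
                          n_landscapes = ng),
                     class = "lmm_cover_result"))
  dat <- data.frame(logd = logd, cover = covers,
                    land = factor(landscape_ids))
  fit <- nlme::lme(logd ~ cover, random = ~ 1 | land, data = dat,
                   method = "REML")
  tt <- summary(fit)$tTable
  vc <- nlme::VarCorr(fit)
  slope <- tt["cover", "Value"]; se <- tt["cover", "Std.Error"]
  df <- n - ng - 1
  t <- slope / se
  structure(list(slope = slope, se = se, t = t, df = df,
                 p = 2 * stats::pt(-abs(t), df),
                 var_random = as.numeric(vc["(Intercept)", "Variance"]),
                 var_resid = as.numeric(vc["Residual", "Variance"]),
                 n = n, n_landscapes = ng),
            class = "lmm_cover_result")
}

#' Summarize parentage assignments per landscape
#'
#' Builds the study-style summary tables from an assignment list: per-site
#' counts of adults, seedlings, and seedlings with a parent assigned in the
#' same landscape, in another landscape, and overall; plus the list of
#' cross-landscape gene-flow records (progeny and parent covers, paternity
#' probability, between-landscape distance in km).
#'
#' @param assignments a `parentage_assignments` data.frame from
#'   [assign_parents()] (possibly empty).
#' @param ds the `study_dataset` the assignments were computed from.
#' @return list with `per_site` (data.frame, one row per site plus an
#'   `Overall` row), `cross_landscape` (data.frame of between-landscape
#'   records), and `overall_percent_assigned`.
#' @export
summarize_assignments <- function(assignments, ds) {
  ind <- ds$individuals
  sid <- stats::setNames(ind$site_id, ind$id)
  cov <- stats::setNames(ds$sites$forest_cover, ds$sites$site_id)
  assigned <- assignments[!is.na(assignments$parent_id), , drop = FALSE]
  per_site <- do.call(rbind, lapply(ds$sites$site_id, function(s) {
    sd_ids <- ind$id[ind$site_id == s & ind$stage == "seedling"]
    a <- assigned[assigned$offspring_id %in% sd_ids, , drop = FALSE]
    data.frame(site_id = s, forest_cover = unname(cov[s]),
               adults = sum(ind$site_id == s & ind$stage == "adult"),
               seedlings = length(sd_ids),
               same_landscape = sum(a$same_site),
               other_landscape = sum(!a$same_site),
               assigned = nrow(a), stringsAsFactors = FALSE)
  }))
  overall <- data.frame(site_id = "Overall", forest_cover = NA_real_,
                        adults = sum(per_site$adults),
                        seedlings = sum(per_site$seedlings),
                        same_landscape = sum(per_site$same_landscape),
                        other_landscape = sum(per_site$other_landscape),
                        assigned = sum(per_site$assigned))
  cross <- assigned[!assigned$same_site, , drop = FALSE]
  cross_landscape <- data.frame(
    progeny_id = cross$offspring_id,
    progeny_cover = unname(cov[sid[cross$offspring_id]]),
    parent_id = cross$parent_id,
    parent_cover = unname(cov[sid[cross$parent_id]]),
    pp = cross$pp,
    distance_km = cross$distance_m / 1000,
    stringsAsFactors = FALSE)
  pct <- if (overall$seedlings > 0)
    100 * overall$assigned / overall$seedlings else 0
  list(per_site = rbind(per_site, overall),
       cross_landscape = cross_landscape,
       overall_percent_assigned = pct)
}
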