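#' Pipeline configuration
#'
#' Bundles every analysis constant of the study design with its published
#' default: 10000 location permutations for the SGS envelopes, 10000
#' parentage simulations at a 0.01 per-locus error rate and 95% confidence,
#' a 0.5 parentage prior, 4999 Monte Carlo randomizations, a minimum of 5
#' individuals per stage per site, and eight 50-m distance classes spanning
#' 0--400 m. All are overridable. Input is either a simulation block or
#' paths to genotype/site files.
#'
#' @param simulation a [simulation_config()], or `NULL` when reading files.
#' @param genotypes_path,genotypes_dialect,sites_path file inputs (used when
#'   `simulation` is `NULL`).
#' @param do_sgs,do_parentage,do_landstats stage toggles.
#' @param n_perm,n_rand,n_sim,error_rate,prior,min_per_stage,confidence
#'   analysis constants (see Description).
#' @param class_breaks distance-class edges in metres.
#' @param n_candidates,prop_sampled parentage-simulation settings; default
#'   `n_candidates` is the number of sampled adults and `prop_sampled` 0.5.
#' @param seed top-level seed; per-stage seeds are derived from it by a
#'   fixed linear rule so stages are independently reproducible.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            genotypes_path = NULL,
                            genotypes_dialect = "csv",
                            sites_path = NULL,
                            do_sgs = TRUE, do_parentage = TRUE,
                            do_landstats = TRUE,
                            n_perm = 10000, n_rand = 4999, n_sim = 10000,
                            error_rate = 0.01, prior = 0.5,
                            min_per_stage = 5, confidence = 0.95,
                            class_breaks = seq(0, 400, by = 50),
                            n_candidates = NULL, prop_sampled = 0.5,
                            seed = 1) {
  if (is.null(simulation) && is.null(genotypes_path))
    stop("either a simulation block or a genotypes path is required")
  structure(list(simulation = simulation,
                 genotypes_path = genotypes_path,
                 genotypes_dialect = genotypes_dialect,
                 sites_path = sites_path,
                 do_sgs = do_sgs, do_parentage = do_parentage,
                 do_landstats = do_landstats,
                 n_perm = n_perm, n_rand = n_rand, n_sim = n_sim,
                 error_rate = error_rate, prior = prior,
                 min_per_stage = min_per_stage, confidence = confidence,
                 class_breaks = class_breaks,
                 n_candidates = n_candidates, prop_sampled = prop_sampled,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulation:` mapping, if present, is passed to [simulation_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    if (!is.null(y$simulation$sites))
      y$simulation$sites <- as.data.frame(y$simulation$sites,
                                          stringsAsFactors = FALSE)
    y$simulation <- do.call(simulation_config, y$simulation)
  }
  do.call(pipeline_config, y)
}

# fixed per-stage seed derivation (kept below 2^31)
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 1L, sgs = 2L, parentage = 3L, landstats = 4L)
  (as.integer(seed) + 100003L * offs[[stage]]) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> site filtering -> SGS profiles -> parentage ->
#' landscape statistics, writing one CSV per product plus a JSON run
#' manifest (configuration, seed, versions). Deterministic given the
#' configuration and seed. A failing stage aborts with the stage name;
#' products of completed stages are retained on disk.
#'
#' @param cfg a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results
#'   (`dataset, ledger, sgs, assignments, summary, landstats`).
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  input <- stage("input", {
    if (!is.null(cfg$simulation)) {
      sim_cfg <- cfg$simulation
      sim_cfg$seed <- .stage_seed(cfg$seed, "simulate")
      sim <- simulate_dataset(sim_cfg)
      utils::write.csv(sim$ledger, file.path(out_dir, "truth_ledger.csv"),
                       row.names = FALSE)
      sim
    } else {
      list(dataset = load_genotypes(
        cfg$genotypes_path, cfg$genotypes_dialect,
        sites = if (is.null(cfg$sites_path)) NULL
        else load_site_table(cfg$sites_path)),
        ledger = NULL)
    }
  })
  res$ledger <- input$ledger
  ds <- input$dataset
  ds <- stage("filter", filter_sites_min_count(ds, cfg$min_per_stage))
  save_dataset(ds, file.path(out_dir, "dataset.csv"), dialect = "csv")
  res$dataset <- ds

  if (cfg$do_sgs) res$sgs <- stage("sgs", {
    prof <- sgs_all_populations(ds, distance_classes(cfg$class_breaks),
                                n_perm = cfg$n_perm,
                                seed = .stage_seed(cfg$seed, "sgs"))
    utils::write.csv(prof, file.path(out_dir, "sgs_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(prof, "overall"),
                     file.path(out_dir, "sgs_overall.csv"),
                     row.names = FALSE)
    prof
  })

  if (cfg$do_parentage) res <- c(res, stage("parentage", {
    freqs <- .augmented_adult_freqs(ds)
    n_cand <- if (is.null(cfg$n_candidates))
      sum(ds$individuals$stage == "adult") else cfg$n_candidates
    crit <- simulate_critical_delta(
      freqs, n_candidates = n_cand, prop_sampled = cfg$prop_sampled,
      error_rate = cfg$error_rate, n_sim = cfg$n_sim,
      confidence = cfg$confidence,
      seed = .stage_seed(cfg$seed, "parentage"))
    asg <- assign_parents(ds, crit, freqs = freqs,
                          error_rate = cfg$error_rate, prior = cfg$prior)
    utils::write.csv(asg, file.path(out_dir, "assignments.csv"),
                     row.names = FALSE)
    summ <- summarize_assignments(asg, ds)
    utils::write.csv(summ$per_site, file.path(out_dir, "counts_table.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$cross_landscape,
                     file.path(out_dir, "geneflow_table.csv"),
                     row.names = FALSE)
    list(critical_delta = crit, assignments = asg, summary = summ)
  }))

  if (cfg$do_landstats && cfg$do_parentage) res$landstats <-
    stage("landstats", {
      out <- landscape_tests(res$summary, res$assignments, ds,
                             n_rand = cfg$n_rand,
                             seed = .stage_seed(cfg$seed, "landstats"))
      utils::write.csv(out, file.path(out_dir, "landstats.csv"),
                       row.names = FALSE)
      out
    })

  manifest <- list(package = "palmflow",
                   version = as.character(utils::packageVersion("palmflow")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = cfg$seed,
                   config = .serialize_config(cfg),
                   config_hash = .config_hash(cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Forest-cover tests on an assignment summary
#'
#' Runs the six presence/proportion GLMs with their Monte Carlo deviance
#' tests, and (when at least two landscapes carry assignments) the mixed
#' model and R-squared randomization on log gene-flow distance.
#'
#' @param summ result of [summarize_assignments()].
#' @param assignments the `parentage_assignments` behind `summ`.
#' @param ds the `study_dataset`.
#' @param n_rand randomizations per Monte Carlo test.
#' @param seed integer seed (each test derives its own offset stream).
#' @return data.frame: one row per test with `test, statistic, value,
#'   p_parametric, p_mc`.
#' @export
landscape_tests <- function(summ, assignments, ds, n_rand = 4999,
                            seed = NULL) {
  tab <- summ$per_site
  tab <- tab[tab$site_id != "Overall", ]
  covers <- tab$forest_cover
  rows <- list(); k <- 0L
  add <- function(test, stat, value, pp, pmc) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(test = test, statistic = stat, value = value,
                             p_parametric = pp, p_mc = pmc)
  }
  variants <- list(assigned = tab$assigned,
                   same_landscape = tab$same_landscape,
                   other_landscape = tab$other_landscape)
  for (v in names(variants)) {
    cnt <- variants[[v]]
    g <- glm_binomial_presence(as.integer(cnt > 0), covers)
    mc <- mc_glm_deviance_test(as.integer(cnt > 0), NULL, covers,
                               n_rand = n_rand,
                               seed = if (is.null(seed)) NULL else seed + k)
    add(paste0("presence_", v), "deviance", g$deviance, g$p, mc$p)
    g2 <- glm_binomial_proportion(cnt, tab$seedlings, covers)
    mc2 <- mc_glm_deviance_test(cnt, tab$seedlings, covers, n_rand = n_rand,
                                seed = if (is.null(seed)) NULL else seed + k)
    add(paste0("proportion_", v), "deviance", g2$deviance, g2$p, mc2$p)
  }
  asg <- assignments[!is.na(assignments$parent_id) &
                       assignments$distance_m > 0, , drop = FALSE]
  land <- ds$individuals$site_id[match(asg$offspring_id, ds$individuals$id)]
  cov_of <- stats::setNames(ds$sites$forest_cover, ds$sites$site_id)
  if (nrow(asg) >= 3 && length(unique(land)) >= 2) {
    lmm <- lmm_log_distance(asg$distance_m, unname(cov_of[land]), land)
    mcr <- mc_regression_r2_test(log(asg$distance_m), unname(cov_of[land]),
                                 landscape_ids = land, n_rand = n_rand,
                                 seed = if (is.null(seed)) NULL
                                 else seed + k)
    add("geneflow_distance", "slope", lmm$slope, lmm$p, mcr$p)
  }
  do.call(rbind, rows)
}

.serialize_config <- function(cfg) {
  x <- unclass(cfg)
  if (!is.null(x$simulation)) {
    s <- unclass(x$simulation)
    s$sites <- NULL
    x$simulation <- s
  }
  x
}

# small order-sensitive FNV-style hash of the deparsed configuration
.config_hash <- function(cfg) {
  txt <- paste(deparse(.serialize_config(cfg)), collapse = "")
  h <- 2166136261
  for (v in utf8ToInt(txt)) h <- ((h * 16777619) + v) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Command-line entry point
#'
#' Subcommands `simulate`, `sgs`, `parentage`, `landstats`, `all` (all of
#' them run the stages of [run_pipeline()] with the matching toggles).
#' Usage: `palmflow <subcommand> --config cfg.yaml --out results/
#' [--seed N]`. Installed at `inst/cli/palmflow.R`; run with `Rscript`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   [commandArgs()] trailing arguments).
#' @return exit status 0 on success (invisibly).
#' @export
palmflow_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: palmflow <simulate|sgs|parentage|landstats|all> ",
         "--config cfg.yaml --out dir [--seed N]")
  sub <- args[1]; args <- args[-1]
  opt <- list(config = NULL, out = "palmflow_results", seed = NULL)
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option --", key)
    opt[[key]] <- args[i + 1]; i <- i + 2
  }
  if (is.null(opt$config)) stop("--config is required")
  cfg <- read_pipeline_config(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  toggles <- switch(sub,
                    simulate = c(FALSE, FALSE, FALSE),
                    sgs = c(TRUE, FALSE, FALSE),
                    parentage = c(FALSE, TRUE, FALSE),
                    landstats = c(FALSE, TRUE, TRUE),
                    all = c(TRUE, TRUE, TRUE),
                    stop("unknown subcommand: ", sub))
  cfg$do_sgs <- toggles[1]; cfg$do_parentage <- toggles[2]
  cfg$do_landstats <- toggles[3]
  run_pipeline(cfg, opt$out)
  message("palmflow: wrote results to ", opt$out)
  invisible(0L)
}
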