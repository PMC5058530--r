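#' Read a genotype file in the CSV or GenePop dialect
#'
#' The long CSV dialect carries everything in one file: columns
#' `individual_id, site_id, stage, x, y` followed by two columns per locus
#' (`LOCUS.a1`, `LOCUS.a2`); missing calls are empty cells. The GenePop
#' dialect (2- or 3-digit-per-allele coding, `Pop`-delimited blocks mapped to
#' sites) lacks stage and coordinates, so a companion CSV
#' (`individual_id, site_id, stage, x, y`) must be supplied; missing calls
#' are `0000`/`000000`.
#'
#' @param path path to the genotype file.
#' @param dialect `"csv"` or `"genepop"`.
#' @param companion path to the companion metadata CSV (GenePop only; by
#'   default `<path>_individuals.csv` is used when it exists).
#' @param sites optional site table (`data.frame` as in [load_site_table()]);
#'   by default `<path>_sites.csv` is read when it exists.
#' @return a `study_dataset`.
#' @export
load_genotypes <- function(path, dialect = c("csv", "genepop"),
                           companion = NULL, sites = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sites)) {
    sp <- paste0(path, "_sites.csv")
    if (file.exists(sp)) sites <- load_site_table(sp)
  }
  switch(dialect,
         csv = read_genotypes_csv(path, sites = sites),
         genepop = read_genepop(path, companion = companion, sites = sites))
}

#' Write a study dataset to disk
#'
#' Writes the genotype file in the requested dialect plus two side-car files:
#' `<path>_individuals.csv` (GenePop only; id, site, stage, coordinates) and
#' `<path>_sites.csv` (site table). `save_dataset` followed by
#' [load_genotypes()] is the identity on any valid dataset.
#'
#' @param ds a `study_dataset`.
#' @param path output path for the genotype file.
#' @param dialect `"csv"` or `"genepop"`.
#' @param digits alleles-per-field digits for GenePop (2 or 3; default 3).
#' @return `path`, invisibly.
#' @export
save_dataset <- function(ds, path, dialect = c("csv", "genepop"), digits = 3) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") write_genotypes_csv(ds, path)
  else write_genepop(ds, path, digits = digits)
  utils::write.csv(ds$sites, paste0(path, "_sites.csv"), row.names = FALSE)
  invisible(path)
}

read_genotypes_csv <- function(path, sites = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("individual_id", "site_id", "stage", "x", "y")
  if (!all(meta_cols %in% names(df)))
    stop("CSV dialect requires columns ", paste(meta_cols, collapse = ", "))
  gcols <- setdiff(names(df), meta_cols)
  if (length(gcols) %% 2 != 0 ||
      !all(grepl("\\.a[12]$", gcols)))
    stop("genotype columns must come in <locus>.a1/<locus>.a2 pairs")
  locus_names <- unique(sub("\\.a[12]$", "", gcols))
  geno <- as.matrix(df[, as.vector(rbind(paste0(locus_names, ".a1"),
                                         paste0(locus_names, ".a2")))])
  suppressWarnings(storage.mode(geno) <- "integer")
  bad <- which(is.na(geno) & !(df[, colnames(geno)] == "" |
                                 is.na(df[, colnames(geno)])), arr.ind = TRUE)
  if (nrow(bad))
    stop("malformed allele field at line ", bad[1, 1] + 1L,
         " column ", colnames(geno)[bad[1, 2]])
  loci <- lapply(locus_names, function(l) {
    sort(unique(c(geno[, paste0(l, ".a1")], geno[, paste0(l, ".a2")])))
  })
  loci <- lapply(loci, function(a) a[!is.na(a)])
  names(loci) <- locus_names
  ind <- data.frame(id = as.character(df$individual_id),
                    site_id = as.character(df$site_id),
                    stage = df$stage,
                    x = as.numeric(df$x), y = as.numeric(df$y),
                    stringsAsFactors = FALSE)
  study_dataset(loci, ind, geno, sites)
}

write_genotypes_csv <- function(ds, path) {
  df <- data.frame(individual_id = ds$individuals$id,
                   site_id = ds$individuals$site_id,
                   stage = ds$individuals$stage,
                   x = ds$individuals$x, y = ds$individuals$y,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ds$genotypes))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

read_genepop <- function(path, companion = NULL, sites = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("not a GenePop file: ", path)
  lines <- lines[nzchar(trimws(lines))]
  pop_idx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_idx)) stop("no 'Pop' delimiter found in ", path)
  header <- lines[2:(pop_idx[1] - 1)]
  locus_names <- trimws(unlist(strsplit(header, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  blocks <- split(
    setdiff(seq(pop_idx[1] + 1L, length(lines)), pop_idx),
    findInterval(setdiff(seq(pop_idx[1] + 1L, length(lines)), pop_idx),
                 pop_idx))
  ids <- character(0); site_ids <- character(0)
  geno_rows <- list()
  for (b in seq_along(blocks)) {
    for (li in blocks[[b]]) {
      parts <- strsplit(lines[li], ",")[[1]]
      if (length(parts) != 2)
        stop("malformed GenePop line ", li, ": expected 'id , alleles'")
      id <- trimws(parts[1])
      fields <- strsplit(trimws(parts[2]), "\\s+")[[1]]
      if (length(fields) != length(locus_names))
        stop("line ", li, ": ", length(fields), " allele fields for ",
             length(locus_names), " loci")
      w <- unique(nchar(fields))
      if (length(w) != 1 || !w %in% c(4L, 6L) ||
          any(grepl("\\D", fields)))
        stop("malformed allele field at line ", li)
      d <- w / 2L
      a1 <- as.integer(substr(fields, 1, d))
      a2 <- as.integer(substr(fields, d + 1, w))
      a1[a1 == 0L] <- NA; a2[a2 == 0L] <- NA
      if (any(is.na(a1) != is.na(a2)))
        stop("half-missing call at line ", li)
      ids <- c(ids, id); site_ids <- c(site_ids, paste0("pop", b))
      geno_rows[[length(geno_rows) + 1L]] <- as.vector(rbind(a1, a2))
    }
  }
  geno <- do.call(rbind, geno_rows)
  colnames(geno) <- as.vector(rbind(paste0(locus_names, ".a1"),
                                    paste0(locus_names, ".a2")))
  if (is.null(companion)) {
    cp <- paste0(path, "_individuals.csv")
    if (file.exists(cp)) companion <- cp
  }
  if (!is.null(companion)) {
    meta <- utils::read.csv(companion, stringsAsFactors = FALSE)
    m <- match(ids, meta$individual_id)
    if (anyNA(m)) stop("companion file misses individual ", ids[is.na(m)][1])
    ind <- data.frame(id = ids, site_id = as.character(meta$site_id[m]),
                      stage = meta$stage[m],
                      x = as.numeric(meta$x[m]), y = as.numeric(meta$y[m]),
                      stringsAsFactors = FALSE)
    # restore the companion's row order (GenePop groups by Pop block, which
    # need not match the original dataset order)
    ord <- order(m)
    ind <- ind[ord, , drop = FALSE]
    rownames(ind) <- NULL
    geno <- geno[ord, , drop = FALSE]
  } else {
    ind <- data.frame(id = ids, site_id = site_ids, stage = "adult",
                      x = 0, y = 0, stringsAsFactors = FALSE)
  }
  loci <- lapply(locus_names, function(l) {
    a <- c(geno[, paste0(l, ".a1")], geno[, paste0(l, ".a2")])
    sort(unique(a[!is.na(a)]))
  })
  names(loci) <- locus_names
  study_dataset(loci, ind, geno, sites)
}

write_genepop <- function(ds, path, digits = 3) {
  stopifnot(digits %in% c(2, 3))
  if (max(unlist(ds$loci)) >= 10^digits)
    stop("allele labels exceed ", digits, "-digit GenePop coding")
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    formatC(a, width = digits, flag = "0")
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines("palmflow export", con)
  writeLines(names(ds$loci), con)
  for (s in ds$sites$site_id) {
    rows <- which(ds$individuals$site_id == s)
    if (!length(rows)) next
    writeLines("Pop", con)
    for (i in rows) {
      g <- ds$genotypes[i, ]
      a1 <- g[seq(1, length(g), 2)]; a2 <- g[seq(2, length(g), 2)]
      writeLines(paste0(ds$individuals$id[i], " ,  ",
                        paste0(fmt(a1), fmt(a2), collapse = " ")), con)
    }
  }
  # individual metadata side-car: GenePop itself has no stage/coordinates
  meta <- data.frame(individual_id = ds$individuals$id,
                     site_id = ds$individuals$site_id,
                     stage = ds$individuals$stage,
                     x = ds$individuals$x, y = ds$individuals$y)
  utils::write.csv(meta, paste0(path, "_individuals.csv"), row.names = FALSE)
  invisible(path)
}

#' Load a site table
#'
#' @param path CSV with columns `site_id, centroid_x, centroid_y,
#'   forest_cover` (cover as percent in \[0, 100\]).
#' @return a validated `data.frame` of site records (possibly empty).
#' @export
load_site_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  need <- c("site_id", "centroid_x", "centroid_y", "forest_cover")
  if (length(readLines(path, n = 2)) < 2)   # empty or header-only file
    return(stats::setNames(
      data.frame(character(0), numeric(0), numeric(0), numeric(0)), need))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(stats::setNames(
      data.frame(character(0), numeric(0), numeric(0), numeric(0)), need))
  if (!all(need %in% names(df)))
    stop("site table requires columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$site_id))
    stop("duplicate site_id: ", df$site_id[duplicated(df$site_id)][1])
  if (any(df$forest_cover < 0 | df$forest_cover > 100))
    stop("forest_cover outside [0, 100]")
  if (anyDuplicated(df[, c("centroid_x", "centroid_y")]))
    stop("site centroids must be pairwise distinct")
  df <- df[, need]
  df$centroid_x <- as.numeric(df$centroid_x)
  df$centroid_y <- as.numeric(df$centroid_y)
  df$forest_cover <- as.numeric(df$forest_cover)
  df
}
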