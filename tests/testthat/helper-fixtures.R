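# in-code fixtures shared across test files

# a tiny two-site dataset built by hand: 3 loci, 6 adults + 5 seedlings
make_tiny_dataset <- function() {
  loci <- list(LA = c(100L, 102L, 104L), LB = c(200L, 202L),
               LC = c(300L, 302L, 304L))
  ind <- data.frame(
    id = c(sprintf("S1_A%d", 1:4), sprintf("S2_A%d", 1:2),
           sprintf("S1_S%d", 1:3), sprintf("S2_S%d", 1:2)),
    site_id = c(rep("S1", 4), rep("S2", 2), rep("S1", 3), rep("S2", 2)),
    stage = c(rep("adult", 6), rep("seedling", 5)),
    x = c(0, 10, 20, 30, 1000, 1010, 5, 15, 25, 1002, 1008),
    y = c(0, 1, 2, 3, 0, 1, 0.5, 1.5, 2.5, 0.2, 0.8),
    stringsAsFactors = FALSE)
  geno <- rbind(
    c(100, 100, 200, 202, 300, 302),
    c(100, 102, 200, 200, 302, 304),
    c(102, 104, 202, 202, 300, 300),
    c(100, 104, 200, 202, 304, 304),
    c(102, 102, 200, 200, 300, 304),
    c(104, 104, 202, 202, 302, 302),
    c(100, 102, 200, 202, 300, 304),
    c(100, 100, 200, 200, NA, NA),
    c(102, 104, 200, 202, 300, 302),
    c(102, 102, 200, 200, 300, 304),
    c(102, 104, 200, 202, 302, 302))
  colnames(geno) <- c("LA.a1", "LA.a2", "LB.a1", "LB.a2", "LC.a1", "LC.a2")
  sites <- data.frame(site_id = c("S1", "S2"),
                      centroid_x = c(0, 1000), centroid_y = c(0, 0),
                      forest_cover = c(30, 70))
  study_dataset(loci, ind, geno, sites)
}

# a scaled-down simulation configuration for fast tests
small_sim_config <- function(seed = 1, ...) {
  simulation_config(covers = c(20, 40, 60, 80),
                    adults_per_site = c(20, 20, 20, 20),
                    seedlings_per_site = c(15, 15, 15, 15),
                    sites = data.frame(
                      site_id = c("A20", "A40", "A60", "A80"),
                      centroid_x = c(0, 4000, 0, 6000),
                      centroid_y = c(0, 0, 5000, 4000),
                      forest_cover = c(20, 40, 60, 80)),
                    seed = seed, ...)
}

# independent brute-force Loiselle kinship for one pair (oracle)
oracle_loiselle_pair <- function(geno, i, j, freqs) {
  locus_names <- unique(sub("\\.a[12]$", "", colnames(geno)))
  num <- 0; den <- 0
  for (l in locus_names) {
    p <- freqs[[l]]
    w <- sum(p * (1 - p))
    if (w <= 0) next
    a1 <- geno[, paste0(l, ".a1")]; a2 <- geno[, paste0(l, ".a2")]
    if (is.na(a1[i]) || is.na(a1[j])) next
    nl <- sum(!is.na(a1))
    if (nl < 2) next
    s <- 0
    for (a in names(p)) {
      pia <- (sum(as.character(c(a1[i], a2[i])) == a)) / 2
      pja <- (sum(as.character(c(a1[j], a2[j])) == a)) / 2
      s <- s + (pia - p[[a]]) * (pja - p[[a]])
    }
    num <- num + s + w / (nl - 1)
    den <- den + w
  }
  if (den == 0) NA_real_ else num / den
}

# enumeration oracle for the single-parent transmission probability:
# candidate transmits each of its two alleles with prob 1/2, the other
# parental allele is drawn from the reference frequencies
oracle_transmission <- function(o1, o2, c1, c2, p) {
  tot <- 0
  for (tx in c(c1, c2)) for (a in names(p)) {
    got <- sort(c(tx, as.integer(a)))
    if (identical(got, sort(c(o1, o2)))) tot <- tot + 0.5 * p[[a]]
  }
  tot
}

table1 <- function() study_counts()
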