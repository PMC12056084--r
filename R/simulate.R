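# Mendelian simulator of divergent parental pools and known hybrid
# classes. Sites are simulated unlinked; each operation seeds the global
# RNG once when a seed is given, so runs are exactly reproducible.

#' Simulation configuration
#'
#' @param n_sites Total number of biallelic sites.
#' @param n_fixed_diff Number of sites fixed for alternate alleles between
#'   the two parental populations (true delta = 1).
#' @param n_per_parental Individuals simulated per parental population.
#' @param spectrum List with elements `p1` and `p2`, each a pair of Beta
#'   shape parameters for the alternate-allele frequency at non-fixed
#'   sites in that population. The default `c(1, 1)` (uniform) yields a
#'   broad spread of true delta values between 0 and 1.
#' @param depth Optional sequencing depth to apply to the parental pools
#'   via [downsample_depth()]; `NULL` keeps true genotypes.
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 1000, n_fixed_diff = 100,
                       n_per_parental = 20,
                       spectrum = list(p1 = c(1, 1), p2 = c(1, 1)),
                       depth = NULL, seed = NULL) {
  stopifnot(n_sites >= 1, n_fixed_diff >= 0, n_per_parental >= 1)
  if (n_fixed_diff > n_sites) {
    stop("`n_fixed_diff` cannot exceed `n_sites`", call. = FALSE)
  }
  for (p in c("p1", "p2")) {
    sh <- spectrum[[p]]
    if (length(sh) != 2 || any(!is.finite(sh)) || any(sh <= 0)) {
      stop("spectrum parameters must be two positive Beta shapes per ",
           "population", call. = FALSE)
    }
  }
  if (!is.null(depth) && (depth < 1 || depth != round(depth))) {
    stop("`depth` must be a positive integer or NULL", call. = FALSE)
  }
  structure(
    list(n_sites = as.integer(n_sites),
         n_fixed_diff = as.integer(n_fixed_diff),
         n_per_parental = as.integer(n_per_parental),
         spectrum = spectrum, depth = depth, seed = seed),
    class = "sim_config"
  )
}

#' Simulate two divergent parental pools
#'
#' Draws per-population true alternate-allele frequencies (fixed
#' differences first: 0 in P1, 1 in P2; remaining sites from the
#' configured Beta spectrum), then each individual's genotype as two
#' binomial allele copies at its population frequency. The site table
#' carries the simulation truth in `true_freq_p1` / `true_freq_p2`.
#'
#' @param cfg A [sim_config()].
#' @return List with `geno` (a [geno_matrix()]) and `popmap` (populations
#'   `"P1"` and `"P2"`).
#' @export
simulate_parental_pools <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ns <- cfg$n_sites
  nf <- cfg$n_fixed_diff
  nv <- ns - nf
  fp1 <- c(rep(0, nf), rbeta(nv, cfg$spectrum$p1[1], cfg$spectrum$p1[2]))
  fp2 <- c(rep(1, nf), rbeta(nv, cfg$spectrum$p2[1], cfg$spectrum$p2[2]))
  n <- cfg$n_per_parental
  draw_pop <- function(f, prefix) {
    g <- matrix(rbinom(n * ns, 2, rep(f, each = n)), nrow = n,
                dimnames = list(sprintf("%s_%02d", prefix, seq_len(n)), NULL))
    g
  }
  geno <- rbind(draw_pop(fp1, "P1"), draw_pop(fp2, "P2"))
  sites <- data.frame(
    chrom = "chr1", pos = seq_len(ns),
    ref = "A", alt = "T",
    true_freq_p1 = fp1, true_freq_p2 = fp2,
    stringsAsFactors = FALSE
  )
  g <- geno_matrix(geno, sites)
  if (!is.null(cfg$depth)) g <- downsample_depth(g, cfg$depth)
  pm <- popmap(individual_ids(g),
               rep(c("P1", "P2"), each = n), p1 = "P1", p2 = "P2")
  list(geno = g, popmap = pm)
}

#' Cross two diploid individuals
#'
#' At every site the offspring receives one allele drawn uniformly from
#' each parent's two copies, independently across sites. A site missing
#' in either parent is missing in the offspring. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param gA,gB Integer dosage vectors (0/1/2/`NA`) over the same sites.
#' @return Integer dosage vector for the offspring.
#' @export
cross_individuals <- function(gA, gB) {
  if (length(gA) != length(gB)) {
    stop("parents cover different site sets", call. = FALSE)
  }
  gamete <- function(g) {
    al <- g / 2                       # 0 or 1 for homozygotes
    het <- !is.na(g) & g == 1L
    al[het] <- rbinom(sum(het), 1, 0.5)
    al
  }
  off <- as.integer(gamete(gA) + gamete(gB))
  off[is.na(gA) | is.na(gB)] <- NA_integer_
  off
}

#' Build known hybrid classes from simulated parental pools
#'
#' Follows the standard construction: parental pairs (one from each
#' population, drawn without replacement where possible) produce F1s;
#' each F1 paired with a different F1 produces an F2; each F1 paired with
#' a randomly chosen parental individual produces a first-generation
#' backcross in each direction. Class labels are `F1`, `F2`, `BC1_P1`
#' (toward P1) and `BC1_P2`.
#'
#' @param parents A [geno_matrix()] of parental individuals.
#' @param pm The parental [popmap()].
#' @param n_per_class Hybrids per class (default 20).
#' @param seed Optional RNG seed.
#' @return List with `geno` (parents plus hybrids) and `popmap` (original
#'   parental labels plus the four class labels).
#' @export
make_hybrid_classes <- function(parents, pm, n_per_class = 20, seed = NULL) {
  stopifnot(n_per_class >= 1)
  if (!is.null(seed)) set.seed(seed)
  check_popmap(pm, parents)
  p1_ids <- intersect(parental_ids(pm, "p1"), individual_ids(parents))
  p2_ids <- intersect(parental_ids(pm, "p2"), individual_ids(parents))
  if (length(p1_ids) == 0 || length(p2_ids) == 0) {
    stop("each parental population needs at least one individual",
         call. = FALSE)
  }
  draw <- function(ids, n) {
    if (n <= length(ids)) sample(ids, n)
    else sample(ids, n, replace = TRUE)
  }
  pa <- draw(p1_ids, n_per_class)
  pb <- draw(p2_ids, n_per_class)
  f1 <- t(vapply(seq_len(n_per_class), function(i) {
    cross_individuals(parents$geno[pa[i], ], parents$geno[pb[i], ])
  }, integer(ncol(parents$geno))))

  # pair each F1 with another F1 (a cyclic shift guarantees distinct
  # partners whenever more than one F1 exists)
  partner <- if (n_per_class >= 2) c(seq_len(n_per_class)[-1], 1L)
             else 1L
  f2 <- t(vapply(seq_len(n_per_class), function(i) {
    cross_individuals(f1[i, ], f1[partner[i], ])
  }, integer(ncol(f1))))

  bc <- function(pool_ids) {
    mates <- draw(pool_ids, n_per_class)
    t(vapply(seq_len(n_per_class), function(i) {
      cross_individuals(f1[i, ], parents$geno[mates[i], ])
    }, integer(ncol(f1))))
  }
  bc1 <- bc(p1_ids)
  bc2 <- bc(p2_ids)

  tag <- function(m, lab) {
    rownames(m) <- sprintf("%s_%02d", lab, seq_len(nrow(m)))
    m
  }
  hyb <- rbind(tag(f1, "F1"), tag(f2, "F2"),
               tag(bc1, "BC1_P1"), tag(bc2, "BC1_P2"))
  geno <- geno_matrix(rbind(parents$geno, hyb), parents$sites)
  pm_out <- popmap(
    individual_ids(geno),
    c(pm$pop[match(individual_ids(parents), pm$id)],
      rep(c("F1", "F2", "BC1_P1", "BC1_P2"), each = n_per_class)),
    p1 = attr(pm, "p1"), p2 = attr(pm, "p2")
  )
  list(geno = geno, popmap = pm_out)
}

#' Downsample genotypes to a fixed sequencing depth
#'
#' Emulates low-coverage genotyping with no sequencing error: for each
#' non-missing genotype, `depth` alleles are drawn with replacement from
#' the individual's two copies; the site is recoded heterozygous if both
#' alleles are observed and homozygous for the observed allele otherwise.
#' Homozygous genotypes are unchanged (only one allele exists to draw),
#' so only true heterozygotes can be miscalled, always towards
#' homozygosity: at depth d a heterozygote survives with probability
#' `1 - 2^(1 - d)`.
#'
#' @param g A [geno_matrix()].
#' @param depth Positive integer number of allele draws per genotype.
#' @param seed Optional RNG seed.
#' @return A [geno_matrix()] with recoded genotypes.
#' @export
downsample_depth <- function(g, depth, seed = NULL) {
  if (length(depth) != 1 || depth < 1 || depth != round(depth)) {
    stop("`depth` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  geno <- g$geno
  het <- which(!is.na(geno) & geno == 1L)
  if (length(het)) {
    n_alt <- rbinom(length(het), depth, 0.5)
    geno[het] <- ifelse(n_alt == 0L, 0L,
                        ifelse(n_alt == depth, 2L, 1L))
  }
  geno_matrix(geno, g$sites)
}

#' Replicated subsampling of parental individuals
#'
#' For studying sample-size effects on AIM selection: each replicate keeps
#' `n` randomly chosen individuals per parental label as parentals and
#' relabels the remaining parental individuals `"<label>_excluded"` so
#' they keep riding along as non-parental samples. Non-parental
#' individuals are untouched.
#'
#' @param pm A [popmap()].
#' @param n Individuals to keep per parental population.
#' @param replicates Number of independent subsampling replicates.
#' @param seed Optional RNG seed.
#' @return List of `replicates` popmaps.
#' @export
subsample_parentals <- function(pm, n, replicates = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- parental_labels(pm)
  for (lab in labs) {
    size <- sum(pm$pop == lab)
    if (n > size) {
      stop(sprintf("n = %d exceeds the %d individuals in population '%s'",
                   n, size, lab), call. = FALSE)
    }
  }
  lapply(seq_len(replicates), function(r) {
    pop <- pm$pop
    for (lab in labs) {
      ids <- pm$id[pm$pop == lab]
      drop <- setdiff(ids, sample(ids, n))
      pop[pm$id %in% drop] <- paste0(lab, "_excluded")
    }
    popmap(pm$id, pop, p1 = labs[["p1"]], p2 = labs[["p2"]])
  })
}
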