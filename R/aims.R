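# Frequencies are kept as exact rational counts divided once; the delta
# threshold is compared with a small tolerance so true fixed differences
# are never lost to floating-point rounding.
DELTA_TOL <- 1e-12

#' Per-site alternate-allele frequencies within one population
#'
#' @param g A [geno_matrix()].
#' @param pop_individuals Ids of the individuals to pool.
#' @param min_alleles Minimum number of non-missing allele copies a site
#'   needs for its frequency to be defined (default 2, i.e. at least one
#'   genotyped individual).
#' @return Data frame with one row per site: `chrom`, `pos`, `freq`
#'   (alternate-allele frequency, `NA` where undefined) and `n_alleles`
#'   (non-missing allele copies used).
#' @export
allele_frequencies <- function(g, pop_individuals, min_alleles = 2) {
  if (length(pop_individuals) == 0) {
    stop("population has no individuals", call. = FALSE)
  }
  sub <- g$geno[match_ids(g, pop_individuals), , drop = FALSE]
  n_alleles <- 2L * colSums(!is.na(sub))
  freq <- colSums(sub, na.rm = TRUE) / n_alleles
  freq[n_alleles < min_alleles] <- NA_real_
  data.frame(chrom = g$sites$chrom, pos = g$sites$pos,
             freq = unname(freq), n_alleles = unname(n_alleles),
             stringsAsFactors = FALSE)
}

match_ids <- function(g, ids) {
  idx <- match(ids, individual_ids(g))
  if (anyNA(idx)) {
    stop("unknown individuals: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Allele-frequency difference (delta) between two parental populations
#'
#' Delta is the absolute difference in allele frequency at a site; a delta
#' of 1 is a fixed difference. Undefined wherever either input frequency
#' is undefined. Symmetric in its arguments.
#'
#' @param f1,f2 Frequency tables from [allele_frequencies()] over the same
#'   sites.
#' @return Numeric vector of per-site delta values (`NA` where undefined).
#' @export
allele_freq_diff <- function(f1, f2) {
  if (!identical(paste(f1$chrom, f1$pos), paste(f2$chrom, f2$pos))) {
    stop("frequency tables cover different site sets", call. = FALSE)
  }
  abs(f1$freq - f2$freq)
}

#' Select ancestry-informative markers above a delta threshold
#'
#' Retains the sites whose parental allele-frequency difference is defined
#' and at least `threshold` (inclusive, so `threshold = 1` keeps exactly
#' the fixed differences), and polarizes each retained site by the allele
#' with the strictly higher frequency in the `p2` group. Genotypes at AIMs
#' are recoded as counts of that P2-associated allele, so parental `p2`
#' individuals score towards 2 and `p1` individuals towards 0.
#'
#' @param g A [geno_matrix()].
#' @param pm A [popmap()] designating the two parental groups; every
#'   genotyped individual must be assigned to some population.
#' @param threshold Delta cutoff in `(0, 1]`.
#' @param min_alleles Passed to [allele_frequencies()].
#' @return An object of class `aim_set`: list with `geno` (individuals x
#'   AIMs matrix of P2-allele dosage), `sites` (AIM site table with
#'   `freq_p1`, `freq_p2`, `delta`, `p2_allele`), `threshold`, and the
#'   parental labels.
#' @export
select_aims <- function(g, pm, threshold = 1, min_alleles = 2) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("`threshold` must be a single value in (0, 1]", call. = FALSE)
  }
  check_popmap(pm, g)
  p1_ids <- intersect(parental_ids(pm, "p1"), individual_ids(g))
  p2_ids <- intersect(parental_ids(pm, "p2"), individual_ids(g))
  if (length(p1_ids) == 0 || length(p2_ids) == 0) {
    stop("each parental group needs at least one genotyped individual",
         call. = FALSE)
  }
  f1 <- allele_frequencies(g, p1_ids, min_alleles)
  f2 <- allele_frequencies(g, p2_ids, min_alleles)
  delta <- allele_freq_diff(f1, f2)
  keep <- !is.na(delta) & delta >= threshold - DELTA_TOL
  if (!any(keep)) {
    stop(sprintf(
      paste0("no AIMs at delta threshold %g; try a lower threshold ",
             "(max defined delta = %s)"),
      threshold,
      if (all(is.na(delta))) "none defined" else format(max(delta, na.rm = TRUE))
    ), call. = FALSE)
  }
  sites <- g$sites[keep, , drop = FALSE]
  sites$freq_p1 <- f1$freq[keep]
  sites$freq_p2 <- f2$freq[keep]
  sites$delta <- delta[keep]
  # delta > 0 forces a strict frequency ordering, so the P2-majority
  # allele is always well defined at retained sites.
  sites$p2_allele <- ifelse(sites$freq_p2 > sites$freq_p1, "alt", "ref")
  rownames(sites) <- NULL

  geno <- g$geno[, keep, drop = FALSE]
  flip <- sites$p2_allele == "ref"
  geno[, flip] <- 2L - geno[, flip, drop = FALSE]

  structure(
    list(geno = geno, sites = sites, threshold = threshold,
         p1 = attr(pm, "p1"), p2 = attr(pm, "p2")),
    class = "aim_set"
  )
}

#' @export
print.aim_set <- function(x, ...) {
  cat(sprintf(
    "aim_set: %d AIMs at delta >= %g (%d fixed differences), %d individuals\n",
    ncol(x$geno), x$threshold,
    sum(x$sites$delta >= 1 - DELTA_TOL), nrow(x$geno)
  ))
  invisible(x)
}

#' Genotype matrix restricted to the AIM sites
#'
#' Returns the AIMs in their original ref/alt encoding (undoing the P2
#' polarization), e.g. for writing an AIM-only VCF.
#'
#' @param aims An `aim_set`.
#' @return A [geno_matrix()] over the AIM sites.
#' @export
aims_as_geno_matrix <- function(aims) {
  geno <- aims$geno
  flip <- aims$sites$p2_allele == "ref"
  geno[, flip] <- 2L - geno[, flip, drop = FALSE]
  geno_matrix(geno, aims$sites[, c("chrom", "pos", "ref", "alt")])
}

#' Write the per-AIM site report
#'
#' One row per AIM: `chrom`, `pos`, `freq_p1`, `freq_p2`, `delta`,
#' `p2_allele`.
#'
#' @param aims An `aim_set`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_aim_report <- function(aims, path) {
  utils::write.table(
    aims$sites[, c("chrom", "pos", "freq_p1", "freq_p2", "delta", "p2_allele")],
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
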