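#' Hybrid index of individuals over an AIM set
#'
#' The hybrid index is the proportion of an individual's alleles at AIMs
#' that match the P2 parental group: the sum of P2-allele dosages over
#' non-missing AIM sites divided by twice the number of those sites.
#' P2-assigned parentals score 1 and P1 parentals 0. Undefined (`NA`) when
#' every AIM genotype is missing.
#'
#' @param aims An `aim_set` from [select_aims()].
#' @param individual Optional single id; default scores all individuals.
#' @return Named numeric vector of hybrid indices in `[0, 1]`.
#' @export
hybrid_index <- function(aims, individual = NULL) {
  geno <- pick_individual(aims, individual)
  n_called <- rowSums(!is.na(geno))
  hi <- rowSums(geno, na.rm = TRUE) / (2 * n_called)
  hi[n_called == 0] <- NA_real_
  hi
}

#' Interclass heterozygosity of individuals over an AIM set
#'
#' The proportion of an individual's non-missing AIM sites that are
#' heterozygous, i.e. carry one allele associated with each parental
#' group. On fixed-difference AIMs an F1 scores 1 and a parental 0.
#' Undefined (`NA`) when every AIM genotype is missing.
#'
#' @inheritParams hybrid_index
#' @return Named numeric vector in `[0, 1]`.
#' @export
interclass_heterozygosity <- function(aims, individual = NULL) {
  geno <- pick_individual(aims, individual)
  n_called <- rowSums(!is.na(geno))
  het <- rowSums(geno == 1L, na.rm = TRUE) / n_called
  het[n_called == 0] <- NA_real_
  het
}

pick_individual <- function(aims, individual) {
  if (is.null(individual)) return(aims$geno)
  idx <- match(individual, rownames(aims$geno))
  if (anyNA(idx)) {
    stop("unknown individual(s): ",
         paste(individual[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  aims$geno[idx, , drop = FALSE]
}

#' Assemble the per-individual triangle table
#'
#' One row per genotyped individual (parental or not): population label,
#' hybrid index, interclass heterozygosity, and percent missing AIM
#' genotypes. Each individual's estimates depend only on its own
#' genotypes, so rows are independent given the AIM set.
#'
#' @param aims An `aim_set` from [select_aims()].
#' @param pm The [popmap()] used to select the AIMs.
#' @param min_sites Optional minimum number of non-missing AIM sites an
#'   individual needs; individuals below it get `NA` estimates (rows are
#'   never dropped). Default 0 disables the filter.
#' @return Data frame of class `triangle_table` with columns `id`, `pop`,
#'   `hybrid_index`, `heterozygosity`, `perc_missing`.
#' @export
build_triangle_table <- function(aims, pm, min_sites = 0) {
  ids <- rownames(aims$geno)
  pop <- pm$pop[match(ids, pm$id)]
  n_called <- rowSums(!is.na(aims$geno))
  hi <- hybrid_index(aims)
  het <- interclass_heterozygosity(aims)
  low <- n_called < min_sites
  hi[low] <- NA_real_
  het[low] <- NA_real_
  out <- data.frame(
    id = ids,
    pop = pop,
    hybrid_index = unname(hi),
    heterozygosity = unname(het),
    perc_missing = unname(100 * (1 - n_called / ncol(aims$geno))),
    stringsAsFactors = FALSE
  )
  attr(out, "p1") <- aims$p1
  attr(out, "p2") <- aims$p2
  attr(out, "orientation") <- sprintf("hybrid_index: %s = 0, %s = 1",
                                      aims$p1, aims$p2)
  class(out) <- c("triangle_table", "data.frame")
  out
}
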