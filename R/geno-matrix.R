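#' Construct a genotype matrix of biallelic SNP dosages
#'
#' The central container of the package: an individuals x sites matrix of
#' alternate-allele counts (0, 1, 2) with `NA` for missing calls, plus a
#' site table carrying chromosome, position and the two alleles.
#'
#' @param geno Integer matrix, individuals in rows, sites in columns.
#'   Values must be 0, 1, 2 or `NA`. Row names are individual ids.
#' @param sites Data frame with one row per column of `geno` and columns
#'   `chrom`, `pos`, `ref`, `alt` (single-nucleotide alleles). Extra
#'   columns (e.g. simulation truth) are carried along untouched.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(geno, sites) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno))) {
    stop("`geno` must carry individual ids as row names", call. = FALSE)
  }
  if (anyDuplicated(rownames(geno))) {
    stop("individual ids must be unique", call. = FALSE)
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("`sites` needs columns chrom, pos, ref, alt", call. = FALSE)
  }
  if (nrow(sites) != ncol(geno)) {
    stop("`sites` must have one row per genotype column", call. = FALSE)
  }
  key <- paste(sites$chrom, sites$pos, sep = ":")
  if (anyDuplicated(key)) {
    stop("sites must be unique by (chrom, pos)", call. = FALSE)
  }
  colnames(geno) <- key
  rownames(sites) <- NULL
  structure(list(geno = geno, sites = sites), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno)) * 100
  cat(sprintf(
    "geno_matrix: %d individuals x %d biallelic sites (%.1f%% missing)\n",
    nrow(x$geno), ncol(x$geno), miss
  ))
  invisible(x)
}

#' Individual ids of a genotype container
#' @param g A `geno_matrix` or `aim_set`.
#' @return Character vector of ids in storage order.
#' @export
individual_ids <- function(g) rownames(g$geno)

#' Number of sites in a genotype container
#' @param g A `geno_matrix` or `aim_set`.
#' @return Integer site count.
#' @export
n_sites <- function(g) ncol(g$geno)

#' Subset a genotype matrix by individual
#'
#' @param g A `geno_matrix`.
#' @param ids Character vector of individual ids to keep, in the order given.
#' @return A `geno_matrix` restricted to `ids`.
#' @export
subset_individuals <- function(g, ids) {
  missing_ids <- setdiff(ids, individual_ids(g))
  if (length(missing_ids)) {
    stop("unknown individuals: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  geno_matrix(g$geno[ids, , drop = FALSE], g$sites)
}

#' Stack two genotype matrices over the same sites
#'
#' @param a,b `geno_matrix` objects with identical site tables.
#' @return A `geno_matrix` holding the individuals of both inputs.
#' @export
bind_individuals <- function(a, b) {
  if (!identical(colnames(a$geno), colnames(b$geno))) {
    stop("genotype matrices cover different site sets", call. = FALSE)
  }
  geno_matrix(rbind(a$geno, b$geno), a$sites)
}
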