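#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses a VCF (via vcfR), keeps only biallelic SNPs, and decodes the GT
#' field into alternate-allele dosages. Phasing is ignored: `0|1` and `1/0`
#' both decode to 1. Fully or half-missing calls (`./.`, `.`, `./1`, ...)
#' become `NA`; partial genotypes carry no defined dosage here and counting
#' them would bias per-individual denominators.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param completeness_min Minimum fraction of non-missing genotypes a site
#'   must have to be retained, in `[0, 1]`. The default 0 keeps everything.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, completeness_min = 0) {
  if (!is.numeric(completeness_min) || length(completeness_min) != 1 ||
      completeness_min < 0 || completeness_min > 1) {
    stop("`completeness_min` must be a single fraction in [0, 1]",
         call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("cannot read VCF: no such file '", path, "'", call. = FALSE)
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("cannot read VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    stop("VCF '", path, "' contains no variant records", call. = FALSE)
  }
  nt <- c("A", "C", "G", "T")
  keep <- !is.na(fix$REF) & !is.na(fix$ALT) &
    toupper(fix$REF) %in% nt & toupper(fix$ALT) %in% nt
  if (!any(keep)) {
    stop("no sites survive the biallelic-SNP filter", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  dosage <- decode_gt(gt)              # sites x individuals
  called <- rowMeans(!is.na(dosage))
  keep2 <- called >= completeness_min
  if (!any(keep2)) {
    stop(sprintf(
      "no sites survive the completeness filter (completeness_min = %g)",
      completeness_min
    ), call. = FALSE)
  }
  dosage <- dosage[keep2, , drop = FALSE]
  fix <- fix[keep2, , drop = FALSE]

  sites <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = toupper(fix$REF), alt = toupper(fix$ALT),
    stringsAsFactors = FALSE
  )
  geno_matrix(t(dosage), sites)
}

# GT strings -> dosage; any genotype containing "." is fully missing.
decode_gt <- function(gt) {
  norm <- gsub("|", "/", as.character(gt), fixed = TRUE)
  out <- rep(NA_integer_, length(norm))
  out[norm %in% "0/0"] <- 0L
  out[norm %in% c("0/1", "1/0")] <- 1L
  out[norm %in% "1/1"] <- 2L
  matrix(out, nrow = nrow(gt), ncol = ncol(gt),
         dimnames = dimnames(gt))
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits VCF v4.2 with a GT-only FORMAT column; the inverse of [read_vcf()]
#' on the dialect this package produces. Dosage 1 is written unphased
#' (`0/1`), missing as `./.`.
#'
#' @param g A [geno_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- apply(g$geno, 2, function(col) {
    out <- gt_code[as.character(col)]
    out[is.na(col)] <- "./."
    out
  })                                   # individuals x sites
  s <- g$sites
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", individual_ids(g)), collapse = "\t"),
    paste(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", "GT",
          apply(body, 2, paste, collapse = "\t"), sep = "\t")
  )
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a triangle table to tab-separated text
#'
#' Columns are `id`, `pop`, `hybrid_index`, `heterozygosity`,
#' `perc_missing`; numeric fields are serialized at full precision and
#' undefined estimates as `NA`.
#'
#' @param table A triangle table from [build_triangle_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_triangle_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("triangle table is empty", call. = FALSE)
  }
  cols <- c("id", "pop", "hybrid_index", "heterozygosity", "perc_missing")
  out <- table[, cols]
  for (v in c("hybrid_index", "heterozygosity", "perc_missing")) {
    out[[v]] <- formatC(out[[v]], digits = 17, format = "g")
    out[[v]][is.na(table[[v]])] <- "NA"
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read back a triangle table written by [write_triangle_table()]
#' @param path Path to the TSV file.
#' @return A data frame with the standard triangle-table columns.
#' @export
read_triangle_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "numeric", "numeric"))
  class(tab) <- c("triangle_table", "data.frame")
  tab
}
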