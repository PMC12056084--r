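#' Build a population map with designated parental groups
#'
#' @param id Character vector of individual ids (unique).
#' @param pop Character vector of population labels, same length as `id`.
#'   Labels other than the two parental labels are legal: contact-zone or
#'   otherwise unassigned samples simply ride along and are scored like any
#'   other individual.
#' @param p1,p2 The two labels designated as parental groups. Hybrid index
#'   is oriented so that individuals of `p2` sit at 1 and of `p1` at 0.
#' @return A data frame of class `popmap` with columns `id`, `pop` and
#'   attributes `p1`/`p2`.
#' @export
popmap <- function(id, pop, p1, p2) {
  id <- as.character(id)
  pop <- as.character(pop)
  if (length(id) != length(pop)) {
    stop("`id` and `pop` must have the same length", call. = FALSE)
  }
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicated individual id(s) in popmap: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (identical(p1, p2)) stop("p1 and p2 must differ", call. = FALSE)
  for (lab in c(p1, p2)) {
    if (!lab %in% pop) {
      stop(sprintf(
        "parental label '%s' not present; available labels: %s",
        lab, paste(sort(unique(pop)), collapse = ", ")
      ), call. = FALSE)
    }
  }
  structure(
    data.frame(id = id, pop = pop, stringsAsFactors = FALSE),
    p1 = p1, p2 = p2, class = c("popmap", "data.frame")
  )
}

#' Parental labels of a popmap
#' @param pm A `popmap`.
#' @return Named character vector with elements `p1` and `p2`.
#' @export
parental_labels <- function(pm) {
  c(p1 = attr(pm, "p1"), p2 = attr(pm, "p2"))
}

#' Ids assigned to one parental group
#' @param pm A `popmap`.
#' @param which `"p1"` or `"p2"`.
#' @return Character vector of ids carrying that parental label.
#' @export
parental_ids <- function(pm, which = c("p1", "p2")) {
  which <- match.arg(which)
  pm$id[pm$pop == attr(pm, which)]
}

# Every genotyped individual must be assigned; popmap-only individuals are
# tolerated (they may have been filtered out upstream) but flagged.
check_popmap <- function(pm, g) {
  vcf_ids <- individual_ids(g)
  unassigned <- setdiff(vcf_ids, pm$id)
  if (length(unassigned)) {
    stop("genotyped individual(s) absent from popmap: ",
         paste(unassigned, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(pm$id, vcf_ids)
  if (length(extra)) {
    warning("popmap individual(s) not in genotype data (retained): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  invisible(pm)
}

#' Read a two-column population map file
#'
#' Expects headerless whitespace- or tab-delimited text with individual ids
#' in the first column and population labels in the second.
#'
#' @param path Path to the popmap file.
#' @param p1,p2 Labels to designate as the parental groups.
#' @param individuals Optional character vector of genotyped individual ids
#'   to validate against: ids present in the genotype data but missing from
#'   the popmap raise an error, popmap-only ids a warning.
#' @return A [popmap()].
#' @export
read_popmap <- function(path, p1, p2, individuals = NULL) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "character",
                      col.names = c("id", "pop")),
    error = function(e) stop("cannot read popmap '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  pm <- popmap(tab$id, tab$pop, p1 = p1, p2 = p2)
  if (!is.null(individuals)) {
    unassigned <- setdiff(individuals, pm$id)
    if (length(unassigned)) {
      stop("genotyped individual(s) absent from popmap: ",
           paste(unassigned, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(pm$id, individuals)
    if (length(extra)) {
      warning("popmap individual(s) not in genotype data (retained): ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  pm
}

#' Write a popmap to two-column text
#' @param pm A `popmap`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(pm[, c("id", "pop")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
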