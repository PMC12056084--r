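# Hardy-Weinberg cross-propagation engine.
#
# On fixed-difference AIMs, an individual's hybrid index equals its
# genome-wide frequency of the P1-associated allele (up to orientation)
# and its interclass heterozygosity equals its genome-wide heterozygote
# frequency. Crossing two individuals whose allele frequencies differ
# inflates offspring heterozygosity relative to the textbook HWE value --
# the inverse of the Wahlund effect -- by twice the between-parent
# variance in allele frequency.

#' Between-parent variance in genome-wide allele frequency
#'
#' For a cross of two parents with genome-wide allele frequencies `hA` and
#' `hB`, the variance over the two parents: `((hA - m)^2 + (hB - m)^2) / 2`
#' with `m` the parental mean, which simplifies to `((hA - hB) / 2)^2`.
#' Bounded by 0.25 (fully divergent parents).
#'
#' @param hA,hB Parental genome-wide allele frequencies in `[0, 1]`
#'   (vectorized).
#' @return Numeric vector of variances in `[0, 0.25]`.
#' @export
cross_variance <- function(hA, hB) {
  ((hA - hB) / 2)^2
}

#' Expected offspring genotype frequencies for an arbitrary cross
#'
#' With `m` the mean parental allele frequency and `s2` the between-parent
#' variance from [cross_variance()], the expected genome-wide genotype
#' frequencies in the offspring are
#' `p11 = m^2 - s2`, `p12 = 2 m (1 - m) + 2 s2`, `p22 = (1 - m)^2 - s2`.
#' The variance enters with the opposite sign to the classical Wahlund
#' deficit because it measures excess offspring heterozygosity from
#' parents that differ. When `hA = hB` this reduces to the standard HWE
#' genotype frequencies. The offspring hybrid index is `m`; parental
#' heterozygosity never enters.
#'
#' @inheritParams cross_variance
#' @return Data frame (one row per cross) with `p11`, `p12`, `p22`
#'   (summing to 1), `hi` (= `m`) and `het` (= `p12`).
#' @export
offspring_genotype_freqs <- function(hA, hB) {
  m <- (hA + hB) / 2
  s2 <- cross_variance(hA, hB)
  p11 <- m^2 - s2        # = hA * hB, hence never negative
  p12 <- 2 * m * (1 - m) + 2 * s2
  p22 <- (1 - m)^2 - s2  # = (1 - hA) * (1 - hB)
  stopifnot(all(p11 >= -1e-12), all(p22 >= -1e-12))
  data.frame(p11 = p11, p12 = p12, p22 = p22, hi = m, het = p12)
}

#' Expected triangle-plot coordinates of the canonical hybrid classes
#'
#' Iterates [offspring_genotype_freqs()] along the canonical pedigrees:
#' F1 = P1 x P2, F2 = F1 x F1, and BCn = (n-1)th backcross crossed again
#' to the same parental group. BCn toward a parent sits at hybrid-index
#' offset `2^-(n+1)` from that parent with heterozygosity `2^-n`; after
#' four backcross generations the offsets (0.03125, 0.0625) are already
#' near-parental.
#'
#' @param max_backcross Number of backcross generations to include
#'   (at least 1).
#' @return Data frame with columns `class`, `hi`, `het`. Hybrid index is
#'   oriented with P2 at 1.
#' @export
class_expectations <- function(max_backcross = 4) {
  if (max_backcross < 1) stop("`max_backcross` must be >= 1", call. = FALSE)
  # States are genome-wide P2-allele frequencies; P1 parent = 0, P2 = 1.
  f1 <- offspring_genotype_freqs(0, 1)
  f2 <- offspring_genotype_freqs(f1$hi, f1$hi)
  rows <- list(
    data.frame(class = c("P1", "P2", "F1", "F2"),
               hi = c(0, 1, f1$hi, f2$hi),
               het = c(0, 0, f1$het, f2$het))
  )
  for (toward in c("P1", "P2")) {
    parent <- if (toward == "P1") 0 else 1
    state <- f1$hi
    for (n in seq_len(max_backcross)) {
      off <- offspring_genotype_freqs(state, parent)
      rows[[length(rows) + 1L]] <- data.frame(
        class = sprintf("BC%d_%s", n, toward), hi = off$hi, het = off$het
      )
      state <- off$hi
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- out$class
  out
}

#' Heterozygosity bounds of the triangle plot at a given hybrid index
#'
#' Under HWE the feasible region is bounded above by the lines `y = 2x`
#' and `y = -2x + 2` and below by the curve `y = 2x(1 - x)`.
#'
#' @param h Hybrid index values in `[0, 1]` (vectorized).
#' @return Data frame with `min_het` (the curve) and `max_het` (the
#'   lines); they meet only at `h` = 0, 0.5, 1.
#' @export
triangle_boundary <- function(h) {
  if (any(h < 0 | h > 1)) {
    stop("hybrid index must lie in [0, 1]", call. = FALSE)
  }
  data.frame(min_het = 2 * h * (1 - h),
             max_het = pmin(2 * h, 2 - 2 * h))
}

#' Locate a point relative to the HWE triangle region
#'
#' Points below the curve `y = 2x(1 - x)` cannot be produced by any cross
#' under HWE; finding individuals there is consistent with HWE violation
#' (drift, selection, nonrandom mating). Points above the bounding lines
#' are unreachable outright.
#'
#' @param h,het Coordinates in `[0, 1]` (vectorized; recycled).
#' @param tol Numerical tolerance for boundary comparisons.
#' @return Character vector with values `"inside"`, `"on_curve"`,
#'   `"below_curve"` or `"outside_lines"`.
#' @export
classify_point <- function(h, het, tol = 1e-9) {
  if (any(h < 0 | h > 1) || any(het < 0 | het > 1)) {
    stop("coordinates must lie in [0, 1]", call. = FALSE)
  }
  b <- triangle_boundary(h)
  out <- rep("inside", length(b$min_het))
  het <- rep_len(het, length(out))
  out[het > b$max_het + tol] <- "outside_lines"
  out[het < b$min_het - tol] <- "below_curve"
  out[abs(het - b$min_het) <= tol] <- "on_curve"
  out
}

#' Enumerate all reachable (hybrid index, heterozygosity) points
#'
#' Starting from the two parental states (0, 0) and (1, 0), repeatedly
#' crosses every pair of states from any earlier generation (including
#' parentals, which is what generates backcrosses; self-pairs stand for
#' two distinct individuals of the same state) through
#' [offspring_genotype_freqs()], accumulating the distinct points reached
#' within `generations` generations. Only the parental hybrid indices
#' matter for offspring, so states are tracked by hybrid index.
#'
#' @param generations Number of generations of mixing (>= 0); 6 matches
#'   the point cloud conventionally drawn on triangle plots.
#' @param cap Safety cap on `generations` (combinatorial growth).
#' @param tol Deduplication tolerance for point coordinates.
#' @return Data frame with `hi`, `het` and `generation` (the first
#'   generation at which each point appears). Every point lies in the
#'   closed triangle region.
#' @export
enumerate_space <- function(generations = 6, cap = 8, tol = 1e-12) {
  if (generations < 0) stop("`generations` must be >= 0", call. = FALSE)
  if (generations > cap) {
    stop(sprintf("`generations` = %d exceeds cap %d", generations, cap),
         call. = FALSE)
  }
  digits <- max(0, ceiling(-log10(tol)))
  pts <- data.frame(hi = c(0, 1), het = c(0, 0), generation = 0L)
  seen <- paste(round(pts$hi, digits), round(pts$het, digits))
  his <- c(0, 1)
  for (g in seq_len(generations)) {
    pair <- expand.grid(a = his, b = his)
    pair <- pair[pair$a <= pair$b, ]      # crosses are unordered
    off <- offspring_genotype_freqs(pair$a, pair$b)
    key <- paste(round(off$hi, digits), round(off$het, digits))
    new <- !duplicated(key) & !(key %in% seen)
    if (any(new)) {
      pts <- rbind(pts, data.frame(hi = off$hi[new], het = off$het[new],
                                   generation = g))
      seen <- c(seen, key[new])
    }
    his <- sort(unique(round(c(his, off$hi), digits)))
  }
  rownames(pts) <- NULL
  pts
}
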