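# Programmatic fixtures shared across the suite.

vcf_fixture_lines <- function(ids, records) {
  c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", ids), collapse = "\t"),
    records
  )
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

write_vcf_fixture <- function(ids, records, path = tempfile(fileext = ".vcf")) {
  writeLines(vcf_fixture_lines(ids, records), path)
  path
}

# Two 5-individual parental pools whose sample deltas are exactly
# 1, 0.8, 0.5 and 0.1 (hand-constructed allele counts).
toy_parental_pools <- function() {
  p1 <- rbind(
    c(0, 1, 1, 2),
    c(0, 0, 1, 2),
    c(0, 0, 0, 1),
    c(0, 0, 0, 0),
    c(0, 0, 0, 0)
  )
  p2 <- rbind(
    c(2, 1, 2, 2),
    c(2, 2, 2, 2),
    c(2, 2, 2, 1),
    c(2, 2, 1, 1),
    c(2, 2, 0, 0)
  )
  geno <- rbind(p1, p2)
  rownames(geno) <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  g <- geno_matrix(geno, data.frame(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
    stringsAsFactors = FALSE
  ))
  pm <- popmap(rownames(geno), rep(c("A", "B"), each = 5),
               p1 = "A", p2 = "B")
  list(geno = g, popmap = pm)
}

# Fixed-difference panel (P1 all dosage 0, P2 all dosage 2) plus extra
# individuals with caller-chosen dosage rows, for hand-count HI/het cases.
fixed_diff_panel <- function(extra = NULL, n_sites = 4) {
  geno <- rbind(
    matrix(0L, 2, n_sites, dimnames = list(c("p1a", "p1b"), NULL)),
    matrix(2L, 2, n_sites, dimnames = list(c("p2a", "p2b"), NULL))
  )
  if (!is.null(extra)) geno <- rbind(geno, extra)
  g <- geno_matrix(geno, data.frame(
    chrom = "chr1", pos = seq_len(n_sites), ref = "A", alt = "T",
    stringsAsFactors = FALSE
  ))
  pop <- c("A", "A", "B", "B", rep("Z", nrow(geno) - 4))
  pm <- popmap(rownames(geno), pop, p1 = "A", p2 = "B")
  list(geno = g, popmap = pm)
}

# Shared simulation for the depth experiments: parental pools with only
# fixed differences, known hybrid classes, hybrids downsampled to `depth`
# while the parentals used for AIM selection stay at full depth.
depth_experiment <- function(depth, seed, n_fixed = 500, n_per_class = 20) {
  cfg <- sim_config(n_sites = n_fixed, n_fixed_diff = n_fixed,
                    n_per_parental = 20, seed = seed)
  pools <- simulate_parental_pools(cfg)
  sim <- make_hybrid_classes(pools$geno, pools$popmap,
                             n_per_class = n_per_class)
  hyb_ids <- setdiff(individual_ids(sim$geno), individual_ids(pools$geno))
  hyb <- downsample_depth(subset_individuals(sim$geno, hyb_ids), depth)
  combined <- bind_individuals(pools$geno, hyb)
  aims <- select_aims(combined, sim$popmap, threshold = 1)
  tab <- build_triangle_table(aims, sim$popmap)
  classes <- data.frame(id = hyb_ids,
                        class = sub("_[0-9]+$", "", hyb_ids),
                        stringsAsFactors = FALSE)
  evaluate_classes(tab, classes)
}
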