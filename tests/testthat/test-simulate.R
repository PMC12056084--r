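test_that("parental pools honor the configuration and are seed-stable", {
  cfg <- sim_config(n_sites = 200, n_fixed_diff = 15, n_per_parental = 10,
                    seed = 11)
  a <- simulate_parental_pools(cfg)
  b <- simulate_parental_pools(cfg)
  expect_identical(a$geno$geno, b$geno$geno)      # determinism under seed

  truth <- a$geno$sites
  expect_equal(sum(abs(truth$true_freq_p1 - truth$true_freq_p2) == 1), 15)
  # with every individual sampled, sample delta at fixed sites is exactly 1
  f1 <- allele_frequencies(a$geno, parental_ids(a$popmap, "p1"))
  f2 <- allele_frequencies(a$geno, parental_ids(a$popmap, "p2"))
  expect_equal(allele_freq_diff(f1, f2)[1:15], rep(1, 15))
  expect_equal(length(individual_ids(a$geno)), 20)

  expect_error(sim_config(n_sites = 10, n_fixed_diff = 11), "exceed")
  expect_error(sim_config(spectrum = list(p1 = c(-1, 1), p2 = c(1, 1))),
               "positive")
})

test_that("crossing draws one allele from each parent", {
  expect_equal(cross_individuals(c(2L, 2L), c(2L, 2L)), c(2L, 2L))
  expect_equal(cross_individuals(c(0L, 0L), c(2L, 2L)), c(1L, 1L))  # F1
  expect_equal(cross_individuals(c(0L, NA), c(2L, 2L))[2], NA_integer_)
  expect_error(cross_individuals(c(0L, 1L), 0L), "different site sets")

  # het x hom-ref: offspring is 1 with probability 1/2, never 2
  set.seed(5)
  off <- replicate(1e4, cross_individuals(1L, 0L))
  expect_true(all(off %in% c(0L, 1L)))
  p <- mean(off == 1L)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("hybrid classes are built per the pairing scheme", {
  cfg <- sim_config(n_sites = 300, n_fixed_diff = 300, n_per_parental = 20,
                    seed = 3)
  pools <- simulate_parental_pools(cfg)
  sim <- make_hybrid_classes(pools$geno, pools$popmap, n_per_class = 20,
                             seed = 4)
  expect_equal(length(individual_ids(sim$geno)), 40 + 80)
  expect_equal(unname(table(sim$popmap$pop)[c("F1", "F2", "BC1_P1", "BC1_P2")]),
               rep(20L, 4), ignore_attr = TRUE)

  # F1 heterozygosity at true fixed differences is forced to 1
  f1_ids <- sim$popmap$id[sim$popmap$pop == "F1"]
  f1_geno <- sim$geno$geno[f1_ids, ]
  expect_true(all(f1_geno == 1L))

  # F2 mean hybrid index approaches 1/2 (Mendelian expectation)
  aims <- select_aims(sim$geno, sim$popmap, threshold = 1)
  hi <- hybrid_index(aims)
  f2_mean <- mean(hi[sim$popmap$id[sim$popmap$pop == "F2"]])
  se <- sqrt(0.5 * 0.5 / (2 * 300 * 20))
  expect_lt(abs(f2_mean - 0.5), 4 * se)
  expect_identical(
    make_hybrid_classes(pools$geno, pools$popmap, 20, seed = 4)$geno$geno,
    sim$geno$geno)
})

test_that("depth downsampling only miscalls heterozygotes, toward homozygosity", {
  hom <- geno_matrix(rbind(i = rep(c(0L, 2L), 50)),
                     data.frame(chrom = "c", pos = 1:100,
                                ref = "A", alt = "T"))
  expect_identical(downsample_depth(hom, 1, seed = 1)$geno, hom$geno)

  het <- geno_matrix(rbind(i = rep(1L, 1e5)),
                     data.frame(chrom = "c", pos = 1:1e5,
                                ref = "A", alt = "T"))
  d1 <- downsample_depth(het, 1, seed = 2)
  expect_true(all(d1$geno %in% c(0L, 2L)))        # depth 1 cannot stay het
  expect_lt(abs(mean(d1$geno == 0L) - 0.5), 0.01) # symmetric miscalls

  # survival probability at depth 6 is 1 - 2^(1-6) = 31/32
  d6 <- downsample_depth(het, 6, seed = 3)
  p <- mean(d6$geno == 1L)
  expect_lt(abs(p - 31 / 32), 3 * sqrt((31 / 32) * (1 / 32) / 1e5))
  expect_error(downsample_depth(het, 0), ">= 1")

  na <- geno_matrix(rbind(i = c(1L, NA)),
                    data.frame(chrom = "c", pos = 1:2, ref = "A", alt = "T"))
  expect_true(is.na(downsample_depth(na, 4, seed = 1)$geno[1, 2]))
})

test_that("observed heterozygosity attenuates as het_true * (1 - 2^(1-d))", {
  set.seed(9)
  n <- 4e4
  for (d in c(2, 4, 8)) {
    g <- geno_matrix(rbind(i = rep(1L, n)),
                     data.frame(chrom = "c", pos = 1:n, ref = "A", alt = "T"))
    obs <- mean(downsample_depth(g, d)$geno == 1L)
    expected <- 1 - 2^(1 - d)
    expect_lt(abs(obs - expected),
              4 * sqrt(expected * (1 - expected) / n))
  }
})

test_that("parental subsampling keeps n per group and retains the rest", {
  pm <- popmap(sprintf("i%02d", 1:50),
               c(rep("A", 20), rep("B", 20), rep("H", 10)),
               p1 = "A", p2 = "B")
  reps <- subsample_parentals(pm, n = 5, replicates = 200, seed = 6)
  expect_length(reps, 200)
  kept <- lapply(reps, parental_ids, "p1")
  expect_true(all(lengths(kept) == 5))
  expect_true(all(unlist(kept) %in% pm$id[pm$pop == "A"]))
  # non-parental individuals and the full roster are untouched
  expect_true(all(vapply(reps, function(r) all(r$id == pm$id), logical(1))))
  expect_true(all(vapply(reps, function(r)
    sum(r$pop == "A_excluded") == 15, logical(1))))
  expect_gt(length(unique(vapply(kept, paste, collapse = ",",
                                 FUN.VALUE = character(1)))), 1)
  # n equal to the population size reproduces the input
  full <- subsample_parentals(pm, n = 20, replicates = 2, seed = 6)
  expect_true(all(full[[1]]$pop == pm$pop))
  expect_error(subsample_parentals(pm, n = 21), "exceeds")
})

test_that("true delta at sample-fixed sites is left-skewed toward 1", {
  # Small parental samples produce false fixed differences; the true
  # deltas behind sample delta = 1 pile up near 1 with a tail downward.
  cfg <- sim_config(n_sites = 4000, n_fixed_diff = 50, n_per_parental = 20,
                    seed = 12)
  sim <- simulate_parental_pools(cfg)
  sub <- subsample_parentals(sim$popmap, n = 5, replicates = 1, seed = 13)[[1]]
  aims <- select_aims(sim$geno, sub, threshold = 1)
  true_delta <- abs(aims$sites$true_freq_p1 - aims$sites$true_freq_p2)
  expect_gt(length(true_delta), 50)    # false fixed differences appear
  expect_lt(min(true_delta), 1)
  # mode at 1: the top decile bin holds the most sites
  bins <- cut(true_delta, seq(0, 1, 0.1), include.lowest = TRUE)
  expect_equal(names(which.max(table(bins))), "(0.9,1]")
  # left skew: mean pulled below the median
  expect_lt(mean(true_delta), stats::median(true_delta) + 1e-12)
})
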