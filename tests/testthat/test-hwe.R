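test_that("between-parent variance follows the two-parent formula", {
  expect_equal(cross_variance(0.3, 0.3), 0)
  expect_equal(cross_variance(1, 0), 0.25)
  expect_equal(cross_variance(0.5, 1), 0.0625)
  # vectorized and symmetric
  h <- seq(0, 1, 0.1)
  expect_equal(cross_variance(h, rev(h)), cross_variance(rev(h), h))
})

test_that("offspring genotype frequencies hit the canonical crosses", {
  f1 <- offspring_genotype_freqs(1, 0)          # P1 x P2
  expect_equal(unlist(f1[c("p11", "p12", "p22")], use.names = FALSE),
               c(0, 1, 0))
  expect_equal(f1$hi, 0.5)

  f2 <- offspring_genotype_freqs(0.5, 0.5)      # F1 x F1
  expect_equal(unlist(f2[c("p11", "p12", "p22")], use.names = FALSE),
               c(0.25, 0.5, 0.25))

  bc <- offspring_genotype_freqs(1, 0.5)        # P x F1
  expect_equal(unlist(bc[c("p11", "p12", "p22")], use.names = FALSE),
               c(0.5, 0.5, 0))
  expect_equal(bc$hi, 0.75)
})

test_that("genotype frequencies conserve mass and never fall below the curve", {
  grid <- expand.grid(hA = seq(0, 1, 0.01), hB = seq(0, 1, 0.01))
  off <- offspring_genotype_freqs(grid$hA, grid$hB)
  expect_true(all(abs(off$p11 + off$p12 + off$p22 - 1) < 1e-12))
  expect_true(all(off$p11 >= -1e-12 & off$p12 >= -1e-12 & off$p22 >= -1e-12))
  # inverse-Wahlund excess: p12 >= HWE value, equality iff equal parents
  hwe <- 2 * off$hi * (1 - off$hi)
  expect_true(all(off$p12 - hwe >= -1e-12))
  eq <- abs(grid$hA - grid$hB) < 1e-12
  expect_true(all(abs(off$p12[eq] - hwe[eq]) < 1e-12))
  expect_true(all(off$p12[!eq] > hwe[!eq]))
  # offspring hybrid index is the parental mean
  expect_equal(off$hi, (grid$hA + grid$hB) / 2)
})

test_that("class expectations follow the backcross halving law", {
  ce <- class_expectations(max_backcross = 4)
  expect_equal(ce["P1", c("hi", "het")], list(hi = 0, het = 0),
               ignore_attr = TRUE)
  expect_equal(ce["P2", c("hi", "het")], list(hi = 1, het = 0),
               ignore_attr = TRUE)
  expect_equal(ce["F1", c("hi", "het")], list(hi = 0.5, het = 1),
               ignore_attr = TRUE)
  expect_equal(ce["F2", c("hi", "het")], list(hi = 0.5, het = 0.5),
               ignore_attr = TRUE)
  expect_equal(ce["BC1_P2", c("hi", "het")], list(hi = 0.75, het = 0.5),
               ignore_attr = TRUE)
  # BCn sits 2^-(n+1) from its parent with heterozygosity 2^-n
  for (n in 1:4) {
    expect_equal(ce[sprintf("BC%d_P1", n), "hi"], 2^-(n + 1))
    expect_equal(ce[sprintf("BC%d_P2", n), "hi"], 1 - 2^-(n + 1))
    expect_equal(ce[sprintf("BC%d_P1", n), "het"], 2^-n)
  }
  # four backcross generations land near-parental
  expect_equal(ce["BC4_P1", "hi"], 0.03125)
  expect_equal(ce["BC4_P1", "het"], 0.0625)
  expect_error(class_expectations(0), ">= 1")
})

test_that("class expectations agree with an independent pedigree simulation", {
  # Oracle: individuals as two 0/1 ancestry haplotypes over unlinked
  # sites; a cross draws one haplotype allele per parent per site.
  set.seed(421)
  L <- 1e5
  mate <- function(a, b) {
    rbind(ifelse(runif(L) < 0.5, a[1, ], a[2, ]),
          ifelse(runif(L) < 0.5, b[1, ], b[2, ]))
  }
  p1 <- rbind(rep(0, L), rep(0, L))
  p2 <- rbind(rep(1, L), rep(1, L))
  f1 <- mate(p1, p2)
  f2 <- mate(f1, mate(p1, p2))
  bc <- f1
  for (i in 1:4) bc <- mate(bc, p1)    # BC4 toward P1
  stats <- function(ind) c(hi = mean(ind), het = mean(ind[1, ] != ind[2, ]))
  ce <- class_expectations(4)
  se <- 3 / sqrt(L)                    # < 3 binomial SEs for all classes
  expect_lt(abs(stats(f2)["hi"] - ce["F2", "hi"]), se)
  expect_lt(abs(stats(f2)["het"] - ce["F2", "het"]), se)
  expect_lt(abs(stats(bc)["hi"] - ce["BC4_P1", "hi"]), se)
  expect_lt(abs(stats(bc)["het"] - ce["BC4_P1", "het"]), se)
})

test_that("triangle boundary and point classification match the geometry", {
  b <- triangle_boundary(c(0, 0.25, 0.5, 1))
  expect_equal(b$min_het, c(0, 0.375, 0.5, 0))
  expect_equal(b$max_het, c(0, 0.5, 1, 0))
  expect_error(triangle_boundary(1.2), "\\[0, 1\\]")

  expect_equal(classify_point(0.5, 0.3), "below_curve")
  expect_equal(classify_point(0.5, 0.5), "on_curve")
  expect_equal(classify_point(0.2, 0.9), "outside_lines")
  expect_equal(classify_point(0.5, 0.8), "inside")
  expect_equal(classify_point(0, 0), "on_curve")   # degenerate vertex
})

test_that("reachable-space enumeration grows inside the triangle", {
  g0 <- enumerate_space(0)
  expect_equal(g0[order(g0$hi), c("hi", "het")],
               data.frame(hi = c(0, 1), het = c(0, 0)),
               ignore_attr = TRUE)
  g1 <- enumerate_space(1)
  expect_equal(nrow(g1), 3)            # parentals plus the F1 apex
  new <- g1[g1$generation == 1, ]
  expect_equal(c(new$hi, new$het), c(0.5, 1))

  g6 <- enumerate_space(6)
  expect_gt(nrow(g6), 100)
  cls <- classify_point(g6$hi, g6$het)
  expect_true(all(cls %in% c("inside", "on_curve")))
  # monotone accumulation across generations
  expect_true(all(table(g6$generation)[as.character(0:6)] > 0))
  expect_error(enumerate_space(9), "cap")
})
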