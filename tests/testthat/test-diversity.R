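test_that("coancestry matches identity-by-state arithmetic and brute force", {
  ## single-locus identities
  ds <- toy_ds(matrix(c(2L, 2L, 0L, 1L), ncol = 1))
  f <- coancestry(ds)$f
  expect_equal(f["s1", "s2"], 1)    # AA vs AA
  expect_equal(f["s1", "s3"], 0)    # AA vs aa
  expect_equal(f["s4", "s4"], 0.5)  # self of Aa
  expect_equal(f["s1", "s1"], 1)    # self of AA
  ds2 <- toy_ds(matrix(c(1L, 1L), ncol = 1))
  expect_equal(coancestry(ds2)$f[1, 2], 0.5)  # Aa vs Aa

  ## 3 individuals x 4 loci (with one missing call) vs per-locus enumeration
  X <- rbind(c(0L, 1L, 2L, 2L), c(2L, 1L, NA, 0L), c(1L, 0L, 2L, 1L))
  ds3 <- toy_ds(X)
  f3 <- coancestry(ds3)$f
  for (i in 1:3) for (j in 1:3)
    expect_equal(f3[i, j], brute_coancestry_pair(X[i, ], X[j, ]))
})

test_that("coancestry errors when a pair shares no called locus", {
  X <- rbind(c(1L, NA), c(NA, 1L))
  expect_error(coancestry(toy_ds(X)), "share no called locus")
})

test_that("Nei minimum distance matches its closed form", {
  mk <- function(p1, p2) list(
    p = rbind(b1 = p1, b2 = p2),
    n = matrix(100, 2, length(p1), dimnames = list(c("b1", "b2"), NULL)))
  expect_equal(nei_minimum_distance(mk(c(1, 1), c(0, 0)))["b1", "b2"], 1)
  expect_equal(nei_minimum_distance(mk(c(0.3, 0.7), c(0.3, 0.7)))["b1", "b2"], 0)
  expect_equal(nei_minimum_distance(mk(0.5, 0.0))["b1", "b2"], 0.25)
  expect_error(nei_minimum_distance(list(p = rbind(b1 = 0.5),
                                         n = rbind(b1 = 10))), "two breeds")
})

test_that("gene-diversity partition reproduces hand-evaluated cases", {
  ## two large breeds fixed for alternative alleles
  X <- rbind(matrix(2L, 10, 5), matrix(0L, 10, 5))
  ds <- toy_ds(X, breeds = rep(c("P", "Q"), each = 10))
  g <- gene_diversity_partition(coancestry(ds))
  expect_equal(g$HS, 0)
  expect_equal(g$DG, 0.5)
  expect_equal(g$HT, 0.5)

  ## B identical breeds: DG exactly 0
  set.seed(2)
  Y <- matrix(rbinom(5 * 8, 2, 0.5), nrow = 5)
  Y3 <- rbind(Y, Y, Y)
  ds3 <- toy_ds(Y3, breeds = rep(c("a", "b", "c"), each = 5))
  g3 <- gene_diversity_partition(coancestry(ds3))
  expect_equal(g3$DG, 0)
  expect_equal(g3$HT, g3$HS)

  ## one panmictic population under arbitrary labels: DG ~ 0
  set.seed(3)
  Z <- matrix(rbinom(40 * 300, 2, runif(300, 0.2, 0.8)), nrow = 40, byrow = TRUE)
  dsz <- toy_ds(Z, breeds = rep(c("u", "v"), each = 20))
  gz <- gene_diversity_partition(coancestry(dsz))
  expect_lt(abs(gz$DG), 0.01)
})

test_that("HT = HS + DG to machine precision on random datasets", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(sample(c(0:2, NA), 12 * 50, replace = TRUE,
                       prob = c(0.4, 0.2, 0.38, 0.02)), nrow = 12)
    ds <- toy_ds(X, breeds = rep(c("a", "b", "c"), each = 4))
    g <- gene_diversity_partition(coancestry(ds))
    expect_lt(abs(g$HT - (g$HS + g$DG)), 1e-12)
  }
})

test_that("allelic partition reproduces hand-evaluated cases", {
  ## breed1 fixed alt, breed2 fixed ref
  X <- rbind(matrix(2L, 6, 4), matrix(0L, 6, 4))
  ds <- toy_ds(X, breeds = rep(c("P", "Q"), each = 6))
  a <- allelic_diversity_partition(ds)
  expect_equal(a$AS, 0)
  expect_equal(a$DA, 1)
  expect_equal(a$AT, 1)

  ## breed1 p = 0.5 exactly, breed2 fixed ref, equal large sizes
  X2 <- rbind(matrix(rep(c(0L, 2L), each = 25), 50, 3),
              matrix(0L, 50, 3))
  ds2 <- toy_ds(X2, breeds = rep(c("P", "Q"), each = 50))
  a2 <- allelic_diversity_partition(ds2)
  expect_equal(a2$AS, 0.5, tolerance = 1e-10)
  expect_equal(a2$DA, 0.5)
  expect_equal(a2$AT, 1, tolerance = 1e-10)

  ## identical polymorphic breeds: DA = 0
  set.seed(4)
  Y <- matrix(rbinom(8 * 30, 2, 0.5), nrow = 8)
  ds3 <- toy_ds(rbind(Y, Y), breeds = rep(c("a", "b"), each = 8))
  a3 <- allelic_diversity_partition(ds3)
  expect_equal(a3$DA, 0)
  expect_equal(a3$AT, a3$AS)
})

test_that("loci uncallable at the rarefaction size are dropped and counted", {
  X <- rbind(c(1L, NA), c(1L, NA), c(0L, 1L), c(2L, 1L))
  ds <- toy_ds(X, breeds = c("a", "a", "b", "b"))
  a <- allelic_diversity_partition(ds, rarefaction_size = 4)
  expect_identical(a$n_loci_dropped, 1L)
  expect_identical(a$n_loci_used, 1L)
})

test_that("private alleles are counted per breed over all loci", {
  ## breed 'a' uniquely carries the alternate allele at 10 of 100 loci
  L <- 100
  Xa <- matrix(0L, 5, L); Xa[1, 1:10] <- 1L
  Xb <- matrix(0L, 5, L)
  ds <- toy_ds(rbind(Xa, Xb), breeds = rep(c("a", "b"), each = 5))
  pa <- private_alleles(ds)
  expect_equal(pa$private_per_locus[pa$breed == "a"], 0.1)
  expect_equal(pa$private_per_locus[pa$breed == "b"], 0)

  ## all alleles shared: zero everywhere
  set.seed(5)
  Y <- matrix(1L, 6, 20)
  ds2 <- toy_ds(Y, breeds = rep(c("a", "b"), each = 3))
  expect_true(all(private_alleles(ds2)$private_per_locus == 0))

  expect_error(private_alleles(toy_ds(matrix(1L, 4, 3))), "single breed")
})

test_that("breed indices match hand evaluation and degenerate rules", {
  ## identical fully homozygous individuals
  ds <- toy_ds(matrix(2L, 3, 4))
  bi <- breed_indices(coancestry(ds))
  expect_equal(bi$fii, 1)
  expect_equal(bi$si, 1)
  expect_equal(bi$dii, 0)
  expect_true(is.na(bi$Gi))

  ## AA vs aa at one locus: s = 1, f = 0, d = 1, Gi = 1
  ds2 <- toy_ds(matrix(c(2L, 0L), ncol = 1))
  bi2 <- breed_indices(coancestry(ds2))
  expect_equal(bi2$fii, 0)
  expect_equal(bi2$si, 1)
  expect_equal(bi2$dii, 1)
  expect_equal(bi2$Gi, 1)

  ## duplicating every individual: si is unchanged, and because a clone
  ## pair has f = s (and d = 0), the pair means follow the replication
  ## closed form: for n originals, fii' = (s + (2n-2) fii)/(2n-1) and
  ## dii' = (2n-2)/(2n-1) dii
  set.seed(6)
  X <- matrix(rbinom(4 * 30, 2, 0.4), nrow = 4)
  d1 <- breed_indices(coancestry(toy_ds(X)))
  d2 <- breed_indices(coancestry(toy_ds(rbind(X, X))))
  expect_equal(d2$si, d1$si)
  expect_equal(d2$fii, (d1$si + 6 * d1$fii) / 7, tolerance = 1e-12)
  expect_equal(d2$dii, 6 / 7 * d1$dii, tolerance = 1e-12)
  expect_equal(d2$Gi, (6 / 7 * d1$dii) / (6 / 7 * d1$dii + 1 - d1$si),
               tolerance = 1e-12)

  expect_error(breed_indices(coancestry(toy_ds(matrix(1L, 3, 2),
                                               breeds = c("a", "a", "b")))),
               "fewer than two")
})

test_that("permuting sample order changes no statistic", {
  set.seed(7)
  X <- matrix(sample(c(0:2, NA), 15 * 80, replace = TRUE,
                     prob = c(0.35, 0.25, 0.38, 0.02)), nrow = 15)
  ds <- toy_ds(X, breeds = rep(c("a", "b", "c"), each = 5))
  perm <- sample(15)
  dsp <- gen_dataset(X[perm, ], ds$markers, ds$samples[perm, ])
  g1 <- glance(gene_diversity_partition(coancestry(ds)))
  g2 <- glance(gene_diversity_partition(coancestry(dsp)))
  expect_equal(g1, g2, tolerance = 1e-12)
  a1 <- glance(allelic_diversity_partition(ds))
  a2 <- glance(allelic_diversity_partition(dsp))
  expect_equal(a1, a2, tolerance = 1e-12)
  n1 <- nei_minimum_distance(ds); n2 <- nei_minimum_distance(dsp)
  expect_equal(unclass(n1)[c("a", "b", "c"), c("a", "b", "c")],
               unclass(n2)[c("a", "b", "c"), c("a", "b", "c")],
               tolerance = 1e-12)
  b1 <- dplyr::arrange(breed_indices(coancestry(ds)), breed)
  b2 <- dplyr::arrange(breed_indices(coancestry(dsp)), breed)
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("coancestry distance equals the frequency-based Nei distance", {
  ## with the diagonal-inclusive within-breed mean, the coancestry block
  ## means reduce algebraically to p^2 + q^2 and p1 p2 + q1 q2, so the
  ## coancestry-based between-breed distance IS the frequency-based Nei
  ## distance on complete data, at every sample size
  for (n in c(10L, 50L, 200L)) {
    ds <- bn_two_breeds(0.1, n_snps = 2000, seed = 31, breed_sizes = c(n, n))
    g <- gene_diversity_partition(coancestry(ds))
    expect_equal(g$D_breed[1, 2], unclass(nei_minimum_distance(ds))[1, 2],
                 tolerance = 1e-12)
  }
  ## with missing calls the two remain close (pairwise-complete averaging)
  cfg <- sim_config(n_breeds = 2, breed_sizes = c(30L, 30L),
                    fst_per_breed = c(0.1, 0.1), froh_per_breed = c(0, 0),
                    chrom_lengths_bp = 50e6, n_snps = 3000,
                    missing_rate = 0.05, seed = 32)
  ds <- simulate_dataset(cfg)
  g <- gene_diversity_partition(coancestry(ds))
  expect_equal(g$D_breed[1, 2], unclass(nei_minimum_distance(ds))[1, 2],
               tolerance = 0.02)
})
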