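test_that("heterozygosity estimators match hand computations", {
  # all heterozygous at p = q = 0.5
  tab <- make_table(matrix(1L, 4, 1), matrix(2L, 4, 1))
  h <- observed_expected_het(tab, by = NULL)
  expect_equal(h$Ho, 1)
  expect_equal(h$Hs, (8 / 7) * 0.5)

  # n = 5, allele counts 6 and 4: unbiased Hs = (10/9)(1 - .36 - .16)
  tab <- make_table(rbind(1L, 1L, 1L, 1L, 2L), rbind(1L, 1L, 2L, 2L, 2L))
  h <- observed_expected_het(tab, by = NULL)
  expect_equal(h$Hs, (10 / 9) * (1 - 0.36 - 0.16))
  expect_equal(h$Ho, 2 / 5)
  # biased variant drops the correction
  hb <- observed_expected_het(tab, by = NULL, unbiased = FALSE)
  expect_equal(hb$Hs, 0.48)

  # large-n limit at p = q = 0.5 approaches 0.5
  tab <- make_table(matrix(rep(c(1L, 2L), 250), 500, 1),
                    matrix(rep(c(1L, 2L), 250), 500, 1))
  h <- observed_expected_het(tab, by = NULL)
  expect_lt(abs(h$Hs - 0.5), 0.001)
})

test_that("PIC matches its closed form", {
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(rep(0.25, 4)), 1 - 0.25 - 2 * 6 * (1 / 16)^2)
  # PIC <= expected heterozygosity at any frequency vector (property)
  for (seed in 1:20) {
    set.seed(seed)
    p <- stats::runif(sample(2:8, 1)); p <- p / sum(p)
    expect_lte(pic(p), 1 - sum(p^2) + 1e-12)
  }
})

test_that("null allele estimators match hand computations and clamp", {
  expect_equal(as.numeric(null_allele_freq(0.6, 0.6)), 0)
  expect_equal(as.numeric(null_allele_freq(0.3, 0.6, "brookfield1")),
               0.3 / 1.6)
  expect_equal(as.numeric(null_allele_freq(0.3, 0.6, "chakraborty")), 1 / 3)
  r <- null_allele_freq(0.8, 0.5)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "clamped"))
  expect_true(is.na(null_allele_freq(0, 0, "chakraborty")))
})

test_that("Hardy-Weinberg test behaves on canonical configurations", {
  # perfect HW proportions: 1 AA, 2 AB, 1 BB
  tab <- make_table(rbind(1L, 1L, 1L, 2L), rbind(1L, 2L, 2L, 2L))
  h <- hwe_test(tab)
  expect_equal(h$chi2, 0)
  expect_equal(h$p, 1)

  # all homozygotes, two equifrequent alleles, n = 50: chi2 = n
  tab <- make_table(matrix(rep(c(1L, 2L), 25), 50, 1),
                    matrix(rep(c(1L, 2L), 25), 50, 1))
  h <- hwe_test(tab)
  expect_equal(h$chi2, 50)
  expect_lt(h$p, 0.001)
  hm <- hwe_test(tab, mode = "monte_carlo", B = 199, seed = 1)
  expect_lt(hm$p, 0.02)

  # monomorphic locus: p = 1 by convention
  tab <- make_table(matrix(1L, 10, 1), matrix(1L, 10, 1))
  expect_equal(hwe_test(tab)$p, 1)
})

test_that("FIS and its locus bootstrap recover simulated inbreeding", {
  # every individual heterozygous: strong heterozygote excess, FIS < 0
  tab <- make_table(matrix(1L, 10, 2), matrix(2L, 10, 2))
  f <- fis_ci(tab, B = 200, seed = 1)
  hs <- (20 / 19) * 0.5
  expect_equal(f$fis, 1 - 1 / hs)

  # random-mating simulated population: FIS CI covers 0
  sim <- simulate_cohort(two_pop_config(n_per_pop = 80, seed = 3))
  f <- fis_ci(sim$table, "east", B = 500, seed = 2)
  expect_true(f$ci[1] < 0 && f$ci[2] > 0)

  # fully inbred population: all homozygous, FIS near 1
  tab2 <- sim$table
  tab2$a2 <- tab2$a1
  tab2 <- genotype_table(tab2$meta, tab2$loci, tab2$a1, tab2$a2, tab2$plastid)
  f2 <- fis_ci(tab2, "east", B = 200, seed = 3)
  expect_gt(f2$fis, 0.99)
})

test_that("FIS confidence interval covers 0 under random mating (property)", {
  # 40 loci: enough resampling units for the percentile bootstrap to be
  # close to nominal (with very few loci it is known to undercover)
  hits <- vapply(1:50, function(s) {
    cfg <- two_pop_config(n_per_pop = 60, seed = 100 + s)
    cfg$n_nuclear <- 40L
    f <- fis_ci(simulate_cohort(cfg)$table, "east", B = 500, seed = s)
    f$ci[1] <= 0 && f$ci[2] >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("rarefied richness obeys its boundary identities", {
  sim <- simulate_cohort(two_pop_config(n_per_pop = 20, seed = 4))
  tab <- sim$table
  af <- allele_freqs(tab)
  # g = N: A_g equals the observed allele count exactly
  N <- min(vapply(nuclear_loci(tab), function(l)
    min(rowSums(af$counts[[l]])), numeric(1)))
  r <- rarefied_richness(tab, g = N, mode = "exact")
  for (l in nuclear_loci(tab)) {
    obs <- sum(af$counts[[l]]["east", ] > 0)
    got <- r$per_locus$A_g[r$per_locus$locus == l &
                             r$per_locus$population == "east"]
    if (sum(af$counts[[l]]["east", ]) == N) expect_equal(got, obs)
  }
  # g = 1: exactly one allele
  r1 <- rarefied_richness(tab, g = 1, mode = "exact")
  expect_true(all(abs(r1$per_locus$A_g - 1) < 1e-12))
  # monotone nondecreasing in g
  a6 <- rarefied_richness(tab, g = 6, mode = "exact")$by_population$A_g
  a12 <- rarefied_richness(tab, g = 12, mode = "exact")$by_population$A_g
  expect_true(all(a12 >= a6 - 1e-12))
  # g beyond the sample errors with the population named
  expect_error(rarefied_richness(tab, g = 10000), "population")
})

test_that("Monte-Carlo rarefaction converges to the exact formula", {
  sim <- simulate_cohort(two_pop_config(n_per_pop = 30, seed = 5))
  ex <- rarefied_richness(sim$table, g = 18, mode = "exact")
  mc <- rarefied_richness(sim$table, g = 18, mode = "monte_carlo",
                          reps = 1000, seed = 6)
  expect_true(all(abs(ex$by_population$A_g - mc$by_population$A_g) < 0.1))
})

test_that("private allelic richness matches its exact formula and limits", {
  # an allele private to the focal population at frequency 1 contributes 1
  tab <- make_table(rbind(1L, 1L, 2L, 2L), rbind(1L, 1L, 2L, 2L),
                    population = c("f", "f", "o", "o"))
  p <- private_rarefied_richness(tab, "f", g = 2, mode = "exact")
  expect_equal(p$by_population$P_g, 1)

  # two copies of the same population: P_g = 0 exactly when the subsample
  # exhausts the pool (every allele certain to be seen in both)
  sim <- simulate_cohort(two_pop_config(n_per_pop = 15, seed = 7,
                                        missing_rate = 0))
  tab <- sim$table
  east <- which(tab$meta$population == "east")
  dup <- make_table(rbind(tab$a1[east, ], tab$a1[east, ]),
                    rbind(tab$a2[east, ], tab$a2[east, ]),
                    population = rep(c("c1", "c2"), each = 15))
  p <- private_rarefied_richness(dup, "c1", g = 30, mode = "exact")
  expect_equal(p$by_population$P_g, 0)
  # and stays far below the allelic richness at smaller g
  p18 <- private_rarefied_richness(dup, "c1", g = 18, mode = "exact")
  a18 <- rarefied_richness(dup, g = 18, mode = "exact")
  expect_lt(p18$by_population$P_g,
            0.25 * a18$by_population$A_g[a18$by_population$population == "c1"])

  # Monte-Carlo agrees with the exact product formula
  sim <- simulate_cohort(two_pop_config(n_per_pop = 30, seed = 8))
  ex <- private_rarefied_richness(sim$table, "east", g = 18, mode = "exact")
  mc <- private_rarefied_richness(sim$table, "east", g = 18,
                                  mode = "monte_carlo", reps = 1000, seed = 9)
  expect_lt(abs(ex$by_population$P_g - mc$by_population$P_g), 0.1)
  expect_error(private_rarefied_richness(sim$table, "nowhere", g = 5),
               "unknown focal")
})

test_that("Tukey grouping letters separate and merge as expected", {
  set.seed(1)
  v <- c(rnorm(100, 10, 1), rnorm(100, 10, 1))
  pop <- rep(c("a", "b"), each = 100)
  g <- tukey_groups(v, pop)
  expect_equal(g$group[1], g$group[2])

  v <- c(rnorm(1000, 10, 0.1), rnorm(1000, 20, 0.1))
  pop <- rep(c("a", "b"), each = 1000)
  g <- tukey_groups(v, pop)
  expect_false(g$group[1] == g$group[2])

  v <- c(rnorm(500, 10, 0.5), rnorm(500, 10.01, 0.5), rnorm(500, 20, 0.5))
  pop <- rep(c("p1", "p2", "p3"), each = 500)
  g <- tukey_groups(v, pop)
  expect_equal(g$group[g$population == "p3"], "a")        # highest mean first
  expect_equal(g$group[g$population == "p1"], "b")
  expect_equal(g$group[g$population == "p2"], "b")

  # zero variance: everyone shares a letter
  g <- tukey_groups(rep(1, 20), rep(c("a", "b"), 10))
  expect_true(all(g$group == "a"))
})

test_that("locus_stats assembles the per-locus quality table", {
  sim <- simulate_cohort(siwa_study_config(seed = 6))
  ls <- locus_stats(sim$table)
  expect_equal(nrow(ls), 18)
  nuc <- ls[ls$kind == "nuclear", ]
  expect_true(all(nuc$PIC >= 0 & nuc$PIC <= 1))
  expect_true(all(nuc$PIC <= nuc$He + 1e-6))
  expect_true(all(nuc$hwe_p >= 0 & nuc$hwe_p <= 1))
  expect_true(is.na(ls$PIC[ls$kind == "plastid"]))
})
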