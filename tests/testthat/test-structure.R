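test_that("dosage matrix codes genotypes and imputes column means", {
  a1 <- rbind(1L, 1L, 2L, NA)
  a2 <- rbind(1L, 2L, 2L, NA)
  tab <- make_table(a1, a2)
  d <- dosage_matrix(tab)
  expect_equal(unname(d[1, "L1.1"]), 2)              # homozygote
  expect_equal(unname(d[2, c("L1.1", "L1.2")]), c(1, 1))  # heterozygote
  # missing row imputed with the column mean of observed dosages
  expect_equal(unname(d[4, "L1.1"]), mean(c(2, 1, 0)))
  # non-missing rows sum to 2 over a locus's columns
  expect_equal(unname(rowSums(d[1:3, ])), rep(2, 3))
})

test_that("PCA separates clusters and is reproducible up to convention", {
  a1 <- rbind(clone_mat(rep(1L, 10), 5), clone_mat(rep(5L, 10), 5))
  tab <- make_table(a1, a1)
  p <- pca_dosage(dosage_matrix(tab))
  expect_equal(p$explained[1], 1)                     # one informative axis
  expect_gt(abs(mean(p$scores[1:5, 1]) - mean(p$scores[6:10, 1])), 1)
  # duplicate accessions get identical scores
  expect_equal(p$scores[1, ], p$scores[2, ])
  expect_true(all(diff(p$explained) < 1e-12))

  # reordering accessions permutes scores without changing them
  sim <- simulate_cohort(two_pop_config(30, seed = 2))
  tab <- sim$table
  p1 <- pca_dosage(dosage_matrix(tab), n_components = 3)
  set.seed(9); perm <- sample(n_accessions(tab))
  p2 <- pca_dosage(dosage_matrix(subset_accessions(tab, accessions(tab)[perm])),
                   n_components = 3)
  expect_equal(p2$scores[accessions(tab), ], p1$scores, tolerance = 1e-8)
})

test_that("PC1 separates simulated populations", {
  sim <- simulate_cohort(two_pop_config(50, theta = 10, seed = 3))
  p <- pca_dosage(dosage_matrix(sim$table), n_components = 2)
  pop <- sim$table$meta$population
  s <- p$scores[, 1]
  # mean silhouette-like separation: centroid gap vs within spread
  gap <- abs(mean(s[pop == "east"]) - mean(s[pop == "west"]))
  spread <- mean(c(stats::sd(s[pop == "east"]), stats::sd(s[pop == "west"])))
  expect_gt(gap / spread, 1)
})

test_that("Weir-Cockerham theta hits its analytic anchors", {
  # fixed differences at every locus: theta = 1 exactly
  a1 <- rbind(clone_mat(rep(1L, 17), 10), clone_mat(rep(2L, 17), 10))
  tab <- make_table(a1, a1, population = rep(c("p1", "p2"), each = 10))
  expect_equal(wc_fst(tab)$theta, 1)

  # a single population split at random: theta within 0.02 of zero
  sim <- simulate_cohort(two_pop_config(100, theta = 1e6, seed = 4))
  tab <- sim$table
  set.seed(5)
  tab$meta$population <- sample(rep(c("h1", "h2"), each = 100))
  tab <- genotype_table(tab$meta, tab$loci, tab$a1, tab$a2, tab$plastid)
  expect_lt(abs(wc_fst(tab)$theta), 0.02)
})

test_that("theta equals hand-computed variance components on a toy table", {
  # 2 populations x 6 individuals, one biallelic locus
  a1 <- c(1L, 1L, 1L, 1L, 1L, 2L,  1L, 1L, 2L, 2L, 2L, 2L)
  a2 <- c(1L, 1L, 1L, 2L, 2L, 2L,  2L, 2L, 2L, 2L, 2L, 2L)
  tab <- make_table(matrix(a1), matrix(a2),
                    population = rep(c("p1", "p2"), each = 6))
  got <- wc_fst(tab)

  # independent oracle: Weir & Cockerham (1984) components from first
  # principles for each allele
  oracle_abc <- function(allele) {
    pops <- list(p1 = 1:6, p2 = 7:12)
    ni <- c(6, 6); r <- 2
    p_i <- vapply(pops, function(ix)
      mean(c(a1[ix], a2[ix]) == allele), numeric(1))
    h_i <- vapply(pops, function(ix)
      mean((a1[ix] == allele) != (a2[ix] == allele)), numeric(1))
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * p_i) / (r * nbar)
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a, b, hbar / 2)
  }
  comp <- oracle_abc(1) + oracle_abc(2)
  expect_equal(got$theta, comp[1] / sum(comp))
  expect_equal(nrow(got$per_locus), 1)
  expect_error(wc_fst(make_table(matrix(1L), matrix(1L))), "2 populations")
})

test_that("shared-allele proportion covers its boundary cases", {
  tab <- make_table(rbind(1L, 2L, 3L, 2L, 3L, 4L), rbind(1L, 2L, 3L, 2L, 3L, 4L),
                    population = rep(c("A", "B"), each = 3))
  # A = {1,2,3}, B = {2,3,4}: intersection-over-union = 0.5
  expect_equal(shared_allele_proportion(tab, "A", "B")$proportion, 0.5)
  expect_equal(shared_allele_proportion(tab, "A", "B", mode = "focal")$proportion,
               2 / 3)
  # identical and disjoint populations
  tab2 <- make_table(rbind(1L, 2L, 1L, 2L), rbind(1L, 2L, 1L, 2L),
                     population = rep(c("A", "B"), each = 2))
  expect_equal(shared_allele_proportion(tab2, "A", "B")$proportion, 1)
  tab3 <- make_table(rbind(1L, 1L, 9L, 9L), rbind(2L, 2L, 8L, 8L),
                     population = rep(c("A", "B"), each = 2))
  expect_equal(shared_allele_proportion(tab3, "A", "B")$proportion, 0)
})

test_that("Nei distance matches its closed form and caps degeneracies", {
  expect_equal(nei_distance_vec(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # hand computation: I = 0.5 / sqrt(0.82 * 0.5)
  I <- 0.5 / sqrt(0.82 * 0.5)
  d <- nei_distance_vec(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(d, -log(I))
  # fixed different alleles: I = 0, capped at -log(eps)
  d0 <- nei_distance_vec(c(1, 0), c(0, 1))
  expect_equal(as.numeric(d0), -log(1e-12))
  expect_true(isTRUE(attr(d0, "capped")))
})

test_that("neighbor joining is exact on additive distances", {
  # 4-taxon additive matrix from tree ((A:1,B:2):1,(C:3,D:4))
  dm <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 5
  dm["A", "D"] <- dm["D", "A"] <- 6
  dm["B", "C"] <- dm["C", "B"] <- 6
  dm["B", "D"] <- dm["D", "B"] <- 7
  dm["C", "D"] <- dm["D", "C"] <- 7
  tr <- nj_tree(dm)
  expect_equal(max(abs(ape::cophenetic.phylo(tr)[rownames(dm), rownames(dm)] - dm)),
               0, tolerance = 1e-10)

  # 3 taxa: unique closed-form star lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(d3)
  lens <- tr3$edge.length[match(seq_len(3), tr3$edge[, 2])]
  expect_equal(sort(lens), c(1, 2, 3))

  # label permutation gives an isomorphic tree
  perm <- c(3, 1, 4, 2)
  tr_p <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr_p)), 0,
               ignore_attr = TRUE)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ recovers random trees from their cophenetic matrices (property)", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
    dm <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
    expect_equal(max(abs(ape::cophenetic.phylo(rec)[rownames(dm), colnames(dm)] - dm)),
                 0, tolerance = 1e-8)
  }
})

test_that("locus bootstrap gives full support to fixed clusters", {
  a1 <- rbind(clone_mat(rep(1L, 17), 4), clone_mat(rep(5L, 17), 4))
  tab <- make_table(a1, a1 + 1L)
  tr0 <- bootstrap_nj(tab, B = 0, seed = 1)
  expect_null(tr0$node.label)
  tr <- bootstrap_nj(tab, B = 25, seed = 1)
  expect_true(all(tr$node.label == 100))
})

test_that("a planted three-clade cohort earns high clade support", {
  cfg <- simulation_config(
    populations = list(population_spec("c1", 0.5, c("3" = 1)),
                       population_spec("c2", 0.5, c("3" = 1)),
                       population_spec("c3", 0.5, c("3" = 1))),
    groups = list(cohort_group("c1", "cultivated", 6),
                  cohort_group("c2", "cultivated", 6),
                  cohort_group("c3", "cultivated", 6)),
    mu_som = 0, epsilon = 0, missing_rate = 0, seed = 12)
  sim <- simulate_cohort(cfg)
  tr <- bootstrap_nj(sim$table, B = 100, seed = 13)
  # support of the bipartition isolating each population's tips
  pops <- split(accessions(sim$table), sim$table$meta$population)
  parts <- ape::prop.part(tr)
  labs <- attr(parts, "labels")
  for (p in pops) {
    hit <- vapply(seq_along(parts), function(i) {
      tips <- labs[parts[[i]]]
      setequal(tips, p) || setequal(setdiff(labs, tips), p)
    }, logical(1))
    node <- which(hit)[which(hit) > 1][1]
    if (!is.na(node))
      expect_gt(as.numeric(tr$node.label[node]), 80)
  }
})
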