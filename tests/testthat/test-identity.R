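test_that("pairwise identity counts matches and excludes missing loci", {
  g <- pair_agreeing_at(17)
  tab <- make_table(g$a1, g$a2)
  pid <- pairwise_identity(tab)
  expect_equal(pid$identity[1, 2], 1)
  expect_equal(pid$n_compared[1, 2], 17)

  g5 <- pair_agreeing_at(5)
  expect_equal(pairwise_identity(make_table(g5$a1, g5$a2))$identity[1, 2],
               5 / 17)

  g <- pair_agreeing_at(17)
  g$a1[2, 4] <- NA; g$a2[2, 4] <- NA
  pid <- pairwise_identity(make_table(g$a1, g$a2))
  expect_equal(pid$n_compared[1, 2], 16)
  expect_equal(pid$identity[1, 2], 1)

  expect_error(pairwise_identity(make_table(rbind(1L), rbind(1L))),
               "at least 2")
  no_cp <- make_table(rbind(c(1L, 1L), c(1L, 1L)), rbind(c(2L, 2L), c(2L, 2L)))
  expect_error(pairwise_identity(no_cp, "plastid"), "plastid")
})

test_that("named-type identity reproduces the analytically forced values", {
  # three identical clones: 100% nuclear and chloroplastic identity
  tab <- make_table(clone_mat(rep(1L, 17), 3), clone_mat(rep(2L, 17), 3),
                    plastid = rep(3L, 3), named_type = "halu",
                    status = "named_type")
  r <- named_type_identity(tab, "halu")
  expect_equal(r$nuc_identity, 100)
  expect_equal(r$cp_identity, 100)

  # four accessions, three identical and one differing at one locus:
  # (3 x 1 + 3 x 16/17) / 6 pairs = 97.06%
  a1 <- clone_mat(rep(1L, 17), 4); a2 <- clone_mat(rep(2L, 17), 4)
  a2[4, 1] <- 3L
  r <- named_type_identity(make_table(a1, a2, plastid = rep(3L, 4),
                                      named_type = "aghzal"), "aghzal")
  expect_equal(round(r$nuc_identity, 2), 97.06)
  expect_equal(r$cp_identity, 100)

  # two accessions with different chlorotypes: 0% chloroplastic identity
  g <- pair_agreeing_at(5)
  r <- named_type_identity(make_table(g$a1, g$a2, plastid = c(3L, 4L),
                                      named_type = "grom"), "grom")
  expect_equal(round(r$nuc_identity, 2), 29.41)
  expect_equal(r$cp_identity, 0)

  # singleton types are undefined-with-reason, not an error
  solo <- make_table(rbind(c(1L, 1L)), rbind(c(2L, 2L)), named_type = "solo")
  r <- named_type_identity(solo, "solo")
  expect_true(is.na(r$nuc_identity))
  expect_match(r$reason, "fewer than two")
})

test_that("clone partition tolerates single-locus somatic deviation", {
  # 13 accessions, 12 identical + 1 differing at one locus: one line at t = 1
  a1 <- clone_mat(rep(1L, 17), 13); a2 <- clone_mat(rep(2L, 17), 13)
  a2[13, 5] <- 3L
  part <- clone_partition(make_table(a1, a2), t = 1)
  expect_equal(length(unique(part$lines$line)), 1)
  # and splits into 2 lines at t = 0
  part0 <- clone_partition(make_table(a1, a2), t = 0)
  expect_equal(length(unique(part0$lines$line)), 2)

  # mutually unrelated genotypes stay singletons
  a1 <- outer(1:6, rep(1L, 17)) * 2L - 1L
  a2 <- a1 + 1L
  part <- clone_partition(make_table(a1, a2), t = 1)
  expect_equal(length(unique(part$lines$line)), 6)
})

test_that("t = 0 partition equals brute-force exact-duplicate groups", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 20
    base <- matrix(sample(1:4, 5 * 17, replace = TRUE), 5, 17)
    rows <- base[sample(5, n, replace = TRUE), , drop = FALSE]
    tab <- make_table(rows, rows + 1L)
    part <- clone_partition(tab, t = 0, min_compared = 1)
    key <- apply(cbind(tab$a1, tab$a2), 1, paste, collapse = "/")
    oracle <- stats::ave(accessions(tab), key,
                         FUN = function(v) rep(min(v), length(v)))
    expect_identical(part$lines$line, unname(oracle))
  }
})

test_that("partition and identity are invariant to accession order", {
  sim <- simulate_cohort(siwa_study_config(seed = 5))
  tab <- sim$table
  set.seed(1)
  perm <- sample(n_accessions(tab))
  tab2 <- subset_accessions(tab, accessions(tab)[perm])
  p1 <- clone_partition(tab)
  p2 <- clone_partition(tab2)
  m1 <- p1$lines$line[match(accessions(tab), p1$lines$accession)]
  m2 <- p2$lines$line[match(accessions(tab), p2$lines$accession)]
  expect_identical(m1, m2)
})

test_that("deduplication keeps one best representative per line", {
  tab <- make_table(clone_mat(rep(1L, 17), 5), clone_mat(rep(2L, 17), 5))
  part <- clone_partition(tab)
  dd <- deduplicate(tab, part)
  expect_equal(n_accessions(dd), 1)
  expect_equal(attr(dd, "n_removed"), 4)

  # representative is the member with fewest missing calls
  a1 <- clone_mat(rep(1L, 17), 3); a2 <- clone_mat(rep(2L, 17), 3)
  a1[1, 1:2] <- NA; a2[1, 1:2] <- NA
  dd <- deduplicate(make_table(a1, a2), clone_partition(make_table(a1, a2)))
  expect_equal(accessions(dd), "S02")

  # all-unique table unchanged
  a1 <- outer(1:4, rep(1L, 17)) * 3L - 2L
  tab <- make_table(a1, a1 + 1L)
  expect_equal(n_accessions(deduplicate(tab, clone_partition(tab))), 4)

  # synthetic truth: removed = sum(line sizes - 1)
  sim <- simulate_cohort(siwa_study_config(seed = 5, mu_som = 0,
                                           epsilon = 0, missing_rate = 0))
  part <- clone_partition(sim$table, t = 0)
  dd <- deduplicate(sim$table, part)
  planted <- table(sim$truth$accessions$clone_line)
  expect_equal(attr(dd, "n_removed"), sum(planted - 1))
})

test_that("classification follows the cultivar/ethnovariety/category rule", {
  # 11 identical accessions across many gardens -> true-to-type cultivar
  tab <- make_table(clone_mat(rep(1L, 17), 11), clone_mat(rep(2L, 17), 11),
                    named_type = "alkak", garden = sprintf("g%02d", 1:11))
  cls <- classify_named_type(tab, clone_partition(tab), "alkak")
  expect_equal(cls$classification, "true_to_type_cultivar")

  # one 4-member cross-garden line + 8 singletons -> ethnovariety
  a1 <- rbind(clone_mat(rep(1L, 17), 4), outer(1:8, rep(1L, 17)) * 3L + 4L)
  tab <- make_table(a1, a1 + 1L, named_type = "niqbel",
                    garden = sprintf("g%02d", 1:12))
  cls <- classify_named_type(tab, clone_partition(tab), "niqbel")
  expect_equal(cls$classification, "ethnovariety")
  expect_equal(cls$n_clone_lines, 9)

  # 6 unrelated except 2 same-garden clones -> local category with caveat
  a1 <- rbind(clone_mat(rep(1L, 17), 2), outer(1:4, rep(1L, 17)) * 3L + 4L)
  tab <- make_table(a1, a1 + 1L, named_type = "zhemb",
                    garden = c("g01", "g01", "g02", "g03", "g04", "g05"))
  cls <- classify_named_type(tab, clone_partition(tab), "zhemb")
  expect_equal(cls$classification, "local_category")
  expect_match(cls$caveat, "confined to one garden")

  # single accession -> inconclusive
  tab <- make_table(rbind(rep(1L, 17)), rbind(rep(2L, 17)), named_type = "solo")
  expect_equal(classify_named_type(tab, clone_partition(tab), "solo")$classification,
               "inconclusive")
})

test_that("misidentified accessions are flagged", {
  # a seedling identical to a 12-member cultivar line
  a1 <- clone_mat(rep(1L, 17), 13)
  a2 <- clone_mat(rep(2L, 17), 13)
  nt <- c(rep("saidi", 12), NA)
  tab <- make_table(a1, a2, named_type = nt,
                    status = c(rep("named_type", 12), "ushik1"))
  fl <- flag_misidentifications(tab, clone_partition(tab))
  expect_true("S13" %in% fl$accession)
  expect_equal(fl$matched_named_type[fl$accession == "S13"], "saidi")

  # an outlier inside an otherwise uniform type
  a1 <- clone_mat(rep(1L, 17), 8); a2 <- clone_mat(rep(2L, 17), 8)
  a1[8, ] <- 7L; a2[8, ] <- 9L
  tab <- make_table(a1, a2, named_type = "tattagt")
  fl <- flag_misidentifications(tab, clone_partition(tab))
  expect_equal(fl$accession, "S08")
  expect_match(fl$reason, "informer")

  # clean table: no flags
  a1 <- outer(1:6, rep(1L, 17)) * 3L - 2L
  tab <- make_table(a1, a1 + 1L, named_type = rep(c("x", "y"), 3))
  fl <- flag_misidentifications(tab, clone_partition(tab))
  expect_equal(nrow(fl), 0)
})

test_that("clone identity is 100% under any missing pattern (property)", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- sample(1:9, 17, replace = TRUE)
    a1 <- clone_mat(g, 4); a2 <- clone_mat(g + 1L, 4)
    # knock out random calls but keep every pair comparable
    for (i in 1:4) {
      drop <- sample(17, 2)
      a1[i, drop] <- NA; a2[i, drop] <- NA
    }
    tab <- make_table(a1, a2, named_type = "cl")
    r <- named_type_identity(tab, "cl")
    expect_equal(r$nuc_identity, 100)
  }
})

test_that("named-type report has the expected schema and rounding", {
  sim <- simulate_cohort(siwa_study_config(seed = 1))
  rep <- named_type_report(sim$table)
  expect_equal(nrow(rep), 18)
  expect_true(all(c("named_type", "n", "nuc_identity", "cp_identity",
                    "n_clone_lines", "classification") %in% names(rep)))
  fmt <- format_named_type_report(rep)
  expect_true(all(grepl("^(/|\\d+\\.\\d{2}%)$", fmt$nuc_identity)))
})
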