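#' Synthetic cohort generation
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: several populations drifted from a shared ancestral allele-frequency
#' vector (an F-model analogue: population frequencies are Dirichlet draws
#' around the ancestral vector, with smaller concentration `theta` giving more
#' drift and larger FST, E\[FST\] ~ 1/(1+theta)), named types composed of
#' clonal lines propagated by offshoot with rare stepwise somatic mutations,
#' accidental seedlings arising from random crosses between garden palms
#' (dioecious: selfing disallowed; the plastid allele is inherited from the
#' mother), genotyping error and missing data.
#'
#' @name synthetic-cohort
NULL

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Population frequency model
#'
#' @param name population name.
#' @param theta Dirichlet concentration of the drift model; smaller values
#'   give larger drift from the ancestral frequencies (expected FST against
#'   the ancestor is about 1/(1+theta)).
#' @param chlorotype_freqs named numeric vector of plastid allele frequencies
#'   (names are allele codes); must sum to 1.
#' @return a `population_spec` list.
#' @export
population_spec <- function(name, theta, chlorotype_freqs) {
  stopifnot(theta > 0, abs(sum(chlorotype_freqs) - 1) < 1e-8,
            all(chlorotype_freqs >= 0))
  list(name = name, theta = theta, chlorotype_freqs = chlorotype_freqs)
}

#' Plain accession group
#'
#' A block of accessions of one status drawn from one population, either as
#' fresh Hardy-Weinberg draws from the population frequencies (`"fresh"`) or
#' as seedlings from random crosses between two distinct named-type garden
#' palms of the parent pool (`"cross"`, maternal plastid inheritance).
#'
#' @param population population name.
#' @param status accession status label.
#' @param n number of accessions.
#' @param founder `"fresh"` or `"cross"`.
#' @export
cohort_group <- function(population, status, n, founder = c("fresh", "cross")) {
  founder <- match.arg(founder)
  stopifnot(n >= 0)
  list(population = population, status = status, n = as.integer(n),
       founder = founder)
}

#' Named-type design
#'
#' A named type is a set of clone lines: each line has a founder genotype and
#' `size - 1` vegetatively propagated copies, each independently carrying
#' stepwise somatic mutations at rate `mu_som` per locus. Lines of size one
#' are independent genotypes.
#'
#' @param name named-type label.
#' @param population population whose allele frequencies found the lines.
#' @param lines integer vector of clone-line sizes (sums to the sample size).
#' @param line_gardens per-line garden rule: `"distinct"` (members scattered
#'   over distinct gardens) or `"shared"` (all members in one garden).
#' @return a `named_type_design` list, carrying the classification implied by
#'   the design (`truth`).
#' @export
named_type_design <- function(name, population, lines,
                              line_gardens = rep("distinct", length(lines))) {
  stopifnot(all(lines >= 1), length(line_gardens) == length(lines),
            all(line_gardens %in% c("distinct", "shared")))
  truth <- .design_truth(lines, line_gardens)
  list(name = name, population = population, lines = as.integer(lines),
       line_gardens = line_gardens, truth = truth)
}

# classification implied by a design, under the same rule the classifier uses
.design_truth <- function(lines, line_gardens) {
  n <- sum(lines)
  if (n < 2) return("inconclusive")
  if (length(lines) == 1) return("true_to_type_cultivar")
  if (any(lines >= 2 & line_gardens == "distinct")) return("ethnovariety")
  "local_category"
}

#' Simulation configuration
#'
#' @param n_nuclear number of nuclear SSR loci.
#' @param alleles_range integer range (min, max) of allele counts per nuclear
#'   locus.
#' @param code_max largest allele code; codes are drawn from `1:code_max` and
#'   somatic mutation steps reflect at 1 and `code_max`.
#' @param plastid_name plastid locus name.
#' @param populations list of [population_spec()].
#' @param groups list of [cohort_group()].
#' @param named_types list of [named_type_design()].
#' @param mu_som somatic mutation rate per locus per propagation.
#' @param epsilon genotyping error rate per allele call.
#' @param missing_rate missing-call rate per accession-locus cell.
#' @param n_gardens number of gardens available per population.
#' @param seed integer RNG seed; the same config and seed always produce a
#'   byte-identical table.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_nuclear = 17, alleles_range = c(4, 12),
                              code_max = 40, plastid_name = "cpM12",
                              populations, groups = list(), named_types = list(),
                              mu_som = 0.002, epsilon = 0.002,
                              missing_rate = 0.011, n_gardens = 46, seed = 1) {
  stopifnot(mu_som >= 0, mu_som <= 0.1, epsilon >= 0, epsilon <= 1,
            missing_rate >= 0, missing_rate <= 1, n_nuclear >= 1)
  pop_names <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(pop_names)) stop("duplicate population names")
  for (g in groups)
    if (!g$population %in% pop_names)
      stop("group references unknown population ", g$population)
  for (d in named_types)
    if (!d$population %in% pop_names)
      stop("named type ", d$name, " references unknown population ", d$population)
  structure(list(n_nuclear = as.integer(n_nuclear),
                 alleles_range = as.integer(alleles_range),
                 code_max = as.integer(code_max), plastid_name = plastid_name,
                 populations = populations, groups = groups,
                 named_types = named_types, mu_som = mu_som, epsilon = epsilon,
                 missing_rate = missing_rate, n_gardens = as.integer(n_gardens),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default oasis study-design configuration
#'
#' 406 accessions emulating the sampling design of the Siwa date-palm survey:
#' 109 named-type palms in 18 named types (clone-line compositions chosen to
#' produce true-to-type cultivars, ethnovarieties and local categories), 18 +
#' 22 accidental seedlings (ushik #1 in gardens, ushik #2 on garden borders),
#' 27 uncultivated palms from abandoned desert oases, 121 North African and 98
#' Middle Eastern / Asian cultivated date palms, 9 \emph{P. theophrasti} and 2
#' \emph{P. reclinata} outgroup accessions; 17 nuclear loci plus the plastid
#' cpM12 minisatellite; 1.1\% missing data.
#'
#' @param seed integer RNG seed.
#' @param mu_som,epsilon,missing_rate noise rates, see [simulation_config()].
#' @return a [simulation_config()].
#' @export
siwa_study_config <- function(seed = 1, mu_som = 0.002, epsilon = 0.002,
                              missing_rate = 0.011) {
  pops <- list(
    population_spec("siwa_oasis",   16, c("3" = 0.48,  "4" = 0.52)),
    population_spec("siwa_desert",  16, c("3" = 0.741, "4" = 0.259)),
    population_spec("north_africa", 16, c("3" = 0.80,  "4" = 0.20)),
    population_spec("middle_east",  16, c("3" = 0.10,  "4" = 0.90)),
    population_spec("theophrasti", 0.6, c("5" = 1)),
    population_spec("reclinata",   0.3, c("6" = 1)))
  nt <- function(name, lines, gardens = rep("distinct", length(lines)))
    named_type_design(name, "siwa_oasis", lines, gardens)
  named_types <- list(
    nt("saidi",           13),
    nt("alkak",           11),
    nt("aghzal",           4),
    nt("halu_en_ghanem",   3),
    nt("tattagt",          c(7, 1)),
    nt("ushik_niqbel",     c(4, 3, 1, 1, 1, 1, 1)),
    nt("ghrom_aghzal",     c(2, 2, 1, 1)),
    nt("alkak_wen_zhemb",  c(2, 1, 1, 1, 1), c("shared", rep("distinct", 4))),
    nt("ghrom_said",       c(1, 1)),
    nt("lekrawmet",        rep(1, 4)),
    nt("ushik_amaghzuz",   c(1, 1)),
    nt("ushik_azzugagh",   c(2, 1, 1)),
    nt("amenzu",           rep(1, 7)),
    nt("ushik_nekwayes",   rep(1, 11)),
    nt("ushik_ezzuwagh",   rep(1, 8)),
    nt("kaibi",            rep(1, 6)),
    nt("tazuwaght",        1),
    nt("tazhubart",        1))
  groups <- list(
    cohort_group("siwa_oasis",   "ushik1",        18, "cross"),
    cohort_group("siwa_oasis",   "ushik2",        22, "cross"),
    cohort_group("siwa_desert",  "uncultivated",  27, "fresh"),
    cohort_group("north_africa", "cultivated",   121, "fresh"),
    cohort_group("middle_east",  "cultivated",    98, "fresh"),
    cohort_group("theophrasti",  "wild_relative",  9, "fresh"),
    cohort_group("reclinata",    "outgroup",       2, "fresh"))
  simulation_config(populations = pops, groups = groups,
                    named_types = named_types, mu_som = mu_som,
                    epsilon = epsilon, missing_rate = missing_rate, seed = seed)
}

#' Apply one round of somatic mutation to a diploid genotype
#'
#' Each locus is independently hit with probability `mu_som`; a hit replaces
#' one of the two alleles (chosen uniformly) by a one-repeat step up or down,
#' reflecting at the domain bounds `1` and `allele_max`.
#'
#' @param geno 2 x L integer matrix (two alleles per locus).
#' @param mu_som per-locus mutation probability in \[0, 1\].
#' @param allele_max upper allele-code bound.
#' @param seed optional integer seed (`NULL` uses the current RNG stream).
#' @return mutated 2 x L matrix, pairs order-normalised.
#' @export
mutate_clone <- function(geno, mu_som, allele_max = 40, seed = NULL) {
  stopifnot(mu_som >= 0, mu_som <= 1, nrow(geno) == 2)
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(geno)
  hit <- stats::runif(L) < mu_som
  for (l in which(hit)) {
    row <- sample(2L, 1L)
    a <- geno[row, l]
    if (is.na(a)) next
    step <- if (a <= 1L) 1L else if (a >= allele_max) -1L else
      sample(c(-1L, 1L), 1L)
    geno[row, l] <- a + step
  }
  apply(geno, 2, sort, na.last = TRUE)
}

#' Add genotyping error and missing data to a table
#'
#' @param table a [genotype_table()].
#' @param epsilon per-allele-call probability of replacement by a random
#'   allele from the locus's observed domain.
#' @param missing_rate per accession-locus cell probability of becoming
#'   missing.
#' @param seed optional integer seed (`NULL` uses the current RNG stream).
#' @return a noisy [genotype_table()].
#' @export
apply_noise <- function(table, epsilon, missing_rate, seed = NULL) {
  stopifnot(epsilon >= 0, epsilon <= 1, missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_accessions(table)
  if (epsilon > 0) {
    for (l in nuclear_loci(table)) {
      dom <- allele_domain(table, l)
      if (length(dom) < 2) next
      for (m in c("a1", "a2")) {
        v <- table[[m]][, l]
        err <- !is.na(v) & stats::runif(n) < epsilon
        if (any(err))
          table[[m]][err, l] <- sample(dom, sum(err), replace = TRUE)
      }
    }
    for (l in plastid_loci(table)) {
      dom <- allele_domain(table, l)
      if (length(dom) < 2) next
      v <- table$plastid[, l]
      err <- !is.na(v) & stats::runif(n) < epsilon
      if (any(err))
        table$plastid[err, l] <- sample(dom, sum(err), replace = TRUE)
    }
  }
  if (missing_rate > 0) {
    for (l in nuclear_loci(table)) {
      gone <- stats::runif(n) < missing_rate
      table$a1[gone, l] <- NA_integer_
      table$a2[gone, l] <- NA_integer_
    }
    for (l in plastid_loci(table)) {
      gone <- stats::runif(n) < missing_rate
      table$plastid[gone, l] <- NA_integer_
    }
  }
  genotype_table(table$meta, table$loci, table$a1, table$a2,
                 if (ncol(table$plastid)) table$plastid else NULL)
}

#' Simulate a genotype cohort
#'
#' Draws a full cohort under a [simulation_config()] and returns the genotype
#' table together with a truth record (true clone partition, pedigree and
#' design-implied named-type classification) for validating the analysis
#' stages.
#'
#' @param config a [simulation_config()].
#' @return list with `table` (a [genotype_table()]) and `truth` (list with
#'   `accessions`: data.frame of accession, population, status, named_type,
#'   clone_line, mother, father; `named_types`: data.frame of named_type,
#'   classification; `config`: the config used).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$n_nuclear
  locus_names <- sprintf("ssr%02d", seq_len(L))

  # ancestral and per-population allele frequencies (F-model analogue)
  domains <- vector("list", L)
  p_anc <- vector("list", L)
  for (l in seq_len(L)) {
    k <- sample(seq(config$alleles_range[1], config$alleles_range[2]), 1)
    domains[[l]] <- sort(sample.int(config$code_max, k))
    p_anc[[l]] <- rdirichlet1(rep(1, k))
  }
  pop_freqs <- lapply(config$populations, function(ps)
    lapply(seq_len(L), function(l) {
      p <- rdirichlet1(ps$theta * p_anc[[l]])
      stats::setNames(p, domains[[l]])
    }))
  names(pop_freqs) <- vapply(config$populations, `[[`, "", "name")
  chloro <- lapply(config$populations, `[[`, "chlorotype_freqs")
  names(chloro) <- names(pop_freqs)

  draw_fresh <- function(pop) {
    g <- vapply(seq_len(L), function(l) {
      p <- pop_freqs[[pop]][[l]]
      sort(sample(domains[[l]], 2, replace = TRUE, prob = p))
    }, integer(2))
    cp <- as.integer(sample(names(chloro[[pop]]), 1, prob = chloro[[pop]]))
    list(nuc = g, cp = cp)
  }

  rows <- list()   # each: list(acc fields..., nuc 2xL, cp)
  add_row <- function(population, status, named_type, garden, clone_line,
                      mother, father, nuc, cp) {
    rows[[length(rows) + 1L]] <<- list(
      population = population, status = status, named_type = named_type,
      garden = garden, clone_line = clone_line, mother = mother,
      father = father, nuc = nuc, cp = cp)
  }

  # named types: clone lines founded in their population
  parent_pool <- list()   # named-type members usable as cross parents
  for (d in config$named_types) {
    gardens_avail <- sprintf("%s_G%02d", d$population, seq_len(config$n_gardens))
    for (li in seq_along(d$lines)) {
      size <- d$lines[li]
      founder <- draw_fresh(d$population)
      line_id <- sprintf("%s.L%d.%d", d$name, li, length(rows) + 1L)
      gards <- if (d$line_gardens[li] == "shared")
        rep(sample(gardens_avail, 1), size)
      else sample(gardens_avail, size)
      for (m in seq_len(size)) {
        nuc <- if (m == 1) founder$nuc else
          mutate_clone(founder$nuc, config$mu_som, config$code_max)
        add_row(d$population, "named_type", d$name, gards[m], line_id,
                NA_character_, NA_character_, nuc, founder$cp)
        parent_pool[[length(parent_pool) + 1L]] <-
          list(pop = d$population, idx = length(rows), nuc = nuc,
               cp = founder$cp)
      }
    }
  }

  # plain groups: fresh HWE draws or seedling crosses (maternal plastid)
  for (g in config$groups) {
    gardens_avail <- sprintf("%s_G%02d", g$population, seq_len(config$n_gardens))
    pool <- Filter(function(p) p$pop == g$population, parent_pool)
    for (i in seq_len(g$n)) {
      cl <- sprintf("%s.%s.%d", g$population, g$status, length(rows) + 1L)
      if (g$founder == "cross") {
        if (length(pool) < 2)
          stop("cross group in population ", g$population,
               " needs >= 2 named-type parents (config error)")
        pid <- sample(length(pool), 2)   # dioecious: two distinct parents
        mo <- pool[[pid[1]]]; fa <- pool[[pid[2]]]
        nuc <- vapply(seq_len(L), function(l)
          sort(c(mo$nuc[sample(2L, 1L), l], fa$nuc[sample(2L, 1L), l])),
          integer(2))
        add_row(g$population, g$status, NA_character_,
                sample(gardens_avail, 1), cl,
                sprintf("A%04d", mo$idx), sprintf("A%04d", fa$idx),
                nuc, mo$cp)
      } else {
        f <- draw_fresh(g$population)
        add_row(g$population, g$status, NA_character_,
                sample(gardens_avail, 1), cl, NA_character_, NA_character_,
                f$nuc, f$cp)
      }
    }
  }

  n <- length(rows)
  acc <- sprintf("A%04d", seq_len(n))
  meta <- data.frame(
    accession = acc,
    named_type = vapply(rows, `[[`, "", "named_type"),
    population = vapply(rows, `[[`, "", "population"),
    garden = vapply(rows, `[[`, "", "garden"),
    status = vapply(rows, `[[`, "", "status"),
    stringsAsFactors = FALSE)
  a1 <- t(vapply(rows, function(r) r$nuc[1, ], integer(L)))
  a2 <- t(vapply(rows, function(r) r$nuc[2, ], integer(L)))
  plastid <- matrix(vapply(rows, `[[`, integer(1), "cp"), ncol = 1)
  loci <- data.frame(name = c(locus_names, config$plastid_name),
                     kind = c(rep("nuclear", L), "plastid"))
  table <- genotype_table(meta, loci, a1, a2, plastid)
  table <- apply_noise(table, config$epsilon, config$missing_rate)

  truth_acc <- data.frame(
    accession = acc,
    population = meta$population, status = meta$status,
    named_type = meta$named_type,
    clone_line = vapply(rows, `[[`, "", "clone_line"),
    mother = vapply(rows, `[[`, "", "mother"),
    father = vapply(rows, `[[`, "", "father"),
    stringsAsFactors = FALSE)
  truth_nt <- data.frame(
    named_type = vapply(config$named_types, `[[`, "", "name"),
    classification = vapply(config$named_types, `[[`, "", "truth"),
    stringsAsFactors = FALSE)
  list(table = table,
       truth = list(accessions = truth_acc, named_types = truth_nt,
                    config = config))
}
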