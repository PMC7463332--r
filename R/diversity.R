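#' Allele counts and frequencies
#'
#' Tabulates allele counts and frequencies per population and locus. Nuclear
#' loci contribute two allele copies per non-missing genotype, plastid loci
#' one.
#'
#' @param table a [genotype_table()].
#' @param by metadata column defining populations (default `"population"`);
#'   `NULL` pools all accessions into one population `"all"`.
#' @return object of class `allele_freqs`: list with `populations`, `loci`,
#'   and `counts`, a list (per locus) of population x allele count matrices.
#' @export
allele_freqs <- function(table, by = "population") {
  pop <- if (is.null(by)) rep("all", n_accessions(table)) else table$meta[[by]]
  pop[is.na(pop)] <- "(unassigned)"
  pops <- unique(pop)
  counts <- list()
  for (l in nuclear_loci(table)) {
    al <- sort(unique(c(table$a1[, l], table$a2[, l])))
    m <- matrix(0L, length(pops), length(al), dimnames = list(pops, al))
    for (p in pops) {
      v <- c(table$a1[pop == p, l], table$a2[pop == p, l])
      tab <- table(factor(v, levels = al))
      m[p, ] <- as.integer(tab)
    }
    counts[[l]] <- m
  }
  for (l in plastid_loci(table)) {
    al <- sort(unique(table$plastid[, l]))
    m <- matrix(0L, length(pops), length(al), dimnames = list(pops, al))
    for (p in pops) {
      tab <- table(factor(table$plastid[pop == p, l], levels = al))
      m[p, ] <- as.integer(tab)
    }
    counts[[l]] <- m
  }
  structure(list(populations = pops, loci = names(counts), counts = counts),
            class = "allele_freqs")
}

#' Observed and expected heterozygosity
#'
#' `Ho` is the fraction of heterozygous non-missing genotypes; `Hs` is Nei's
#' unbiased gene diversity, `(2n/(2n-1)) (1 - sum p^2)` with `n` the number of
#' genotyped individuals (`unbiased = FALSE` drops the small-sample factor).
#'
#' @param table a [genotype_table()].
#' @param by population column (`NULL` pools everything).
#' @param unbiased apply the small-sample correction to `Hs`.
#' @return data.frame with columns `population`, `locus`, `n`, `Ho`, `Hs`
#'   (`NA` with zero genotyped individuals); nuclear loci only.
#' @export
observed_expected_het <- function(table, by = "population", unbiased = TRUE) {
  pop <- if (is.null(by)) rep("all", n_accessions(table)) else table$meta[[by]]
  pop[is.na(pop)] <- "(unassigned)"
  rows <- list()
  for (p in unique(pop)) {
    sel <- pop == p
    for (l in nuclear_loci(table)) {
      x1 <- table$a1[sel, l]; x2 <- table$a2[sel, l]
      ok <- !is.na(x1)
      n <- sum(ok)
      if (n == 0) { ho <- hs <- NA_real_ } else {
        ho <- mean(x1[ok] != x2[ok])
        pr <- table(c(x1[ok], x2[ok])) / (2 * n)
        hs <- 1 - sum(pr^2)
        if (unbiased) hs <- hs * 2 * n / (2 * n - 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, locus = l, n = n, Ho = ho, Hs = hs,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Polymorphic information content
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p numeric vector of allele frequencies (summing to 1).
#' @return PIC in \[0, 1\] (0 for a monomorphic locus).
#' @export
pic <- function(p) {
  stopifnot(all(p >= 0))
  p <- p / sum(p)
  p2 <- p^2
  s2 <- sum(p2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4, all over i != j, halved*2
  cross <- s2^2 - sum(p2^2)
  1 - s2 - cross
}

#' Null allele frequency estimators
#'
#' `brookfield1`: r = (He - Ho) / (1 + He); `chakraborty`:
#' r = (He - Ho) / (He + Ho). Negative estimates are clamped to 0 and
#' flagged via the `clamped` attribute.
#'
#' @param Ho,He observed and expected heterozygosity in \[0, 1\] (vectorised).
#' @param method `"brookfield1"` (default) or `"chakraborty"`.
#' @return estimated null allele frequency, clamped to \[0, 1\].
#' @export
null_allele_freq <- function(Ho, He, method = c("brookfield1", "chakraborty")) {
  method <- match.arg(method)
  stopifnot(all(Ho >= 0 & Ho <= 1, na.rm = TRUE),
            all(He >= 0 & He <= 1, na.rm = TRUE))
  r <- switch(method,
              brookfield1 = (He - Ho) / (1 + He),
              chakraborty = ifelse(He + Ho == 0, NA_real_,
                                   (He - Ho) / (He + Ho)))
  clamped <- !is.na(r) & r < 0
  r[clamped] <- 0
  attr(r, "clamped") <- clamped
  r
}

.hw_chisq <- function(a1, a2) {
  # observed vs Hardy-Weinberg expected genotype counts, all k(k+1)/2 cells
  al <- sort(unique(c(a1, a2)))
  k <- length(al)
  n <- length(a1)
  p <- table(factor(c(a1, a2), levels = al)) / (2 * n)
  obs <- table(factor(paste(pmin(a1, a2), pmax(a1, a2)),
                      levels = {
                        g <- expand.grid(i = seq_len(k), j = seq_len(k))
                        g <- g[g$i <= g$j, ]
                        paste(al[g$i], al[g$j])
                      }))
  g <- expand.grid(i = seq_len(k), j = seq_len(k))
  g <- g[g$i <= g$j, ]
  exp_p <- ifelse(g$i == g$j, p[g$i]^2, 2 * p[g$i] * p[g$j])
  exp_n <- n * as.numeric(exp_p)
  keep <- exp_n > 0
  sum((as.numeric(obs[keep]) - exp_n[keep])^2 / exp_n[keep])
}

#' Hardy-Weinberg equilibrium test
#'
#' Chi-squared test of observed genotype counts against Hardy-Weinberg
#' expectations with `k(k-1)/2` degrees of freedom (no rare-allele pooling),
#' or a Monte-Carlo version that permutes allele copies among genotypes `B`
#' times with `p = (1 + #\{chi2_perm >= chi2_obs\}) / (B + 1)`. Monomorphic
#' loci return p = 1 by convention.
#'
#' @param table a [genotype_table()].
#' @param loci loci to test (default all nuclear loci).
#' @param mode `"chi2"` or `"monte_carlo"`.
#' @param B Monte-Carlo permutations.
#' @param seed optional seed for the Monte-Carlo mode.
#' @return data.frame with columns `locus`, `n`, `k`, `chi2`, `df`, `p`.
#' @export
hwe_test <- function(table, loci = nuclear_loci(table),
                     mode = c("chi2", "monte_carlo"), B = 999, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(loci, function(l) {
    x1 <- table$a1[, l]; x2 <- table$a2[, l]
    ok <- !is.na(x1)
    x1 <- x1[ok]; x2 <- x2[ok]
    n <- length(x1)
    al <- sort(unique(c(x1, x2)))
    k <- length(al)
    if (n == 0 || k < 2)
      return(data.frame(locus = l, n = n, k = k, chi2 = 0, df = 0, p = 1,
                        stringsAsFactors = FALSE))
    chi2 <- .hw_chisq(x1, x2)
    df <- k * (k - 1) / 2
    p <- if (mode == "chi2") stats::pchisq(chi2, df, lower.tail = FALSE) else {
      copies <- c(x1, x2)
      hits <- 0L
      for (b in seq_len(B)) {
        perm <- sample(copies)
        if (.hw_chisq(perm[seq_len(n)], perm[n + seq_len(n)]) >= chi2 - 1e-12)
          hits <- hits + 1L
      }
      (1 + hits) / (B + 1)
    }
    data.frame(locus = l, n = n, k = k, chi2 = chi2, df = df, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Inbreeding coefficient with locus-bootstrap confidence interval
#'
#' `FIS = 1 - mean(Ho) / mean(Hs)` (ratio of locus averages); the 95% CI is
#' the 2.5/97.5 percentile of the statistic recomputed on `B` bootstrap
#' resamples of loci.
#'
#' @param table a [genotype_table()].
#' @param population population to evaluate (`NULL` pools all accessions).
#' @param B bootstrap replicates over loci.
#' @param seed optional seed.
#' @return list with `fis`, `ci` (length-2), `Ho`, `Hs` (locus means),
#'   `reason` (non-`NA` when undefined).
#' @export
fis_ci <- function(table, population = NULL, B = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  het <- observed_expected_het(table, by = if (is.null(population)) NULL
                               else "population")
  if (!is.null(population)) het <- het[het$population == population, ]
  het <- het[!is.na(het$Hs), ]
  if (!nrow(het) || mean(het$Hs) == 0)
    return(list(fis = NA_real_, ci = c(NA_real_, NA_real_),
                Ho = NA_real_, Hs = NA_real_,
                reason = "mean expected heterozygosity is zero"))
  fis_of <- function(idx) 1 - mean(het$Ho[idx]) / mean(het$Hs[idx])
  fis <- fis_of(seq_len(nrow(het)))
  ci <- if (nrow(het) >= 2) {
    boots <- vapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(het), replace = TRUE)
      if (mean(het$Hs[idx]) == 0) NA_real_ else fis_of(idx)
    }, numeric(1))
    stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  } else c(NA_real_, NA_real_)
  list(fis = fis, ci = ci, Ho = mean(het$Ho), Hs = mean(het$Hs),
       reason = NA_character_)
}

.rarefied_presence <- function(N_a, N, g) {
  # Q_a = 1 - C(N - N_a, g) / C(N, g), presence probability of each allele in
  # a hypergeometric subsample of g copies
  out <- numeric(length(N_a))
  for (i in seq_along(N_a)) {
    if (N_a[i] == 0) { out[i] <- 0; next }
    if (N - N_a[i] < g) { out[i] <- 1; next }
    out[i] <- 1 - exp(lchoose(N - N_a[i], g) - lchoose(N, g))
  }
  out
}

.mc_subsample_distinct <- function(N_a, g, reps) {
  copies <- rep(seq_along(N_a), N_a)
  vapply(seq_len(reps), function(r)
    length(unique(copies[sample.int(length(copies), g)])), numeric(1))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` allele
#' copies, per locus and averaged over loci. The exact mode uses the
#' hypergeometric formula `A_g = sum_a [1 - C(N-N_a, g)/C(N, g)]`; the
#' Monte-Carlo mode averages the distinct-allele count over `reps`
#' subsamples and also reports its spread.
#'
#' @param table a [genotype_table()] (nuclear loci only are used).
#' @param g haploid rarefaction size; must not exceed any population's
#'   haploid sample size at any locus.
#' @param by population column.
#' @param mode `"exact"` or `"monte_carlo"`.
#' @param reps Monte-Carlo replicates.
#' @param seed optional seed.
#' @return list with `per_locus` (data.frame population, locus, A_g, and for
#'   Monte-Carlo `sd`), `by_population` (data.frame population, A_g = mean
#'   over loci), and for Monte-Carlo `replicates` (population x reps matrix
#'   of across-locus means).
#' @export
rarefied_richness <- function(table, g = 18, by = "population",
                              mode = c("exact", "monte_carlo"),
                              reps = 1000, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  af <- allele_freqs(table, by = by)
  nuc <- intersect(af$loci, nuclear_loci(table))
  rows <- list(); repmat <- NULL
  if (mode == "monte_carlo")
    repmat <- matrix(0, length(af$populations), reps,
                     dimnames = list(af$populations, NULL))
  for (p in af$populations) {
    loc_reps <- matrix(0, length(nuc), reps)
    for (li in seq_along(nuc)) {
      l <- nuc[li]
      cnt <- af$counts[[l]][p, ]
      N <- sum(cnt)
      if (g > N) stop("g = ", g, " exceeds haploid sample size ", N,
                      " of population ", p, " at locus ", l)
      if (mode == "exact") {
        a_g <- sum(.rarefied_presence(cnt, N, g))
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, locus = l, A_g = a_g, stringsAsFactors = FALSE)
      } else {
        draws <- .mc_subsample_distinct(cnt, g, reps)
        loc_reps[li, ] <- draws
        rows[[length(rows) + 1L]] <- data.frame(
          population = p, locus = l, A_g = mean(draws), sd = stats::sd(draws),
          stringsAsFactors = FALSE)
      }
    }
    if (mode == "monte_carlo") repmat[p, ] <- colMeans(loc_reps)
  }
  per_locus <- do.call(rbind, rows)
  by_pop <- stats::aggregate(A_g ~ population, per_locus, mean)
  out <- list(per_locus = per_locus, by_population = by_pop, g = g, mode = mode)
  if (mode == "monte_carlo") out$replicates <- repmat
  out
}

#' Rarefied private allelic richness
#'
#' Expected number of alleles present in a `g`-copy subsample of the focal
#' population and absent from independent `g`-copy subsamples of every other
#' population: `P_g = sum_a Q_a(focal) prod_j (1 - Q_a(j))` in the exact
#' mode, where `Q_a(pop)` is the hypergeometric presence probability; the
#' Monte-Carlo mode subsamples every population and counts alleles seen only
#' in the focal one.
#'
#' @inheritParams rarefied_richness
#' @param focal focal population name.
#' @return list like [rarefied_richness()] with `P_g` columns (Monte-Carlo
#'   mode adds a `replicates` vector of across-locus means).
#' @export
private_rarefied_richness <- function(table, focal, g = 18, by = "population",
                                      mode = c("exact", "monte_carlo"),
                                      reps = 1000, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  af <- allele_freqs(table, by = by)
  if (!focal %in% af$populations) stop("unknown focal population ", focal)
  if (length(af$populations) < 2) stop("need at least two populations")
  others <- setdiff(af$populations, focal)
  nuc <- intersect(af$loci, nuclear_loci(table))
  rows <- list()
  repmat <- if (mode == "monte_carlo") matrix(0, length(nuc), reps)
  for (li in seq_along(nuc)) {
    l <- nuc[li]
    m <- af$counts[[l]]
    Ns <- rowSums(m)
    if (g > min(Ns)) stop("g = ", g, " exceeds haploid sample size of population ",
                          rownames(m)[which.min(Ns)], " at locus ", l)
    if (mode == "exact") {
      q_focal <- .rarefied_presence(m[focal, ], Ns[focal], g)
      prod_absent <- rep(1, ncol(m))
      for (j in others)
        prod_absent <- prod_absent * (1 - .rarefied_presence(m[j, ], Ns[j], g))
      rows[[length(rows) + 1L]] <- data.frame(
        population = focal, locus = l, P_g = sum(q_focal * prod_absent),
        stringsAsFactors = FALSE)
    } else {
      draws <- vapply(seq_len(reps), function(r) {
        seen <- lapply(af$populations, function(p) {
          copies <- rep(seq_len(ncol(m)), m[p, ])
          unique(copies[sample.int(length(copies), g)])
        })
        names(seen) <- af$populations
        length(setdiff(seen[[focal]], unlist(seen[others])))
      }, numeric(1))
      repmat[li, ] <- draws
      rows[[length(rows) + 1L]] <- data.frame(
        population = focal, locus = l, P_g = mean(draws), sd = stats::sd(draws),
        stringsAsFactors = FALSE)
    }
  }
  per_locus <- do.call(rbind, rows)
  out <- list(per_locus = per_locus,
              by_population = data.frame(population = focal,
                                         P_g = mean(per_locus$P_g)),
              g = g, mode = mode)
  if (mode == "monte_carlo") out$replicates <- colMeans(repmat)
  out
}

#' Tukey HSD grouping letters
#'
#' One-way ANOVA of replicate values across populations followed by Tukey's
#' honest significant difference test; populations that are not significantly
#' different at level `alpha` share a letter (standard insert-and-absorb
#' assignment, letters ordered by decreasing mean).
#'
#' @param values numeric vector of replicate values.
#' @param population factor/character vector of the same length.
#' @param alpha significance threshold.
#' @return data.frame with columns `population`, `mean`, `group` (letters).
#' @export
tukey_groups <- function(values, population, alpha = 0.05) {
  population <- as.character(population)
  stopifnot(length(values) == length(population))
  pops <- names(sort(tapply(values, population, mean), decreasing = TRUE))
  k <- length(pops)
  if (k < 2) stop("need at least two populations")
  if (stats::var(values) == 0) {
    return(data.frame(population = pops,
                      mean = as.numeric(tapply(values, population, mean)[pops]),
                      group = "a", stringsAsFactors = FALSE))
  }
  fit <- stats::aov(values ~ factor(population))
  hsd <- stats::TukeyHSD(fit, conf.level = 1 - alpha)[[1]]
  padj <- hsd[, "p adj"]
  pair_names <- strsplit(rownames(hsd), "-", fixed = TRUE)
  # insert-and-absorb (Piepho-style): start from one all-inclusive group and
  # split it at every significant pair, absorbing subset groups
  absorb <- function(groups) {
    keep <- rep(TRUE, length(groups))
    for (i in seq_along(groups)) for (j in seq_along(groups))
      if (i != j && keep[i] && keep[j] &&
          all(groups[[i]] %in% groups[[j]]) &&
          !(length(groups[[i]]) == length(groups[[j]]) && i < j))
        keep[i] <- FALSE
    groups[keep]
  }
  groups <- list(pops)
  sig <- which(!is.na(padj) & padj <= alpha)
  for (s in sig) {
    a <- pair_names[[s]][1]; b <- pair_names[[s]][2]
    new_groups <- list()
    for (g in groups) {
      if (all(c(a, b) %in% g)) {
        new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
      } else new_groups <- c(new_groups, list(g))
    }
    groups <- absorb(new_groups)
  }
  # letters ordered by the best mean each group contains
  ord <- order(vapply(groups, function(g) min(match(g, pops)), numeric(1)))
  groups <- groups[ord]
  letters_of <- vapply(pops, function(p)
    paste(letters[which(vapply(groups, function(g) p %in% g, logical(1)))],
          collapse = ""), character(1))
  data.frame(population = pops,
             mean = as.numeric(tapply(values, population, mean)[pops]),
             group = unname(letters_of), stringsAsFactors = FALSE)
}

#' Per-locus summary statistics
#'
#' The per-locus quality table of a genotyping campaign: missing-data
#' percentage, allele count, PIC, observed and expected heterozygosity, null
#' allele frequency (both estimators) and a Hardy-Weinberg p-value. Plastid
#' loci report only missingness and allele count.
#'
#' @param table a [genotype_table()].
#' @param hwe_mode passed to [hwe_test()].
#' @param B,seed Monte-Carlo settings for [hwe_test()].
#' @return data.frame, one row per locus.
#' @export
locus_stats <- function(table, hwe_mode = "chi2", B = 999, seed = NULL) {
  het <- observed_expected_het(table, by = NULL)
  hwe <- hwe_test(table, mode = hwe_mode, B = B, seed = seed)
  rows <- lapply(table$loci$name, function(l) {
    kind <- locus_kind(table, l)
    if (kind == "nuclear") {
      miss <- mean(is.na(table$a1[, l]))
      p <- table(c(table$a1[, l], table$a2[, l]))
      p <- p / sum(p)
      h <- het[het$locus == l, ]
      data.frame(locus = l, kind = kind, missing_pct = round(100 * miss, 2),
                 n_alleles = length(p), PIC = pic(as.numeric(p)),
                 Ho = h$Ho, He = h$Hs,
                 null_brookfield1 = as.numeric(null_allele_freq(h$Ho, h$Hs, "brookfield1")),
                 null_chakraborty = as.numeric(null_allele_freq(h$Ho, h$Hs, "chakraborty")),
                 hwe_p = hwe$p[hwe$locus == l], stringsAsFactors = FALSE)
    } else {
      miss <- mean(is.na(table$plastid[, l]))
      data.frame(locus = l, kind = kind, missing_pct = round(100 * miss, 2),
                 n_alleles = length(allele_domain(table, l)), PIC = NA_real_,
                 Ho = NA_real_, He = NA_real_, null_brookfield1 = NA_real_,
                 null_chakraborty = NA_real_, hwe_p = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
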