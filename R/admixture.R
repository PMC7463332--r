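#' Bayesian admixture clustering by Gibbs sampling
#'
#' Model-based clustering of multilocus diploid genotypes into `K` clusters
#' under the admixture model: each individual has ancestry proportions
#' `q_i` (a point on the K-simplex) and each cluster per-locus allele
#' frequencies `p_kl`; every allele copy arises from a cluster drawn from
#' `q_i` and then from that cluster's frequencies. The sampler augments the
#' data with per-copy cluster assignments and alternates conjugate Dirichlet
#' updates of `Q` and `P`; under the correlated-frequency F-model, `P` is
#' shrunk towards ancestral frequencies with per-cluster drift `F_k`, both
#' updated by Metropolis-Hastings (drift prior Uniform(0.001, 0.5)). Missing
#' calls are skipped in the likelihood; the haploid plastid locus is excluded
#' by default.
#'
#' The `log_P_D` summary is the standard harmonic-style estimate
#' `mean(L) - var(L)/2` over post-burn-in iterations, the quantity compared
#' across `K` in model selection.
#'
#' @param table a [genotype_table()].
#' @param K number of clusters (>= 1).
#' @param burn_in,iters burn-in and sampling iteration counts.
#' @param alpha initial symmetric Dirichlet parameter on ancestry
#'   proportions; by default `alpha` is itself inferred by a
#'   Metropolis-Hastings random walk with uniform prior on (0.001, 10), the
#'   standard treatment that lets the posterior sharpen when populations are
#'   discrete (`infer_alpha = FALSE` keeps it fixed).
#' @param infer_alpha update `alpha` by MH (default `TRUE`).
#' @param lambda Dirichlet prior on allele frequencies (independent model) or
#'   on the ancestral frequencies (correlated model).
#' @param model `"independent"` (default) or `"correlated"`.
#' @param loci loci entering the likelihood (default all nuclear loci).
#' @param seed optional integer seed; fixed seed gives identical results.
#' @return object of class `admixture_fit`: list with `Q` (posterior-mean
#'   ancestry, rows sum to 1), `P` (allele x locus x cluster posterior-mean
#'   frequencies), `trace` (per-iteration log-likelihood, length
#'   `burn_in + iters`), `log_P_D`, `K`, `F` (final drift values, correlated
#'   model), and the settings used.
#' @export
gibbs_admixture <- function(table, K, burn_in = 1000, iters = 10000,
                            alpha = 1, lambda = 1,
                            model = c("independent", "correlated"),
                            infer_alpha = TRUE,
                            loci = nuclear_loci(table), seed = NULL) {
  model <- match.arg(model)
  stopifnot(K >= 1, burn_in >= 0, iters >= 1)
  if (K > n_accessions(table))
    stop("K exceeds the number of accessions")
  if (!length(loci)) stop("no loci selected")
  if (!is.null(seed)) set.seed(seed)
  domains <- lapply(loci, function(l) allele_domain(table, l))
  enc <- function(m) {
    out <- vapply(seq_along(loci), function(j) {
      idx <- match(m[, loci[j]], domains[[j]])
      idx[is.na(idx)] <- 0L
      idx
    }, integer(n_accessions(table)))
    matrix(out, nrow = n_accessions(table))
  }
  res <- .gibbs_admixture_cpp(enc(table$a1), enc(table$a2),
                              vapply(domains, length, integer(1)),
                              as.integer(K), as.integer(burn_in),
                              as.integer(iters), alpha, lambda,
                              as.integer(model == "correlated"),
                              as.integer(infer_alpha))
  post <- res$trace[(burn_in + 1):(burn_in + iters)]
  rownames(res$Q) <- accessions(table)
  if (any(!is.finite(res$trace)))
    stop("non-finite likelihood encountered; aborting (check input genotypes)")
  structure(list(Q = res$Q, P = res$P, trace = res$trace,
                 log_P_D = mean(post) - stats::var(post) / 2,
                 K = K, F = res$F, model = model, burn_in = burn_in,
                 iters = iters, alpha = alpha, alpha_final = res$alpha_final,
                 infer_alpha = infer_alpha, lambda = lambda,
                 loci = loci, seed = seed),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d (%s model), %d accessions, %d loci\n",
              x$K, x$model, nrow(x$Q), length(x$loci)))
  cat(sprintf("burn-in %d + %d iterations; log P(D) = %.1f\n",
              x$burn_in, x$iters, x$log_P_D))
  invisible(x)
}

#' Align clusters across replicate runs
#'
#' MCMC runs of the same `K` differ by arbitrary cluster relabelling. Each
#' run is greedily permuted to maximise ancestry agreement (column
#' cross-products of `Q`) against the highest-likelihood run, and the mean
#' aligned `Q` is returned.
#'
#' @param runs list of [gibbs_admixture()] fits with identical `K` and
#'   accession order.
#' @return list with `runs` (aligned fits), `mean_Q`, `reference` (index of
#'   the reference run), `permutations`.
#' @export
align_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  K <- runs[[1]]$K
  acc <- rownames(runs[[1]]$Q)
  for (r in runs) {
    if (r$K != K) stop("runs have different K")
    if (!identical(rownames(r$Q), acc)) stop("runs have mismatched accessions")
  }
  ref <- which.max(vapply(runs, `[[`, numeric(1), "log_P_D"))
  Qref <- runs[[ref]]$Q
  perms <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    S <- crossprod(runs[[ri]]$Q, Qref)   # S[j, k] = agreement of run col j with ref col k
    perm <- integer(K)
    Sw <- S
    for (step in seq_len(K)) {
      ij <- which(Sw == max(Sw), arr.ind = TRUE)[1, ]
      perm[ij[2]] <- ij[1]
      Sw[ij[1], ] <- -Inf; Sw[, ij[2]] <- -Inf
    }
    perms[[ri]] <- perm
    runs[[ri]]$Q <- runs[[ri]]$Q[, perm, drop = FALSE]
    colnames(runs[[ri]]$Q) <- NULL
    runs[[ri]]$P <- runs[[ri]]$P[, , perm, drop = FALSE]
  }
  mean_Q <- Reduce(`+`, lapply(runs, `[[`, "Q")) / length(runs)
  list(runs = runs, mean_Q = mean_Q, reference = ref, permutations = perms)
}

#' Evanno delta-K table
#'
#' Second-order rate of change of the model log-likelihood across `K`:
#' `L'(K) = L(K) - L(K-1)` on run means, `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `deltaK = |L''(K)| / sd(L(K))` over replicate runs. `deltaK` is defined
#' only for interior K with positive run-to-run standard deviation. The modal
#' K by delta-K (argmax) and by mean likelihood are both reported, as
#' practice uses both criteria.
#'
#' @param loglik named list: for each K (names are the K values), a numeric
#'   vector of per-run final log-likelihoods (e.g. `log_P_D` of
#'   [gibbs_admixture()] fits).
#' @return list with `table` (data.frame K, n_runs, mean_L, sd_L, Lprime,
#'   Lpp, deltaK, reason), `modal_K_evanno`, `modal_K_likelihood`.
#' @export
evanno <- function(loglik) {
  Ks <- as.integer(names(loglik))
  if (anyNA(Ks)) stop("loglik must be a named list with K values as names")
  ord <- order(Ks)
  Ks <- Ks[ord]; loglik <- loglik[ord]
  if (any(diff(Ks) != 1) || length(Ks) < 3)
    stop("need at least 3 consecutive K values")
  mean_L <- vapply(loglik, mean, numeric(1))
  sd_L <- vapply(loglik, stats::sd, numeric(1))
  m <- length(Ks)
  Lprime <- c(NA, diff(mean_L))
  Lpp <- rep(NA_real_, m)
  Lpp[2:(m - 1)] <- abs(Lprime[3:m] - Lprime[2:(m - 1)])
  deltaK <- Lpp / sd_L
  reason <- rep(NA_character_, m)
  reason[is.na(Lpp)] <- "boundary K: L'' undefined"
  zero_sd <- !is.na(Lpp) & (is.na(sd_L) | sd_L == 0)
  if (any(zero_sd)) {
    reason[zero_sd] <- "zero run-to-run sd: deltaK undefined"
    deltaK[zero_sd] <- NA_real_
    warning("deltaK undefined at K = ",
            paste(Ks[zero_sd], collapse = ", "), " (zero sd)")
  }
  tab <- data.frame(K = Ks, n_runs = lengths(loglik), mean_L = mean_L,
                    sd_L = sd_L, Lprime = Lprime, Lpp = Lpp, deltaK = deltaK,
                    reason = reason, row.names = NULL,
                    stringsAsFactors = FALSE)
  modal <- if (all(is.na(deltaK))) NA_integer_ else
    Ks[which.max(ifelse(is.na(deltaK), -Inf, deltaK))]
  list(table = tab, modal_K_evanno = modal,
       modal_K_likelihood = Ks[which.max(mean_L)])
}

#' Per-population mean ancestry
#'
#' @param Q ancestry matrix (accessions x K), e.g. `mean_Q` of
#'   [align_runs()].
#' @param populations character vector of population labels per accession.
#' @return matrix (populations x K) of column means; rows sum to 1.
#' @export
ancestry_summary <- function(Q, populations) {
  stopifnot(nrow(Q) == length(populations))
  out <- rowsum(Q, populations) / as.vector(table(populations)[sort(unique(populations))])
  out[order(rownames(out)), , drop = FALSE]
}

#' Multi-run, multi-K admixture sweep
#'
#' Runs [gibbs_admixture()] for each K in `K_range`, `n_runs` independent
#' seeded runs per K, aligns runs within K and assembles the Evanno table.
#'
#' @param table a [genotype_table()].
#' @param K_range integer vector of K values (consecutive for Evanno).
#' @param n_runs runs per K.
#' @param seed base seed; run r of K uses `seed + 1000 * K + r`.
#' @param ... passed to [gibbs_admixture()].
#' @return list with `fits` (list per K of run fits), `aligned` (per-K
#'   [align_runs()] results), `evanno` (when `K_range` allows it).
#' @export
admixture_sweep <- function(table, K_range = 1:4, n_runs = 5, seed = 1, ...) {
  fits <- list()
  for (K in K_range) {
    fits[[as.character(K)]] <- lapply(seq_len(n_runs), function(r)
      gibbs_admixture(table, K, seed = seed + 1000L * K + r, ...))
  }
  aligned <- lapply(fits, align_runs)
  ll <- lapply(fits, function(fl) vapply(fl, `[[`, numeric(1), "log_P_D"))
  ev <- if (length(K_range) >= 3 && all(diff(sort(K_range)) == 1))
    evanno(ll)
  list(fits = fits, aligned = aligned, loglik = ll, evanno = ev)
}
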