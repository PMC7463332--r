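#' Allele dosage matrix
#'
#' Expands nuclear genotypes into an accessions x (locus, allele) matrix of
#' allele counts (0/1/2). Missing calls are imputed with the column mean
#' dosage (the mean-allele-frequency imputation conventional before PCA);
#' columns with no observed call are dropped with a warning.
#'
#' @param table a [genotype_table()].
#' @return numeric matrix with columns named `<locus>.<allele>`; attribute
#'   `imputed` marks imputed cells.
#' @export
dosage_matrix <- function(table) {
  nuc <- nuclear_loci(table)
  if (!length(nuc)) stop("table has no nuclear locus")
  n <- n_accessions(table)
  cols <- list(); imput <- list()
  for (l in nuc) {
    al <- allele_domain(table, l)
    al <- al[!is.na(al)]
    for (a in al) {
      d <- (table$a1[, l] == a) + (table$a2[, l] == a)
      miss <- is.na(table$a1[, l])
      if (all(miss)) next
      d[miss] <- mean(d[!miss])
      cols[[paste0(l, ".", a)]] <- d
      imput[[paste0(l, ".", a)]] <- miss
    }
    if (!length(allele_domain(table, l)))
      warning("locus ", l, " has no observed call; dropped")
  }
  m <- do.call(cbind, cols)
  rownames(m) <- accessions(table)
  attr(m, "imputed") <- do.call(cbind, imput)
  m
}

#' Principal component analysis of allele dosages
#'
#' Columns are centred (and optionally scaled to unit variance) before a
#' singular value decomposition. Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so results are
#' deterministic and invariant to accession order up to that convention.
#'
#' @param dosage matrix from [dosage_matrix()] (or any numeric matrix).
#' @param n_components number of components to keep.
#' @param scale scale columns to unit variance (default centre-only).
#' @return object of class `dosage_pca`: list with `scores`, `explained`
#'   (variance fractions, nonincreasing), `loadings`.
#' @export
pca_dosage <- function(dosage, n_components = 10, scale = FALSE) {
  if (nrow(dosage) < 2) stop("need at least 2 accessions")
  x <- scale(dosage, center = TRUE, scale = scale)
  if (scale) x[, attr(x, "scaled:scale") == 0] <- 0
  x[is.na(x)] <- 0
  sv <- svd(x)
  pos <- sv$d > max(sv$d) * 1e-10
  if (!any(pos)) stop("dosage matrix has rank 0")
  k <- min(n_components, sum(pos))
  d <- sv$d[seq_len(k)]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(dosage)
  rownames(loadings) <- colnames(dosage)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained = (sv$d^2)[seq_len(k)] / sum((sv$d^2)[pos]),
                 loadings = loadings),
            class = "dosage_pca")
}

#' @export
print.dosage_pca <- function(x, ...) {
  cat("dosage_pca:", nrow(x$scores), "accessions,",
      ncol(x$scores), "components\n")
  cat("explained:", paste(sprintf("%.1f%%", 100 * x$explained), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
plot.dosage_pca <- function(x, components = c(1, 2), col = 1, ...) {
  lab <- sprintf("PC%d (%.1f%%)", components, 100 * x$explained[components])
  plot(x$scores[, components[1]], x$scores[, components[2]],
       xlab = lab[1], ylab = lab[2], col = col, ...)
  invisible(x)
}

#' Weir-Cockerham FST
#'
#' The Weir and Cockerham (1984) variance-components estimator theta for
#' codominant multiallelic data. Per allele at each locus the among-
#' population (a), among-individual (b) and within-individual (c) components
#' are computed; the per-locus and multilocus estimates are ratios of sums,
#' `theta = sum(a) / sum(a + b + c)`.
#'
#' @param table a [genotype_table()].
#' @param populations restrict to these populations (default all with data).
#' @param by population column.
#' @return list with `theta` (multilocus), `per_locus` (data.frame locus,
#'   a, b, c, theta), `populations`.
#' @export
wc_fst <- function(table, populations = NULL, by = "population") {
  pop <- table$meta[[by]]
  if (is.null(populations)) populations <- unique(stats::na.omit(pop))
  if (length(populations) < 2) stop("need at least 2 populations")
  sel <- !is.na(pop) & pop %in% populations
  rows <- list()
  for (l in nuclear_loci(table)) {
    x1 <- table$a1[sel, l]; x2 <- table$a2[sel, l]
    pp <- pop[sel]
    ok <- !is.na(x1)
    x1 <- x1[ok]; x2 <- x2[ok]; pp <- pp[ok]
    ni <- table(pp)
    ni <- ni[ni > 0]
    if (length(ni) < 2) next
    r <- length(ni)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(c(x1, x2)))
    A <- B <- C <- 0
    for (a in alleles) {
      p_i <- vapply(names(ni), function(p)
        (sum(x1[pp == p] == a) + sum(x2[pp == p] == a)) / (2 * ni[[p]]),
        numeric(1))
      h_i <- vapply(names(ni), function(p) {
        het <- (x1[pp == p] == a) != (x2[pp == p] == a)
        mean(het)
      }, numeric(1))
      pbar <- sum(ni * p_i) / (r * nbar)
      s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * h_i) / (r * nbar)
      a_c <- nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b_c <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      c_c <- hbar / 2
      A <- A + a_c; B <- B + b_c; C <- C + c_c
    }
    rows[[length(rows) + 1L]] <- data.frame(
      locus = l, a = A, b = B, c = C,
      theta = if (A + B + C == 0) NA_real_ else A / (A + B + C),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no locus with data in at least 2 populations")
  per_locus <- do.call(rbind, rows)
  denom <- sum(per_locus$a + per_locus$b + per_locus$c)
  list(theta = if (denom == 0) NA_real_ else sum(per_locus$a) / denom,
       per_locus = per_locus, populations = populations)
}

#' Pairwise Weir-Cockerham FST table
#'
#' @inheritParams wc_fst
#' @return data.frame with columns `pop1`, `pop2`, `theta`.
#' @export
wc_fst_pairwise <- function(table, populations = NULL, by = "population") {
  pop <- table$meta[[by]]
  if (is.null(populations)) populations <- unique(stats::na.omit(pop))
  pairs <- .pair_indices(seq_along(populations))
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    ps <- populations[pairs[k, ]]
    data.frame(pop1 = ps[1], pop2 = ps[2],
               theta = wc_fst(table, ps, by = by)$theta,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Proportion of shared alleles between two populations
#'
#' By default the Jaccard ratio |A∩B| / |A∪B| of the populations' allele
#' sets pooled over nuclear loci; `mode = "focal"` reports |A∩B| / |A| for
#' the first population.
#'
#' @param table a [genotype_table()].
#' @param pop1,pop2 population names.
#' @param mode `"jaccard"` or `"focal"`.
#' @param by population column.
#' @return list with `proportion`, `mode` and per-locus data.frame.
#' @export
shared_allele_proportion <- function(table, pop1, pop2,
                                     mode = c("jaccard", "focal"),
                                     by = "population") {
  mode <- match.arg(mode)
  pop <- table$meta[[by]]
  sets <- function(p, l) {
    sel <- !is.na(pop) & pop == p
    unique(stats::na.omit(c(table$a1[sel, l], table$a2[sel, l])))
  }
  inter <- tot <- 0
  per_locus <- list()
  for (l in nuclear_loci(table)) {
    s1 <- sets(pop1, l); s2 <- sets(pop2, l)
    i <- length(intersect(s1, s2))
    d <- if (mode == "jaccard") length(union(s1, s2)) else length(s1)
    inter <- inter + i; tot <- tot + d
    per_locus[[length(per_locus) + 1L]] <- data.frame(
      locus = l, shared = i, denom = d, stringsAsFactors = FALSE)
  }
  if (tot == 0)
    return(list(proportion = NA_real_, mode = mode,
                reason = "empty allele sets"))
  list(proportion = inter / tot, mode = mode,
       per_locus = do.call(rbind, per_locus))
}

#' Genetic distances
#'
#' Two distances serving two displays: `euclidean_dosage` is the Euclidean
#' distance between rows of the (imputed, uncentred) allele dosage matrix,
#' suited to accession-level heatmaps and trees; `nei1972` is Nei's standard
#' genetic distance `D = -ln I` with the identity `I` pooled over loci,
#' `I = sum_l sum_a x_a y_a / sqrt(sum x^2 * sum y^2)`, computed between
#' populations (or between accessions treated as single-individual
#' populations). `I = 0` is capped at `D = ln(1/eps)`, `eps = 1e-12`.
#'
#' @param table a [genotype_table()].
#' @param method `"euclidean_dosage"` or `"nei1972"`.
#' @param level `"accession"` or `"population"`.
#' @param by population column for `level = "population"`.
#' @return a `dist` object with attribute `metric`.
#' @export
genetic_distance <- function(table,
                             method = c("euclidean_dosage", "nei1972"),
                             level = c("accession", "population"),
                             by = "population") {
  method <- match.arg(method)
  level <- match.arg(level)
  if (method == "euclidean_dosage") {
    if (level != "accession")
      stop("euclidean_dosage is an accession-level distance")
    d <- stats::dist(dosage_matrix(table))
  } else {
    groups <- if (level == "accession") accessions(table) else {
      p <- table$meta[[by]]; p[is.na(p)] <- "(unassigned)"; p
    }
    key <- if (level == "accession") "accession" else by
    units <- unique(groups)
    freq <- .nei_freq_matrix(table, groups, units)
    n <- length(units)
    m <- matrix(0, n, n, dimnames = list(units, units))
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      m[i, j] <- m[j, i] <- nei_distance_vec(freq[i, ], freq[j, ])
    }
    d <- stats::as.dist(m)
  }
  attr(d, "metric") <- method
  d
}

# per-unit pooled allele-frequency matrix over nuclear loci
.nei_freq_matrix <- function(table, groups, units) {
  cols <- list()
  for (l in nuclear_loci(table)) {
    al <- allele_domain(table, l)
    for (a in al) cols[[paste0(l, ".", a)]] <- rep(0, length(units))
  }
  freq <- do.call(cbind, cols)
  rownames(freq) <- units
  for (u in units) {
    sel <- groups == u
    for (l in nuclear_loci(table)) {
      v <- c(table$a1[sel, l], table$a2[sel, l])
      v <- v[!is.na(v)]
      if (!length(v)) next
      tab <- table(v) / length(v)
      freq[u, paste0(l, ".", names(tab))] <- as.numeric(tab)
    }
  }
  freq
}

#' Nei (1972) distance between two pooled frequency vectors
#'
#' @param x,y numeric vectors of allele frequencies pooled over loci
#'   (concatenated per-locus frequency vectors on the same allele layout).
#' @param eps cap: `I < eps` returns `-log(eps)` with attribute
#'   `capped = TRUE`.
#' @return non-negative distance `D = -ln I`.
#' @export
nei_distance_vec <- function(x, y, eps = 1e-12) {
  jxy <- sum(x * y)
  jx <- sum(x^2); jy <- sum(y^2)
  if (jx == 0 || jy == 0) return(structure(-log(eps), capped = TRUE))
  I <- jxy / sqrt(jx * jy)
  if (I < eps) return(structure(-log(eps), capped = TRUE))
  d <- max(0, -log(I))
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration of a symmetric distance matrix (via [ape::nj()]);
#' negative branch lengths are clamped to zero and flagged through the
#' `clamped` attribute. NJ is exact on additive distances.
#'
#' @param d a `dist` or symmetric matrix with labels.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (nrow(m) < 3) stop("need at least 3 labels")
  tree <- ape::nj(stats::as.dist(m))
  clamped <- tree$edge.length < 0
  tree$edge.length[clamped] <- 0
  attr(tree, "clamped") <- any(clamped)
  tree
}

#' Bootstrapped neighbor-joining tree
#'
#' Resamples loci (columns) with replacement `B` times, rebuilds the tree on
#' each replicate, and reports for every internal bipartition of the main
#' tree the percentage of replicate trees containing it (stored as
#' `node.label`). A display threshold of 80% is conventional; nothing is
#' filtered.
#'
#' @param table a [genotype_table()].
#' @param method distance metric, see [genetic_distance()].
#' @param B bootstrap replicates (`0` skips supports).
#' @param seed optional seed.
#' @return an [ape::phylo] tree with `node.label` supports in \[0, 100\]
#'   (absent when `B = 0`).
#' @export
bootstrap_nj <- function(table, method = "nei1972", B = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  main <- nj_tree(genetic_distance(table, method, level = "accession"))
  if (B == 0) return(main)
  nuc <- nuclear_loci(table)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    pick <- sample(nuc, length(nuc), replace = TRUE)
    boot_tab <- .subset_loci(table, pick)
    boots[[b]] <- nj_tree(genetic_distance(boot_tab, method,
                                           level = "accession"))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- round(100 * counts / B, 1)
  main
}

# duplicate-tolerant locus subset (bootstrap resamples repeat loci)
.subset_loci <- function(table, loci) {
  new_names <- make.unique(loci)
  meta <- table$meta
  a1 <- table$a1[, loci, drop = FALSE]
  a2 <- table$a2[, loci, drop = FALSE]
  colnames(a1) <- colnames(a2) <- new_names
  genotype_table(meta, data.frame(name = new_names, kind = "nuclear"),
                 a1, a2, NULL)
}
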