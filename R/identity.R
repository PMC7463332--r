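#' Pairwise multilocus identity
#'
#' For every unordered pair of accessions, counts the loci at which both calls
#' are non-missing (`n_compared`) and the compared loci with identical
#' unordered genotypes (`n_match`); `identity = n_match / n_compared`. Loci
#' missing in either member are excluded from the denominator. For the plastid
#' locus a pair is a match, mismatch, or incomparable (either call missing).
#'
#' @param table a [genotype_table()] with at least 2 accessions.
#' @param locus_set `"nuclear"` or `"plastid"`.
#' @return object of class `pairwise_identity`: list with `accessions` and
#'   symmetric matrices `n_compared`, `n_match`, `identity` (NaN where no
#'   locus is comparable). For `locus_set = "plastid"`, `n_compared` is 0/1.
#' @export
pairwise_identity <- function(table, locus_set = c("nuclear", "plastid")) {
  locus_set <- match.arg(locus_set)
  n <- n_accessions(table)
  if (n < 2) stop("need at least 2 accessions")
  loci <- if (locus_set == "nuclear") nuclear_loci(table) else plastid_loci(table)
  if (!length(loci))
    stop("table has no ", locus_set, " locus (configuration error)")
  code <- if (locus_set == "nuclear") nuclear_codes(table)
          else table$plastid[, loci, drop = FALSE]
  ok <- !is.na(code)
  ncomp <- tcrossprod(ok * 1L)
  nmatch <- matrix(0L, n, n)
  for (l in seq_along(loci)) {
    v <- code[, l]
    eq <- outer(v, v, "==")
    eq[is.na(eq)] <- FALSE
    nmatch <- nmatch + eq
  }
  id <- nmatch / ncomp
  dimnames(ncomp) <- dimnames(nmatch) <- dimnames(id) <-
    list(accessions(table), accessions(table))
  structure(list(accessions = accessions(table), locus_set = locus_set,
                 n_compared = ncomp, n_match = nmatch, identity = id),
            class = "pairwise_identity")
}

#' @export
print.pairwise_identity <- function(x, ...) {
  n <- length(x$accessions)
  cat(sprintf("pairwise_identity (%s): %d accessions, %d pairs\n",
              x$locus_set, n, n * (n - 1) / 2))
  invisible(x)
}

.pair_indices <- function(idx) {
  if (length(idx) < 2) return(matrix(integer(), 0, 2))
  t(utils::combn(idx, 2))
}

#' Per-named-type identity statistic
#'
#' The identity of a named type is the unweighted mean, over all unordered
#' pairs of its accessions, of the proportion of matching nuclear genotypes
#' among compared loci (`nuc_identity`), and the fraction of comparable pairs
#' with equal plastid allele (`cp_identity`), both as percentages. A set of
#' true clones scores 100/100. Pairs with fewer than `min_compared` compared
#' nuclear loci are excluded from the mean and counted.
#'
#' @param table a [genotype_table()].
#' @param named_type named-type label to evaluate.
#' @param min_compared minimum compared nuclear loci for a pair to enter the
#'   mean.
#' @param nuc,cp optional precomputed [pairwise_identity()] objects for the
#'   full table (saves recomputation when reporting many types).
#' @return list with `named_type`, `n`, `nuc_identity` (%), `cp_identity`
#'   (%), `n_pairs`, `n_excluded`, and `reason` (non-`NA` when the statistic
#'   is undefined, e.g. fewer than two accessions).
#' @export
named_type_identity <- function(table, named_type, min_compared = 12,
                                nuc = NULL, cp = NULL) {
  idx <- which(!is.na(table$meta$named_type) &
                 table$meta$named_type == named_type)
  out <- list(named_type = named_type, n = length(idx),
              nuc_identity = NA_real_, cp_identity = NA_real_,
              n_pairs = 0L, n_excluded = 0L, reason = NA_character_)
  if (length(idx) < 2) {
    out$reason <- "fewer than two sampled accessions"
    return(out)
  }
  if (is.null(nuc)) nuc <- pairwise_identity(table, "nuclear")
  pairs <- .pair_indices(idx)
  ncomp <- nuc$n_compared[pairs]
  usable <- ncomp >= min_compared
  out$n_pairs <- sum(usable)
  out$n_excluded <- sum(!usable)
  if (any(usable))
    out$nuc_identity <- 100 * mean(nuc$identity[pairs][usable])
  else out$reason <- "no pair with enough compared loci"
  if (length(plastid_loci(table))) {
    if (is.null(cp)) cp <- pairwise_identity(table, "plastid")
    comp <- cp$n_compared[pairs] >= 1
    if (any(comp))
      out$cp_identity <- 100 * mean(cp$identity[pairs][comp])
  }
  out
}

#' Clone-line partition
#'
#' Builds the graph whose edges join accession pairs with at most `t`
#' mismatching compared nuclear loci (and at least `min_compared` compared
#' loci) and returns its connected components as clone lines. The tolerance
#' `t = 1` accepts single-locus deviations as somatic mutations or genotyping
#' errors. Line IDs are the lexicographically smallest member, so the
#' partition is independent of input order.
#'
#' @param table a [genotype_table()].
#' @param t maximum mismatching compared loci within a line edge.
#' @param min_compared minimum compared loci for a pair to be linkable.
#' @param nuc optional precomputed nuclear [pairwise_identity()].
#' @return object of class `clone_partition`: data.frame `lines` (accession,
#'   line) plus parameters.
#' @export
clone_partition <- function(table, t = 1, min_compared = 12, nuc = NULL) {
  stopifnot(t >= 0, min_compared >= 1)
  n <- n_accessions(table)
  acc <- accessions(table)
  if (n == 1) {
    lines <- data.frame(accession = acc, line = acc, stringsAsFactors = FALSE)
  } else {
    if (is.null(nuc)) nuc <- pairwise_identity(table, "nuclear")
    adj <- (nuc$n_compared - nuc$n_match) <= t & nuc$n_compared >= min_compared
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
    for (e in seq_len(nrow(edges))) {
      ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
      if (ri != rj) parent[ri] <- rj
    }
    root <- vapply(seq_len(n), find, integer(1))
    line <- stats::ave(acc, root, FUN = function(v) rep(min(v), length(v)))
    lines <- data.frame(accession = acc, line = line, stringsAsFactors = FALSE)
  }
  structure(list(lines = lines, t = t, min_compared = min_compared),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  sizes <- table(x$lines$line)
  cat(sprintf("clone_partition: %d accessions in %d lines (t = %d, min_compared = %d)\n",
              nrow(x$lines), length(sizes), x$t, x$min_compared))
  cat(sprintf("multi-accession lines: %d (largest: %d)\n",
              sum(sizes > 1), max(sizes)))
  invisible(x)
}

#' Remove duplicated genotypes
#'
#' Keeps one representative per clone line: the member with the fewest
#' missing calls, ties broken by lexicographically smallest accession ID.
#'
#' @param table a [genotype_table()].
#' @param partition a [clone_partition()] over the table's accessions.
#' @return the deduplicated [genotype_table()], with attributes `n_removed`
#'   and `removed` (the dropped accession IDs).
#' @export
deduplicate <- function(table, partition) {
  stopifnot(inherits(partition, "clone_partition"))
  if (!setequal(partition$lines$accession, accessions(table)))
    stop("partition does not cover the table's accessions")
  nmiss <- rowSums(is.na(table$a1)) + rowSums(is.na(table$plastid))
  names(nmiss) <- accessions(table)
  keep <- vapply(split(partition$lines$accession, partition$lines$line),
                 function(members) {
                   members <- sort(members)
                   members[which.min(nmiss[members])]
                 }, character(1))
  keep <- accessions(table)[accessions(table) %in% keep]   # original order
  out <- subset_accessions(table, keep)
  attr(out, "n_removed") <- n_accessions(table) - length(keep)
  attr(out, "removed") <- setdiff(accessions(table), keep)
  out
}

#' Classify a named type
#'
#' Applies the ethnobotanical classification rule to the clone structure of a
#' named type: a single accession is inconclusive; all accessions in one
#' clone line make a true-to-type cultivar (offshoot-propagated); at least
#' one multi-accession clone line spanning distinct gardens alongside at
#' least one other genotype makes an ethnovariety; otherwise the type is a
#' local category. A multi-accession line confined to a single garden is
#' discounted as evidence of clonal propagation (the two palms may simply be
#' offshoots planted side by side) and reported as a caveat.
#'
#' @param table a [genotype_table()].
#' @param partition a [clone_partition()] computed on the full table.
#' @param named_type named-type label.
#' @return list with `named_type`, `n`, `n_clone_lines`, `largest_line`,
#'   `classification` and `caveat` (`NA` or a same-garden note).
#' @export
classify_named_type <- function(table, partition, named_type) {
  idx <- which(!is.na(table$meta$named_type) &
                 table$meta$named_type == named_type)
  acc <- accessions(table)[idx]
  line <- partition$lines$line[match(acc, partition$lines$accession)]
  garden <- table$meta$garden[idx]
  sizes <- table(line)
  multi <- names(sizes)[sizes > 1]
  spans <- vapply(multi, function(l) {
    g <- unique(stats::na.omit(garden[line == l]))
    length(g) >= 2
  }, logical(1))
  caveat <- NA_character_
  if (length(multi) && any(!spans))
    caveat <- "multi-accession clone line confined to one garden (discounted)"
  classification <-
    if (length(idx) < 2) "inconclusive"
    else if (length(sizes) == 1) "true_to_type_cultivar"
    else if (any(spans)) "ethnovariety"
    else "local_category"
  list(named_type = named_type, n = length(idx),
       n_clone_lines = length(sizes),
       largest_line = if (length(sizes)) max(sizes) else 0L,
       classification = classification, caveat = caveat)
}

#' Named-type report
#'
#' The per-named-type summary table of the identity analysis: sample size,
#' nuclear and chloroplastic identity percentages, clone-line structure and
#' classification.
#'
#' @param table a [genotype_table()].
#' @param partition optional [clone_partition()]; computed with defaults when
#'   `NULL`.
#' @param min_compared passed to [named_type_identity()].
#' @return data.frame with one row per named type (columns `named_type`, `n`,
#'   `nuc_identity`, `cp_identity`, `n_clone_lines`, `largest_line`,
#'   `classification`, `caveat`); percentages rounded to 2 decimals.
#' @export
named_type_report <- function(table, partition = NULL, min_compared = 12) {
  types <- unique(stats::na.omit(table$meta$named_type))
  nuc <- pairwise_identity(table, "nuclear")
  cp <- if (length(plastid_loci(table))) pairwise_identity(table, "plastid")
  if (is.null(partition)) partition <- clone_partition(table, nuc = nuc)
  rows <- lapply(types, function(ty) {
    ident <- named_type_identity(table, ty, min_compared, nuc = nuc, cp = cp)
    cls <- classify_named_type(table, partition, ty)
    data.frame(named_type = ty, n = ident$n,
               nuc_identity = round(ident$nuc_identity, 2),
               cp_identity = round(ident$cp_identity, 2),
               n_clone_lines = cls$n_clone_lines,
               largest_line = cls$largest_line,
               classification = cls$classification,
               caveat = cls$caveat, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n, out$named_type), , drop = FALSE]
}

#' Flag suspected misidentifications
#'
#' Two kinds of label problems are flagged: (i) an accession whose clone line
#' contains two or more accessions of a different named type (e.g. a seedling
#' that is in fact an offshoot of a widespread cultivar), and (ii) an
#' accession inside an otherwise internally consistent named type (mean
#' pairwise identity of the remaining members at least
#' `consistent_identity`) that is unrelated (nuclear identity below
#' `outlier_identity`) to every other member, suggesting an identification
#' error by the informer.
#'
#' @param table a [genotype_table()].
#' @param partition a [clone_partition()] on the full table.
#' @param outlier_identity identity threshold (fraction) below which an
#'   accession counts as unrelated to a type member.
#' @param consistent_identity mean pairwise identity (fraction) the remaining
#'   members must reach for the outlier rule to apply; without it every
#'   member of a genuinely heterogeneous local category would be flagged.
#' @return data.frame with columns `accession`, `named_type`,
#'   `matched_named_type`, `reason` (empty when nothing is flagged).
#' @export
flag_misidentifications <- function(table, partition, outlier_identity = 0.5,
                                    consistent_identity = 0.9) {
  acc <- accessions(table)
  nt <- table$meta$named_type
  line <- partition$lines$line[match(acc, partition$lines$accession)]
  nuc <- pairwise_identity(table, "nuclear")
  out <- list()
  # (i) clone line shared with >= 2 accessions of a consistent other type
  for (i in seq_along(acc)) {
    members <- which(line == line[i])
    members <- members[members != i]
    if (!length(members)) next
    other <- nt[members]
    other <- other[!is.na(other) & (is.na(nt[i]) | other != nt[i])]
    if (!length(other)) next
    counts <- table(other)
    hits <- names(counts)[counts >= 2]
    for (h in hits)
      out[[length(out) + 1L]] <- data.frame(
        accession = acc[i], named_type = nt[i], matched_named_type = h,
        reason = "clone of another named type", stringsAsFactors = FALSE)
  }
  # (ii) within-type outlier unrelated to all other members
  for (ty in unique(stats::na.omit(nt))) {
    idx <- which(!is.na(nt) & nt == ty)
    if (length(idx) < 3) next
    for (i in idx) {
      others <- setdiff(idx, i)
      rest <- nuc$identity[others, others, drop = FALSE]
      rest <- rest[upper.tri(rest)]
      rest <- rest[is.finite(rest)]
      if (!length(rest) || mean(rest) < consistent_identity) next
      ids <- nuc$identity[i, others]
      ids <- ids[is.finite(ids)]
      if (length(ids) && all(ids < outlier_identity))
        out[[length(out) + 1L]] <- data.frame(
          accession = acc[i], named_type = ty,
          matched_named_type = NA_character_,
          reason = "suspected informer error (unrelated to all type members)",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(accession = character(), named_type = character(),
                      matched_named_type = character(), reason = character(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}
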