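#' Codominant genotype table
#'
#' The universal input container of the package: an accessions-by-loci table of
#' codominant microsatellite calls. Nuclear loci are diploid (an unordered
#' allele pair per accession, stored order-normalised low/high); plastid loci
#' are haploid (a single allele). Alleles are positive integer codes (fragment
#' sizes or repeat counts). Missing calls are `NA`.
#'
#' @param meta data.frame with one row per accession. Required column
#'   `accession` (unique character IDs); optional columns `named_type`,
#'   `population`, `garden`, `status`. `status` is one of `"named_type"`,
#'   `"ushik1"`, `"ushik2"`, `"uncultivated"`, `"cultivated"`,
#'   `"wild_relative"`, `"outgroup"` (or `NA`).
#' @param loci data.frame with columns `name` (unique) and `kind`
#'   (`"nuclear"` or `"plastid"`).
#' @param a1,a2 integer matrices (accessions x nuclear loci) holding the two
#'   alleles of each nuclear call; pairs are re-ordered so `a1 <= a2`, and a
#'   half-missing pair is treated as fully missing.
#' @param plastid integer matrix (accessions x plastid loci) of haploid calls.
#'   May be `NULL` when the table has no plastid locus.
#'
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(meta, loci, a1, a2, plastid = NULL) {
  stopifnot(is.data.frame(meta), "accession" %in% names(meta))
  meta$accession <- as.character(meta$accession)
  if (anyDuplicated(meta$accession))
    stop("duplicate accession IDs: ",
         paste(unique(meta$accession[duplicated(meta$accession)]), collapse = ", "))
  for (col in c("named_type", "population", "garden", "status"))
    if (!col %in% names(meta)) meta[[col]] <- NA_character_ else
      meta[[col]] <- as.character(meta[[col]])
  bad_status <- setdiff(stats::na.omit(unique(meta$status)), genotype_statuses())
  if (length(bad_status))
    stop("unknown status value(s): ", paste(bad_status, collapse = ", "))

  stopifnot(is.data.frame(loci), all(c("name", "kind") %in% names(loci)))
  loci$name <- as.character(loci$name)
  loci$kind <- as.character(loci$kind)
  if (anyDuplicated(loci$name)) stop("duplicate locus names")
  if (!all(loci$kind %in% c("nuclear", "plastid")))
    stop("locus kind must be 'nuclear' or 'plastid'")

  n <- nrow(meta)
  nuc <- loci$name[loci$kind == "nuclear"]
  pla <- loci$name[loci$kind == "plastid"]

  a1 <- .as_call_matrix(a1, n, nuc, meta$accession)
  a2 <- .as_call_matrix(a2, n, nuc, meta$accession)
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) { a1[half] <- NA_integer_; a2[half] <- NA_integer_ }
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }

  if (length(pla)) {
    plastid <- .as_call_matrix(plastid, n, pla, meta$accession)
  } else {
    plastid <- matrix(NA_integer_, n, 0, dimnames = list(meta$accession, NULL))
  }
  .check_alleles(a1); .check_alleles(a2); .check_alleles(plastid)

  structure(list(meta = meta, loci = loci, a1 = a1, a2 = a2, plastid = plastid),
            class = "genotype_table")
}

genotype_statuses <- function() {
  c("named_type", "ushik1", "ushik2", "uncultivated", "cultivated",
    "wild_relative", "outgroup")
}

.as_call_matrix <- function(x, n, locus_names, acc) {
  if (is.null(x)) x <- matrix(NA_integer_, n, length(locus_names))
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (nrow(x) != n || ncol(x) != length(locus_names))
    stop("call matrix dimensions do not match accessions x loci")
  dimnames(x) <- list(acc, locus_names)
  x
}

.check_alleles <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) && any(v < 1))
    stop("allele codes must be positive integers")
  invisible(TRUE)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d accessions, %d nuclear + %d plastid loci\n",
              n_accessions(x), length(nuclear_loci(x)), length(plastid_loci(x))))
  pops <- table(x$meta$population, useNA = "ifany")
  cat("populations:", paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  cat(sprintf("missing calls: %.2f%%\n", 100 * missing_fraction(x)))
  invisible(x)
}

#' @export
summary.genotype_table <- function(object, ...) {
  data.frame(
    locus   = object$loci$name,
    kind    = object$loci$kind,
    n_alleles = vapply(object$loci$name, function(l)
      length(allele_domain(object, l)), integer(1)),
    missing = vapply(object$loci$name, function(l) {
      if (locus_kind(object, l) == "nuclear") mean(is.na(object$a1[, l]))
      else mean(is.na(object$plastid[, l]))
    }, numeric(1)),
    row.names = NULL)
}

#' Accessors for genotype tables
#'
#' @param table a [genotype_table()].
#' @name genotype-accessors
NULL

#' @rdname genotype-accessors
#' @export
n_accessions <- function(table) nrow(table$meta)

#' @rdname genotype-accessors
#' @export
accessions <- function(table) table$meta$accession

#' @rdname genotype-accessors
#' @export
nuclear_loci <- function(table) table$loci$name[table$loci$kind == "nuclear"]

#' @rdname genotype-accessors
#' @export
plastid_loci <- function(table) table$loci$name[table$loci$kind == "plastid"]

locus_kind <- function(table, locus) table$loci$kind[match(locus, table$loci$name)]

#' Observed allele domain of a locus
#'
#' @param table a [genotype_table()].
#' @param locus locus name.
#' @return sorted unique non-missing allele codes observed at `locus`.
#' @export
allele_domain <- function(table, locus) {
  if (locus_kind(table, locus) == "nuclear")
    sort(unique(c(table$a1[, locus], table$a2[, locus])))
  else sort(unique(table$plastid[, locus]))
}

#' Fraction of missing calls
#'
#' One call is one accession-by-locus cell (a diploid pair counts once).
#' @param table a [genotype_table()].
#' @export
missing_fraction <- function(table) {
  cells <- cbind(is.na(table$a1), is.na(table$plastid))
  if (!length(cells)) return(0)
  mean(cells)
}

#' Subset a genotype table by accession
#'
#' @param table a [genotype_table()].
#' @param ids accession IDs to keep (order preserved).
#' @return a [genotype_table()] restricted to `ids`.
#' @export
subset_accessions <- function(table, ids) {
  idx <- match(ids, table$meta$accession)
  if (anyNA(idx)) stop("unknown accession(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  genotype_table(table$meta[idx, , drop = FALSE], table$loci,
                 table$a1[idx, , drop = FALSE], table$a2[idx, , drop = FALSE],
                 if (ncol(table$plastid)) table$plastid[idx, , drop = FALSE] else NULL)
}

# one integer code per nuclear genotype for fast pairwise comparison;
# assumes allele codes < 1e5
nuclear_codes <- function(table) {
  code <- table$a1 * 100000L + table$a2
  dimnames(code) <- dimnames(table$a1)
  code
}
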