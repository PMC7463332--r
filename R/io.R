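#' Read a genotype table
#'
#' Reads codominant genotype data in one of three dialects:
#' \describe{
#'   \item{`canonical_csv`}{One row per accession. Metadata columns
#'     (`accession`, `named_type`, `population`, `garden`, `status`) first,
#'     then two columns `<locus>_1`, `<locus>_2` per nuclear locus and one
#'     column per plastid locus.}
#'   \item{`structure`}{STRUCTURE main file with a locus-name header row and
#'     two rows per individual (`id pop allele...`). Plastid loci are encoded
#'     as a duplicated allele and must be named via `plastid_loci`.}
#'   \item{`genepop`}{GenePop with 4-digit genotypes (two 2-digit alleles);
#'     plastid loci duplicated-allele coded, named via `plastid_loci`.}
#' }
#' The on-disk missing sentinel is `-9` (blanks and `0`/`0000` are accepted on
#' read); internally missing is `NA`.
#'
#' @param path file path.
#' @param dialect `"canonical_csv"`, `"structure"` or `"genepop"`.
#' @param plastid_loci names of plastid (haploid) loci, for dialects whose
#'   format cannot mark them (`structure`, `genepop`).
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path,
                                dialect = c("canonical_csv", "structure", "genepop"),
                                plastid_loci = character()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         canonical_csv = .read_canonical(path),
         structure     = .read_structure(path, plastid_loci),
         genepop       = .read_genepop(path, plastid_loci))
}

META_COLS <- c("accession", "named_type", "population", "garden", "status")

.na_in <- function(x) {
  x[x %in% c("-9", "", "0", "NA")] <- NA_character_
  x
}

.int_calls <- function(x, path, what) {
  y <- suppressWarnings(as.integer(x))
  bad <- !is.na(x) & is.na(y)
  if (any(bad)) stop("non-integer allele code in ", what, " of ", path)
  y
}

.read_canonical <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!all(META_COLS %in% names(raw)))
    stop("canonical CSV must start with columns ",
         paste(META_COLS, collapse = ", "))
  if (anyDuplicated(raw$accession))
    stop("duplicate accession ID in ", path)
  call_cols <- setdiff(names(raw), META_COLS)
  is_pair <- grepl("_[12]$", call_cols)
  nuc <- unique(sub("_[12]$", "", call_cols[is_pair]))
  for (l in nuc)
    if (!all(paste0(l, c("_1", "_2")) %in% call_cols))
      stop("nuclear locus ", l, " must have both _1 and _2 columns (dialect error)")
  pla <- call_cols[!is_pair]
  loci <- data.frame(name = c(nuc, pla),
                     kind = rep(c("nuclear", "plastid"), c(length(nuc), length(pla))))
  grab <- function(cols) {
    m <- vapply(cols, function(cn) .int_calls(.na_in(raw[[cn]]), path, cn),
                integer(nrow(raw)))
    matrix(m, nrow = nrow(raw))
  }
  meta <- raw[META_COLS]
  meta[-1] <- lapply(meta[-1], .na_in)
  genotype_table(meta, loci,
                 a1 = grab(paste0(nuc, "_1")), a2 = grab(paste0(nuc, "_2")),
                 plastid = if (length(pla)) grab(pla) else NULL)
}

.read_structure <- function(path, plastid_loci) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  locus_names <- strsplit(trimws(lines[[1]]), "[ \t]+")[[1]]
  body <- strsplit(trimws(lines[-1]), "[ \t]+")
  ncol_exp <- 2L + length(locus_names)
  bad <- which(lengths(body) != ncol_exp)
  if (length(bad))
    stop("malformed STRUCTURE row at line ", bad[1] + 1L, " of ", path,
         " (expected ", ncol_exp, " fields)")
  if (length(body) %% 2L != 0L)
    stop("STRUCTURE file must have two rows per individual: ", path)
  m <- do.call(rbind, body)
  ids <- m[seq(1, nrow(m), by = 2), 1]
  if (!identical(ids, m[seq(2, nrow(m), by = 2), 1]))
    stop("STRUCTURE row pairs disagree on individual IDs in ", path)
  if (anyDuplicated(ids)) stop("duplicate accession ID in ", path)
  pops <- m[seq(1, nrow(m), by = 2), 2]
  al <- apply(m[, -(1:2), drop = FALSE], 2, function(col)
    .int_calls(.na_in(col), path, "allele column"))
  r1 <- al[seq(1, nrow(m), by = 2), , drop = FALSE]
  r2 <- al[seq(2, nrow(m), by = 2), , drop = FALSE]
  is_pla <- locus_names %in% plastid_loci
  loci <- data.frame(name = c(locus_names[!is_pla], locus_names[is_pla]),
                     kind = rep(c("nuclear", "plastid"),
                                c(sum(!is_pla), sum(is_pla))))
  meta <- data.frame(accession = ids, population = pops)
  genotype_table(meta, loci,
                 a1 = r1[, !is_pla, drop = FALSE], a2 = r2[, !is_pla, drop = FALSE],
                 plastid = if (any(is_pla)) r1[, is_pla, drop = FALSE] else NULL)
}

.read_genepop <- function(path, plastid_loci) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3) stop("not a GenePop file: ", path)
  locus_names <- unlist(strsplit(trimws(lines[2:(first_pop - 1)]), "[ \t]*,[ \t]*"))
  ids <- character(); pops <- character(); rows <- list()
  pop_i <- 0L
  for (i in seq(first_pop, length(lines))) {
    if (is_pop[i]) { pop_i <- pop_i + 1L; next }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) != 2)
      stop("malformed GenePop row at line ", i, " of ", path)
    geno <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
    if (length(geno) != length(locus_names))
      stop("malformed GenePop row at line ", i, " of ", path,
           " (expected ", length(locus_names), " genotypes)")
    ids <- c(ids, trimws(parts[1])); pops <- c(pops, paste0("pop", pop_i))
    rows[[length(rows) + 1L]] <- geno
  }
  if (anyDuplicated(ids)) stop("duplicate accession ID in ", path)
  g <- do.call(rbind, rows)
  if (any(nchar(g) != 4))
    stop("GenePop genotypes must be 4-digit (two 2-digit alleles) in ", path)
  a1 <- matrix(as.integer(substr(g, 1, 2)), nrow = nrow(g))
  a2 <- matrix(as.integer(substr(g, 3, 4)), nrow = nrow(g))
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  is_pla <- locus_names %in% plastid_loci
  loci <- data.frame(name = c(locus_names[!is_pla], locus_names[is_pla]),
                     kind = rep(c("nuclear", "plastid"),
                                c(sum(!is_pla), sum(is_pla))))
  meta <- data.frame(accession = ids, population = pops)
  genotype_table(meta, loci,
                 a1 = a1[, !is_pla, drop = FALSE], a2 = a2[, !is_pla, drop = FALSE],
                 plastid = if (any(is_pla)) a1[, is_pla, drop = FALSE] else NULL)
}

#' Write a genotype table
#'
#' Deterministic (byte-stable) writers for the dialects of
#' [read_genotype_table()]. Haploid plastid loci are exported to STRUCTURE and
#' GenePop as a duplicated allele (homozygous coding), a documented
#' lossy-but-reversible convention; GenePop requires allele codes <= 99.
#'
#' @param table a [genotype_table()].
#' @param path output file path.
#' @param dialect `"canonical_csv"`, `"structure"` or `"genepop"`.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path,
                                 dialect = c("canonical_csv", "structure", "genepop")) {
  dialect <- match.arg(dialect)
  lines <- switch(dialect,
                  canonical_csv = .format_canonical(table),
                  structure     = .format_structure(table),
                  genepop       = .format_genepop(table))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

.fmt_call <- function(x) ifelse(is.na(x), "-9", as.character(x))
.fmt_meta <- function(x) ifelse(is.na(x), "", x)

.format_canonical <- function(table) {
  nuc <- nuclear_loci(table); pla <- plastid_loci(table)
  header <- c(META_COLS,
              if (length(nuc)) as.vector(rbind(paste0(nuc, "_1"), paste0(nuc, "_2"))),
              pla)
  cols <- c(lapply(table$meta[META_COLS], .fmt_meta),
            unlist(lapply(nuc, function(l)
              list(.fmt_call(table$a1[, l]), .fmt_call(table$a2[, l]))),
              recursive = FALSE),
            lapply(pla, function(l) .fmt_call(table$plastid[, l])))
  body <- if (n_accessions(table)) do.call(paste, c(cols, sep = ",")) else character()
  enc2utf8(c(paste(header, collapse = ","), body))
}

.format_structure <- function(table) {
  nuc <- nuclear_loci(table); pla <- plastid_loci(table)
  pop <- as.integer(factor(table$meta$population,
                           levels = unique(table$meta$population)))
  pop[is.na(pop)] <- 1L
  rows <- character(2L * n_accessions(table))
  for (i in seq_len(n_accessions(table))) {
    nu1 <- .fmt_call(table$a1[i, ]); nu2 <- .fmt_call(table$a2[i, ])
    pl <- .fmt_call(table$plastid[i, ])
    rows[2 * i - 1] <- paste(c(table$meta$accession[i], pop[i], nu1, pl), collapse = "\t")
    rows[2 * i]     <- paste(c(table$meta$accession[i], pop[i], nu2, pl), collapse = "\t")
  }
  enc2utf8(c(paste(c(nuc, pla), collapse = "\t"), rows))
}

.format_genepop <- function(table) {
  all_codes <- c(table$a1, table$a2, table$plastid)
  if (any(all_codes > 99, na.rm = TRUE))
    stop("GenePop 2-digit coding requires allele codes <= 99")
  nuc <- nuclear_loci(table); pla <- plastid_loci(table)
  two <- function(x) ifelse(is.na(x), "00", sprintf("%02d", x))
  pops <- unique(table$meta$population)
  if (all(is.na(pops))) pops <- NA_character_
  out <- c("palmdiv genotype export", c(nuc, pla))
  for (p in pops) {
    out <- c(out, "POP")
    idx <- which(if (is.na(p)) is.na(table$meta$population)
                 else !is.na(table$meta$population) & table$meta$population == p)
    for (i in idx) {
      geno <- c(paste0(two(table$a1[i, ]), two(table$a2[i, ])),
                paste0(two(table$plastid[i, ]), two(table$plastid[i, ])))
      out <- c(out, paste0(table$meta$accession[i], " ,  ",
                           paste(geno, collapse = " ")))
    }
  }
  enc2utf8(out)
}

#' Write a phylogenetic tree in Newick format
#'
#' Internal-node labels (e.g. bootstrap supports) are preserved.
#'
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a data frame as a UTF-8 TSV report
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(lapply(df, function(x)
               ifelse(is.na(x), "", as.character(x))), sep = "\t")))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}
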