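#' Default chlorotype map
#'
#' Date-palm chlorotypes are defined by the repeat number of the plastid
#' psbZ-trnfM dodecanucleotide minisatellite: three repeats mark the
#' occidental (western) chlorotype, four the oriental (eastern) one, and five
#' repeats are characteristic of \emph{Phoenix theophrasti}. Any other
#' observed allele maps to `"other"` rather than erroring.
#'
#' @return named character vector mapping allele code to chlorotype label.
#' @export
default_chlorotype_map <- function() {
  c("3" = "occidental", "4" = "oriental", "5" = "theophrasti")
}

#' Assign plastid chlorotypes
#'
#' Labels every accession by its plastid minisatellite allele and tabulates
#' label frequencies per population (proportions over non-missing calls).
#'
#' @param table a [genotype_table()] with exactly one plastid locus.
#' @param map named character vector, allele code -> label; defaults to
#'   [default_chlorotype_map()]. Unmapped alleles become `"other"`.
#' @return list with `labels` (data.frame: accession, population, allele,
#'   chlorotype) and `frequencies` (data.frame: population, chlorotype,
#'   n, freq; `freq` sums to 1 per population over non-missing calls).
#' @export
assign_chlorotypes <- function(table, map = default_chlorotype_map()) {
  pla <- plastid_loci(table)
  if (length(pla) != 1)
    stop("table must have exactly one plastid locus (found ", length(pla), ")")
  allele <- table$plastid[, pla]
  lab <- unname(map[as.character(allele)])
  lab[!is.na(allele) & is.na(lab)] <- "other"
  lab[is.na(allele)] <- "missing"
  labels <- data.frame(accession = accessions(table),
                       population = table$meta$population,
                       allele = allele, chlorotype = lab,
                       stringsAsFactors = FALSE)
  obs <- labels[labels$chlorotype != "missing", , drop = FALSE]
  freqs <- if (nrow(obs)) {
    tab <- table(obs$population, obs$chlorotype)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(df) <- c("population", "chlorotype", "n")
    df <- df[df$n > 0 | TRUE, , drop = FALSE]
    tot <- stats::ave(df$n, df$population, FUN = sum)
    df$freq <- ifelse(tot > 0, df$n / tot, NA_real_)
    df[order(df$population, df$chlorotype), , drop = FALSE]
  } else data.frame(population = character(), chlorotype = character(),
                    n = integer(), freq = numeric())
  rownames(freqs) <- NULL
  list(labels = labels, frequencies = freqs)
}
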