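# in-code fixtures: small genotype tables built from explicit call matrices

make_table <- function(a1, a2, plastid = NULL, named_type = NA,
                       population = "pop1", garden = NA, status = NA,
                       acc = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  n <- nrow(a1)
  if (is.null(acc)) acc <- sprintf("S%02d", seq_len(n))
  meta <- data.frame(accession = acc,
                     named_type = rep_len(named_type, n),
                     population = rep_len(population, n),
                     garden = rep_len(garden, n),
                     status = rep_len(status, n),
                     stringsAsFactors = FALSE)
  has_cp <- !is.null(plastid)
  loci <- data.frame(name = c(paste0("L", seq_len(ncol(a1))), if (has_cp) "cp"),
                     kind = c(rep("nuclear", ncol(a1)), if (has_cp) "plastid"))
  genotype_table(meta, loci, a1, a2,
                 if (has_cp) matrix(as.integer(plastid), ncol = 1))
}

# n identical diploid rows from one genotype (vectors of the two alleles)
clone_mat <- function(g, n) matrix(rep(g, each = n), nrow = n)

# a 17-locus genotype pair agreeing at exactly `k` loci
pair_agreeing_at <- function(k, L = 17) {
  a1 <- clone_mat(rep(1L, L), 2)
  a2 <- clone_mat(rep(2L, L), 2)
  if (k < L) a2[2, (k + 1):L] <- 3L   # second member differs at L - k loci
  list(a1 = a1, a2 = a2)
}

# small two-population drift config used by several structure tests
two_pop_config <- function(n_per_pop = 50, theta = 10, seed = 1,
                           missing_rate = 0, epsilon = 0) {
  simulation_config(
    populations = list(population_spec("east", theta, c("3" = 1)),
                       population_spec("west", theta, c("4" = 1))),
    groups = list(cohort_group("east", "cultivated", n_per_pop),
                  cohort_group("west", "cultivated", n_per_pop)),
    mu_som = 0, epsilon = epsilon, missing_rate = missing_rate, seed = seed)
}
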