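#' Pipeline configuration
#'
#' Describes a full analysis run: the input (a CSV path or a
#' [simulation_config()]), which stages to execute, per-stage parameters, the
#' output directory and a global seed. Stage seeds are derived from the
#' global seed by a stable hash of the stage name, so adding or removing a
#' stage does not shift the random streams of the others.
#'
#' @param input path to a canonical CSV, or a [simulation_config()].
#' @param stages character vector among `"identity"`, `"diversity"`,
#'   `"structure"`, `"admixture"`.
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed.
#' @param params named list of per-stage parameter overrides; recognised:
#'   `identity$t`, `identity$min_compared`, `diversity$g`, `diversity$reps`,
#'   `structure$bootstrap_B`, `admixture$K_range`, `admixture$n_runs`,
#'   `admixture$burn_in`, `admixture$iters`, `admixture$model`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, stages = c("identity", "diversity", "structure"),
                            out_dir = "palmdiv_out", seed = 1, params = list()) {
  stopifnot(all(stages %in% c("identity", "diversity", "structure", "admixture")))
  if (is.character(input) && !file.exists(input))
    stop("input file not found: ", input)
  structure(list(input = input, stages = stages, out_dir = out_dir,
                 seed = as.integer(seed), params = params),
            class = "pipeline_config")
}

# stable non-cryptographic string hash for stage seeds; the modulus keeps
# every product below 2^53 so double arithmetic stays exact
.stage_seed <- function(global_seed, stage) {
  h <- 17
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 100000007
  as.integer((global_seed + h) %% 2147483647)
}

.file_checksum <- function(path) unname(tools::md5sum(path))

#' Run the full analysis pipeline
#'
#' Simulates or loads a genotype table, then executes the requested stages in
#' dependency order: identity analysis and named-type classification,
#' deduplication (one accession per clone line feeds the downstream stages),
#' diversity statistics, population structure (FST, PCA, bootstrapped NJ
#' tree), and optionally the admixture sweep. All outputs are UTF-8
#' TSV/JSON/Newick files under `config$out_dir`, and a manifest records the
#' config hash, per-stage output checksums and wall time; deterministic
#' stages are bit-reproducible for a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (also written as `manifest.json`) and
#'   `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  outputs <- character()
  results <- list()
  log_stage <- function(stage, ...)
    message(sprintf("[palmdiv] %s: %s", stage, paste0(...)))
  emit <- function(name, writer) {
    path <- file.path(config$out_dir, name)
    writer(path)
    outputs[[name]] <<- .file_checksum(path)
    path
  }

  # --- input stage
  if (inherits(config$input, "simulation_config")) {
    sim_cfg <- config$input
    sim_cfg$seed <- .stage_seed(config$seed, "simulate")
    log_stage("simulate", "seed ", sim_cfg$seed)
    sim <- simulate_cohort(sim_cfg)
    table <- sim$table
    results$truth <- sim$truth
    emit("cohort.csv", function(p) write_genotype_table(table, p))
    emit("truth.json", function(p)
      jsonlite::write_json(sim$truth[c("accessions", "named_types")], p,
                           dataframe = "rows", na = "null", pretty = TRUE))
  } else {
    log_stage("load", config$input)
    table <- read_genotype_table(config$input, "canonical_csv")
  }
  results$table <- table
  emit("cohort_summary.tsv", function(p)
    write_tsv_report(cohort_summary(table), p))

  dedup <- table
  if ("identity" %in% config$stages) {
    pr <- config$params$identity
    t <- pr$t %||% 1; mc <- pr$min_compared %||% 12
    log_stage("identity", sprintf("t = %d, min_compared = %d", t, mc))
    partition <- clone_partition(table, t = t, min_compared = mc)
    report <- named_type_report(table, partition, min_compared = mc)
    flags <- flag_misidentifications(table, partition)
    dedup <- deduplicate(table, partition)
    results$partition <- partition
    results$named_type_report <- report
    results$flags <- flags
    results$deduplicated <- dedup
    emit("named_types.tsv", function(p)
      write_tsv_report(format_named_type_report(report), p))
    emit("clone_lines.tsv", function(p) write_tsv_report(partition$lines, p))
    emit("misidentifications.tsv", function(p) write_tsv_report(flags, p))
    emit("deduplicated.csv", function(p) write_genotype_table(dedup, p))
    log_stage("identity", attr(dedup, "n_removed"), " duplicate genotypes removed")
  }

  if ("diversity" %in% config$stages) {
    pr <- config$params$diversity
    g <- pr$g %||% 18; reps <- pr$reps %||% 1000
    seed_d <- .stage_seed(config$seed, "diversity")
    log_stage("diversity", sprintf("g = %d, reps = %d, seed = %d", g, reps, seed_d))
    ls <- locus_stats(table)
    results$locus_stats <- ls
    emit("locus_stats.tsv", function(p) write_tsv_report(ls, p))
    pops <- names(which(table(dedup$meta$population) >= 2))
    div <- lapply(pops, function(p) {
      f <- fis_ci(dedup, p, B = 1000, seed = .stage_seed(seed_d, p))
      data.frame(population = p, Ho = f$Ho, Hs = f$Hs, FIS = f$fis,
                 FIS_low = f$ci[1], FIS_high = f$ci[2],
                 stringsAsFactors = FALSE)
    })
    results$diversity <- do.call(rbind, div)
    emit("diversity.tsv", function(p) write_tsv_report(results$diversity, p))
    # rarefied (private) allelic richness at the largest shared haploid size
    af <- allele_freqs(dedup)
    minN <- min(vapply(intersect(af$loci, nuclear_loci(dedup)),
                       function(l) min(rowSums(af$counts[[l]])), numeric(1)))
    g_eff <- min(g, minN)
    if (g_eff >= 2 && length(af$populations) >= 2) {
      if (g_eff < g)
        log_stage("diversity", sprintf("g reduced to %d (smallest haploid sample)", g_eff))
      rr <- rarefied_richness(dedup, g = g_eff, mode = "monte_carlo",
                              reps = reps, seed = .stage_seed(seed_d, "richness"))
      tg <- tukey_groups(as.vector(t(rr$replicates)),
                         rep(rownames(rr$replicates), each = reps))
      pg <- vapply(af$populations, function(p)
        private_rarefied_richness(dedup, p, g = g_eff, mode = "monte_carlo",
                                  reps = reps,
                                  seed = .stage_seed(seed_d, paste0("private_", p))
        )$by_population$P_g, numeric(1))
      rich <- merge(rr$by_population,
                    data.frame(population = af$populations, P_g = pg),
                    by = "population")
      rich <- merge(rich, tg[c("population", "group")], by = "population")
      results$richness <- rich
      results$richness$g <- g_eff
      emit("richness.tsv", function(p) write_tsv_report(results$richness, p))
    }
    if (length(plastid_loci(table)) == 1) {
      ch <- assign_chlorotypes(table)
      results$chlorotypes <- ch
      emit("chlorotypes.tsv", function(p) write_tsv_report(ch$frequencies, p))
    }
  }

  if ("structure" %in% config$stages) {
    pr <- config$params$structure
    B <- pr$bootstrap_B %||% 100
    seed_s <- .stage_seed(config$seed, "structure")
    log_stage("structure", sprintf("bootstrap B = %d, seed = %d", B, seed_s))
    pca <- pca_dosage(dosage_matrix(dedup))
    results$pca <- pca
    emit("pca_scores.tsv", function(p)
      write_tsv_report(data.frame(accession = rownames(pca$scores),
                                  round(pca$scores, 6)), p))
    pops <- names(which(table(dedup$meta$population) >= 2))
    if (length(pops) >= 2) {
      results$fst <- wc_fst_pairwise(dedup, pops)
      emit("fst.tsv", function(p)
        write_tsv_report(transform(results$fst, theta = round(theta, 4)), p))
    }
    tree <- bootstrap_nj(dedup, "nei1972", B = B, seed = seed_s)
    results$tree <- tree
    emit("nj_tree.nwk", function(p) write_newick(tree, p))
  }

  if ("admixture" %in% config$stages) {
    pr <- config$params$admixture
    K_range <- pr$K_range %||% 1:4
    n_runs <- pr$n_runs %||% 5
    seed_a <- .stage_seed(config$seed, "admixture")
    log_stage("admixture", sprintf("K in %s, %d runs, seed = %d",
                                   paste(range(K_range), collapse = ".."),
                                   n_runs, seed_a))
    sw <- admixture_sweep(dedup, K_range = K_range, n_runs = n_runs,
                          seed = seed_a,
                          burn_in = pr$burn_in %||% 1000,
                          iters = pr$iters %||% 10000,
                          model = pr$model %||% "independent")
    results$admixture <- sw
    for (K in K_range) {
      Q <- sw$aligned[[as.character(K)]]$mean_Q
      emit(sprintf("admixture_Q_K%d.tsv", K), function(p)
        write_tsv_report(data.frame(accession = rownames(Q), round(Q, 4)), p))
    }
    if (!is.null(sw$evanno))
      emit("evanno.tsv", function(p) write_tsv_report(sw$evanno$table, p))
  }

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(.config_digestible(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("palmdiv")),
    config_hash = .file_checksum(cfg_file),
    seed = config$seed,
    stages = config$stages,
    outputs = as.list(outputs),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(manifest = manifest, results = results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the hash covers the scientific content of a run, not where it is written
.config_digestible <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  if (inherits(x$input, "simulation_config")) x$input <- unclass(x$input)
  x
}

#' Cohort summary table
#'
#' One row per (population, status) group with its sample size, the layout of
#' a study-design summary table.
#'
#' @param table a [genotype_table()].
#' @return data.frame with columns `population`, `status`, `n`.
#' @export
cohort_summary <- function(table) {
  key <- paste(table$meta$population, table$meta$status, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(population = vapply(parts, `[`, "", 1),
                    status = vapply(parts, `[`, "", 2),
                    n = as.integer(tab), stringsAsFactors = FALSE)
  out[order(out$population, out$status), , drop = FALSE]
}

#' Render a named-type report for display
#'
#' Formats identity percentages with two decimals (e.g. `97.06%`), the
#' convention of agrobiodiversity summary tables.
#'
#' @param report data.frame from [named_type_report()].
#' @return data.frame with formatted percentage columns.
#' @export
format_named_type_report <- function(report) {
  pct <- function(x) ifelse(is.na(x), "/", sprintf("%.2f%%", x))
  data.frame(named_type = report$named_type, n = report$n,
             nuc_identity = pct(report$nuc_identity),
             cp_identity = pct(report$cp_identity),
             n_clone_lines = report$n_clone_lines,
             classification = report$classification,
             stringsAsFactors = FALSE)
}
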