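# End-to-end orchestration: simulate -> validate -> abundance -> stats /
# ordination / rf / lsa from a single config, with a reproducible run
# manifest. All inter-stage flow goes through the documented TSV contracts.

#' Built-in pipeline configuration
#'
#' @param preset Simulation preset (see [sim_config()]); `"small"` keeps the
#'   run under a few seconds.
#' @param seed Global pipeline seed; per-stage seeds are derived from it
#'   with [derive_seed()].
#' @return A config list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(preset = "small", seed = 1) {
  list(
    seed = as.integer(seed),
    simulate = list(preset = preset),
    validate = list(rules = NULL),
    abundance = list(rank = "family"),
    stats = list(scale_response = FALSE),
    ordination = list(n_perm = 199),
    rf = list(n_trees = 301, n_splits = 10, n_null_perms = 0, mtry = 4),
    lsa = list(D = 2, n_perm = 199)
  )
}

.validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop_config("config must be a list or a YAML file path")
  if (is.null(config$seed)) stop_config("config field 'seed' is required")
  known <- c("seed", "simulate", "validate", "abundance", "stats",
             "ordination", "rf", "lsa")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop_config("unknown config field(s): %s", paste(bad, collapse = ", "))
  config
}

.md5_of <- function(paths) {
  unname(tools::md5sum(paths))
}

.md5_of_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline from a single config
#'
#' Stages run in dependency order (simulate, validate, abundance, stats,
#' ordination, rf, lsa); any stage failure aborts with the stage name. All
#' stage outputs are TSVs under `out_dir`, and a JSON run manifest records
#' the config hash, seeds, package version, input digests, per-stage row
#' counts, and output digests — rerunning with an identical config yields an
#' identical manifest digest.
#'
#' @param config A config list (see [pipeline_config()]) or path to a YAML
#'   file with the same fields.
#' @param out_dir Output directory.
#' @param seed Optional seed override.
#' @return The manifest list, invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("paddymehg_run_"),
                         seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_config("config file does not exist: %s", config)
    config <- yaml::read_yaml(config)
  }
  config <- .validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  defaults <- pipeline_config()
  for (nm in setdiff(names(defaults), "seed")) {
    config[[nm]] <- utils::modifyList(defaults[[nm]], config[[nm]] %||% list())
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("paddyMeHg")),
    config_hash = .md5_of_object(config),
    seed = config$seed,
    stages = list(), outputs = character())
  stage <- function(name, expr) {
    log_msg("info", "stage %s", name)
    tryCatch(expr, error = function(e) {
      stop_data("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # simulate
  fx <- panel <- lagged <- NULL
  stage("simulate", {
    scfg <- do.call(sim_config, c(list(seed = derive_seed(config$seed, 1)),
                                  config$simulate))
    fx <- make_search_fixtures(cfg = scfg)
    panel <- make_panel(scfg)
    lagged <- make_lagged_series(scfg)
    sim_dir <- file.path(out_dir, "simulated")
    p1 <- write_search_fixtures(fx, sim_dir)
    p2 <- write_panel(panel, sim_dir)
    manifest$stages$simulate <- list(preset = scfg$preset,
                                      n_orfs = nrow(fx$hmm),
                                      n_samples = nrow(panel$meta))
    manifest$inputs <- as.list(stats::setNames(.md5_of(c(p1, p2)),
                                                basename(c(p1, p2))))
  })

  # validate (round-trips through the written fixtures to exercise the readers)
  val <- NULL
  stage("validate", {
    sim_dir <- file.path(out_dir, "simulated")
    hmm <- read_hmm_table(file.path(sim_dir, "hits.domtblout"))
    blast <- read_blast_table(file.path(sim_dir, "hits.blastp.tsv"))
    lin <- read_table_schema(file.path(sim_dir, "lineage.tsv"),
                             c(orf_id = "character", lineage = "character"))
    cov <- read_table_schema(file.path(sim_dir, "coverage.tsv"),
                             c(orf_id = "character", coverage = "numeric",
                               sample_id = "character"))
    prot <- read_fasta(file.path(sim_dir, "proteins.faa"))
    lin$lineage[is.na(lin$lineage)] <- ""
    hits <- do.call(rbind, lapply(unique(hmm$hmm_name), function(fam) {
      sub <- hmm[hmm$hmm_name == fam, , drop = FALSE]
      assemble_gene_hits(sub, gene_family = fam,
                         sample_id = cov$sample_id[match(sub$orf_id, cov$orf_id)],
                         blast = blast, lineage = lin, coverage = cov,
                         proteins = prot)
    }))
    rules <- load_validation_rules(config$validate$rules)
    val <- validate_all(gene_hits(hits), rules)
    write_table(as.data.frame(val$retained), file.path(out_dir, "hits_retained.tsv"))
    write_table(as.data.frame(val$rejected), file.path(out_dir, "hits_rejected.tsv"))
    manifest$stages$validate <- list(hits_in = nrow(hits),
                                      retained = nrow(val$retained),
                                      rejected = nrow(val$rejected))
  })

  # abundance
  stage("abundance", {
    agg <- aggregate_guilds(val$retained, fx$meta, rank = config$abundance$rank)
    write_table(agg$guilds, file.path(out_dir, "guild_abundance.tsv"))
    write_table(agg$taxa, file.path(out_dir, "guild_taxa.tsv"))
    manifest$stages$abundance <- list(samples = nrow(agg$guilds),
                                       taxa_rows = nrow(agg$taxa))
  })

  # stats: AICc model selection on the simulated panel
  stage("stats", {
    dat <- merge(merge(panel$geochem, panel$guilds, by = "sample_id"),
                 panel$meta, by = "sample_id")
    sel <- aicc_select(seven_model_family(), dat,
                       scale_response = isTRUE(config$stats$scale_response))
    write_table(sel$table, file.path(out_dir, "model_selection.tsv"))
    best <- sel$fits[[sel$best]]
    write_table(best$coefficients, file.path(out_dir, "best_model_coefficients.tsv"))
    manifest$stages$stats <- list(best_model = sel$best,
                                   complete_cases = best$n)
  })

  # ordination: Bray-Curtis + PERMANOVA + db-RDA on guild composition
  stage("ordination", {
    gm <- as.matrix(panel$guilds[, setdiff(names(panel$guilds), "sample_id")])
    rownames(gm) <- panel$guilds$sample_id
    d <- bray_curtis(gm)
    write_table(data.frame(sample_id = rownames(as.matrix(d)), as.matrix(d),
                           check.names = FALSE),
                file.path(out_dir, "bray_curtis.tsv"))
    pm <- permanova(d, panel$meta[, c("site", "compartment")],
                    n_perm = config$ordination$n_perm,
                    seed = derive_seed(config$seed, 5), pairwise = FALSE)
    write_table(pm$overall, file.path(out_dir, "permanova.tsv"))
    env <- as.data.frame(scale(panel$geochem[, c("THg", "MeHg", "DOM")]))
    dr <- db_rda(d, env, n_perm = config$ordination$n_perm,
                 seed = derive_seed(config$seed, 6))
    write_table(dr$term_tests, file.path(out_dir, "dbrda_terms.tsv"))
    manifest$stages$ordination <- list(
      permanova_terms = nrow(pm$overall),
      constrained_fraction = dr$constrained_fraction)
  })

  # rf attribution
  stage("rf", {
    feats <- build_feature_table(panel$guilds, panel$geochem)
    cfg_rf <- rf_protocol_config(
      n_trees = config$rf$n_trees, mtry = config$rf$mtry,
      n_splits = config$rf$n_splits, n_null_perms = config$rf$n_null_perms,
      seed = derive_seed(config$seed, 7),
      predictors = intersect(.default_rf_predictors, names(feats)))
    rf <- run_rf_protocol(feats, "MeHg", cfg_rf)
    write_table(rf$splits, file.path(out_dir, "rf_split_metrics.tsv"))
    write_table(rank_variables(rf), file.path(out_dir, "rf_importance.tsv"))
    manifest$stages$rf <- list(n = rf$n, splits = nrow(rf$splits),
                                mean_test_r2 = mean(rf$splits$r2))
  })

  # lsa
  stage("lsa", {
    res <- lsa_test(lagged$series, lagged$target, D = config$lsa$D,
                    n_perm = config$lsa$n_perm,
                    seed = derive_seed(config$seed, 8))
    write_table(as.data.frame(res), file.path(out_dir, "lsa_results.tsv"))
    manifest$stages$lsa <- list(pairs = nrow(res),
                                 significant_q05 = sum(res$q < 0.05))
  })

  outputs <- list.files(out_dir, pattern = "\\.tsv$", recursive = TRUE,
                        full.names = TRUE)
  manifest$outputs <- as.list(stats::setNames(
    .md5_of(outputs), sub("^/*", "", substring(outputs, nchar(out_dir) + 2L))))
  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), manifest_path)
  log_msg("info", "pipeline complete: %s", manifest_path)
  invisible(manifest)
}
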