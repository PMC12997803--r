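# Seeded synthetic-data generator. Every input the pipeline consumes can be
# produced here with known ground truth, emulating the field-study design:
# 3 sites x 2 soil compartments x 11 time points, marker-gene protein sets
# with and without diagnostic motifs, search-result fixtures with known
# failure modes, and a guild-abundance / geochemistry panel with a stated
# generative model for MeHg.

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Central knobs of the synthetic-data generator, with defaults that encode
#' the emulated study design: 3 sites (HX, GX, SK), surface and rhizosphere
#' compartments, 11 time points at 33-day spacing, flooding for the first
#' ~100 days, site-level MeHg baselines at the field magnitudes
#' (HX 0.78, GX 3.44, SK 2.42 µg/kg), a bioavailable-mercury effect of 0.73
#' per SD of F1-Hg (the stylized headline coefficient), and log-normal guild
#' coverages at the ~1e-8 scale of reads-and-length normalized values.
#'
#' Presets:
#' * `"paper"` — full design, F1-Hg + methanogen + flooded-gated
#'   methanogen x methanotroph interaction effects on MeHg.
#' * `"small"` — as `"paper"` but with few marker sequences, for fast tests.
#' * `"null"` — all effects and site/compartment structure off; MeHg is
#'   pure noise.
#' * `"dominant_f1"` — F1-Hg dominates; weak methanogen effect, no
#'   interaction.
#' * `"flooded_interaction"` — strong methanogen x methanotroph interaction
#'   active only while flooded.
#' * `"model5"` — MeHg generated from F1-Hg + total hgcA + site +
#'   compartment (the additive model with design covariates).
#'
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @param preset Preset name, see Details.
#' @param ... Named overrides of any configuration field.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       preset = c("paper", "small", "null", "dominant_f1",
                                  "flooded_interaction", "model5"),
                       ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = as.integer(seed),
    preset = preset,
    sites = c("HX", "GX", "SK"),
    compartments = c("surface", "rhizosphere"),
    n_timepoints = 11L,
    day_step = 33L,
    flooded_cutoff_day = 100L,
    # marker-sequence generation
    n_true_seqs = 20L,
    n_decoy_seqs = 20L,
    n_amoa = NULL,              # pmoA confounders; default n_decoy_seqs
    near_motif_fraction = 0.3,  # fraction of decoys carrying a hamming-1 near-motif
    seq_length = c(150L, 300L),
    # panel generative model (MeHg, µg/kg)
    mehg_baseline = 5,
    site_offsets = c(HX = 0.78, GX = 3.44, SK = 2.42),
    compartment_offset = 0.5,
    beta_F1 = 0.73,
    beta_methanogen = 0.5,
    beta_hgca = 0,
    beta_interaction = 0.8,
    noise_sd = 0.3,
    rho_coupling = 0.5,         # log-scale methanogen-methanotroph correlation
    guild_site_sd = 0.3,        # site-level spread of log guild abundance
    abundance_meanlog = log(3e-8),
    abundance_sdlog = 0.8,
    total_reads_range = c(8e6, 1.2e7),
    # lagged time-series generator
    n_lagged = 4L,
    n_null_series = 10L,
    lag_delays = 0:2,
    lag_noise_sd = 0.25,
    neg_sign_prob = 0.25
  )
  cfg <- switch(preset,
    paper = cfg,
    small = utils::modifyList(cfg, list(n_true_seqs = 4L, n_decoy_seqs = 6L)),
    null = utils::modifyList(cfg, list(
      site_offsets = c(HX = 0, GX = 0, SK = 0), compartment_offset = 0,
      beta_F1 = 0, beta_methanogen = 0, beta_hgca = 0, beta_interaction = 0,
      guild_site_sd = 0, noise_sd = 1)),
    dominant_f1 = utils::modifyList(cfg, list(
      site_offsets = c(HX = 0, GX = 0, SK = 0), compartment_offset = 0,
      beta_F1 = 0.73, beta_methanogen = 0.2, beta_interaction = 0,
      guild_site_sd = 0)),
    flooded_interaction = utils::modifyList(cfg, list(
      beta_F1 = 0.5, beta_methanogen = 0.3, beta_interaction = 0.9)),
    model5 = utils::modifyList(cfg, list(
      beta_methanogen = 0, beta_interaction = 0, beta_hgca = 0.5))
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop_config("unknown sim_config field(s): %s", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, dots)
  if (cfg$n_timepoints < 4L) stop_config("n_timepoints must be >= 4")
  structure(cfg, class = "sim_config")
}

# sample one concrete instance of a character-class pattern
.motif_instance <- function(pattern) {
  toks <- regmatches(pattern, gregexpr("\\[[A-Z]+\\]|[A-Z]", pattern))[[1]]
  paste(vapply(toks, function(t) {
    if (startsWith(t, "[")) {
      opts <- strsplit(substr(t, 2, nchar(t) - 1), "")[[1]]
      opts[sample.int(length(opts), 1L)]
    } else t
  }, ""), collapse = "")
}

# corrupt one position of a motif instance to a residue outside its class
.near_motif <- function(pattern) {
  toks <- regmatches(pattern, gregexpr("\\[[A-Z]+\\]|[A-Z]", pattern))[[1]]
  inst <- strsplit(.motif_instance(pattern), "")[[1]]
  pos <- sample.int(length(toks), 1L)
  allowed <- if (startsWith(toks[pos], "["))
    strsplit(substr(toks[pos], 2, nchar(toks[pos]) - 1), "")[[1]]
  else toks[pos]
  forbidden <- setdiff(.aa_alphabet, allowed)
  inst[pos] <- forbidden[sample.int(length(forbidden), 1L)]
  paste(inst, collapse = "")
}

.random_protein <- function(len, avoid_patterns = NULL) {
  repeat {
    s <- paste(sample(.aa_alphabet, len, replace = TRUE), collapse = "")
    if (is.null(avoid_patterns) ||
        !any(vapply(avoid_patterns, function(p) grepl(p, s), TRUE))) return(s)
  }
}

# overwrite `inserts` into seq at mutually non-overlapping positions
.embed_all <- function(seq, inserts) {
  used <- matrix(numeric(0), ncol = 2)
  for (ins in inserts) {
    m <- nchar(ins)
    repeat {
      pos <- sample.int(nchar(seq) - m, 1L)
      if (!nrow(used) || all(pos + m <= used[, 1] | pos >= used[, 2])) break
    }
    used <- rbind(used, c(pos, pos + m))
    seq <- paste0(substr(seq, 1, pos), ins,
                  substr(seq, pos + m + 1, nchar(seq)))
  }
  seq
}

.embed <- function(seq, insert) .embed_all(seq, insert)

#' Generate labeled marker-gene protein sets
#'
#' For each motif-validated family, emits `n_true_seqs` sequences that embed
#' one exact instance of every diagnostic motif and `n_decoy_seqs` motif-free
#' decoys; a configurable fraction of decoys carries a hamming-distance-1
#' near-motif (one class position mutated outside its class), so only exact
#' character-class matching separates the labels. True MerB sequences carry
#' all configured signature patterns; MerB decoys lack at least one.
#'
#' @param cfg A [sim_config()].
#' @param families Families to generate (default hgcA, hgcB, merB).
#' @param rules Validation rules supplying the motif patterns (default the
#'   packaged rules).
#' @return List with `sequences` (named character vector) and `truth`
#'   (data frame `orf_id`, `gene_family`, `label`).
#' @export
make_marker_proteins <- function(cfg, families = c("hgcA", "hgcB", "merB"),
                                 rules = load_validation_rules()) {
  with_seed(derive_seed(cfg$seed, 101), {
    seqs <- character()
    truth <- list()
    for (fam in families) {
      patterns <- rules[[fam]]$motif_patterns
      if (is.null(patterns)) stop_config("family '%s' has no motif patterns", fam)
      n_near <- ceiling(cfg$near_motif_fraction * cfg$n_decoy_seqs)
      for (i in seq_len(cfg$n_true_seqs)) {
        id <- sprintf("%s_true_%03d", fam, i)
        s <- .random_protein(sample(cfg$seq_length[1]:cfg$seq_length[2], 1L),
                             avoid_patterns = patterns)
        s <- .embed_all(s, vapply(patterns, .motif_instance, ""))
        seqs[[id]] <- s
        truth[[id]] <- data.frame(orf_id = id, gene_family = fam,
                                  label = "true", stringsAsFactors = FALSE)
      }
      for (i in seq_len(cfg$n_decoy_seqs)) {
        id <- sprintf("%s_decoy_%03d", fam, i)
        s <- .random_protein(sample(cfg$seq_length[1]:cfg$seq_length[2], 1L),
                             avoid_patterns = patterns)
        if (i <= n_near) {
          # near-motif decoy: hamming distance 1 from a valid instance
          s <- .embed(s, .near_motif(patterns[[1L]]))
        } else if (length(patterns) > 1L && i %% 2L == 0L) {
          # multi-signature decoy carrying all but one signature
          drop <- sample.int(length(patterns), 1L)
          s <- .embed_all(s, vapply(patterns[-drop], .motif_instance, ""))
        }
        if (any(vapply(patterns, function(p) grepl(p, s), TRUE))) {
          # embedding may, rarely, complete a motif by chance; such a decoy
          # would be mislabeled, so regenerate as a plain motif-free decoy
          s <- .random_protein(sample(cfg$seq_length[1]:cfg$seq_length[2], 1L),
                               avoid_patterns = patterns)
        }
        seqs[[id]] <- s
        truth[[id]] <- data.frame(orf_id = id, gene_family = fam,
                                  label = "decoy", stringsAsFactors = FALSE)
      }
    }
    list(sequences = seqs,
         truth = do.call(rbind, c(unname(truth), list(make.row.names = FALSE))))
  })
}

.methanogen_families <- c("Methanoregulaceae", "Methanosarcinaceae",
                          "Methanobacteriaceae", "Methanotrichaceae")
.methanotroph_families <- c("Methylomonadaceae", "Beijerinckiaceae",
                            "Methylococcaceae")
.hgca_guild_lineages <- c(
  SRB = "Bacteria;Desulfobacterota;Desulfobacteria;Desulfobacterales;Desulfobacteraceae;;",
  IRB = "Bacteria;Desulfobacterota;Desulfuromonadia;Geobacterales;Geobacteraceae;;",
  methanogen = "Archaea;Halobacteriota;Methanomicrobia;Methanomicrobiales;Methanoregulaceae;;",
  syntroph = "Bacteria;Desulfobacterota;Syntrophia;Syntrophales;Syntrophaceae;;",
  unclassified = ""
)

.sim_meta_small <- function(cfg) {
  ids <- sprintf("S%02d", 1:6)
  data.frame(sample_id = ids,
             site = rep(cfg$sites, each = 2L),
             compartment = rep(cfg$compartments, 3L),
             day = 0L, flooded = TRUE,
             total_reads = round(seq(cfg$total_reads_range[1],
                                     cfg$total_reads_range[2], length.out = 6L)),
             stringsAsFactors = FALSE)
}

#' Generate search-result fixtures with known validation outcomes
#'
#' Builds hmmsearch-style, BLAST-style, lineage, and coverage tables for all
#' gene families, consistent with the marker-protein truth labels: every true
#' McrA row is titled with "methyl coenzyme M reductase" while McrA decoys
#' are titled "hypothetical protein"; pmoA confounder rows carry
#' ammonia-oxidizer lineages and the title "ammonia monooxygenase"; mbnT rows
#' split between the three demethylating genera (true) and other genera
#' (decoys); dsrA decoys score below the 392.9 cutoff; iron_reduction decoys
#' fail the E-value gate; hgcA/hgcB/merB rows carry the generated proteins so
#' the motif stage is the discriminator. True hgcA rows cycle through SRB,
#' IRB, methanogen, syntroph, and unclassified lineages.
#'
#' @param markers Output of [make_marker_proteins()], or `NULL` to generate
#'   one from `cfg`.
#' @param cfg A [sim_config()].
#' @return List with data frames `hmm`, `blast`, `lineage`, `coverage`,
#'   `meta`, `truth` (columns `orf_id`, `gene_family`, `label`,
#'   `fail_stage`), and `sequences`.
#' @export
make_search_fixtures <- function(markers = NULL, cfg) {
  if (is.null(markers)) markers <- make_marker_proteins(cfg)
  with_seed(derive_seed(cfg$seed, 202), {
    hmm_len <- c(mcrA = 550L, pmoA = 250L, mmoX = 520L, hgcA = 300L,
                 hgcB = 95L, merB = 210L, dsrA = 400L, mbnT = 700L,
                 iron_reduction = 350L)
    meta <- .sim_meta_small(cfg)
    rows <- list(); blast <- list(); lineage <- list(); truth <- list()
    add_row <- function(id, fam, label, fail_stage, score, evalue, title, lin) {
      rows[[id]] <<- data.frame(
        orf_id = id, hmm_name = fam, hmm_length = hmm_len[[fam]],
        hmm_evalue = evalue, hmm_score = score, dom_evalue = evalue,
        dom_score = score * 0.97, description = "", stringsAsFactors = FALSE)
      if (!is.na(title)) {
        blast[[id]] <<- data.frame(orf_id = id, hit_id = sprintf("ref_%s", id),
                                   title = title, stringsAsFactors = FALSE)
      }
      lineage[[id]] <<- data.frame(orf_id = id, lineage = lin,
                                   stringsAsFactors = FALSE)
      truth[[id]] <<- data.frame(orf_id = id, gene_family = fam, label = label,
                                 fail_stage = fail_stage, stringsAsFactors = FALSE)
    }
    lin_of <- function(fam_names, genus = "") {
      f <- sample(fam_names, 1L)
      sprintf("Bacteria;;;;%s;%s;", f, genus)
    }
    # families whose decoys fail at a designated non-motif stage
    for (fam in c("mcrA", "pmoA", "mmoX", "dsrA", "mbnT", "iron_reduction")) {
      n_decoy <- if (fam == "pmoA") (cfg$n_amoa %||% cfg$n_decoy_seqs)
                 else cfg$n_decoy_seqs
      for (i in seq_len(cfg$n_true_seqs)) {
        id <- sprintf("%s_true_%03d", fam, i)
        tl <- switch(fam,
          mcrA = "methyl coenzyme M reductase alpha subunit",
          pmoA = "particulate methane monooxygenase subunit A",
          mmoX = "soluble methane monooxygenase hydroxylase alpha",
          NA_character_)
        lin <- switch(fam,
          mcrA = sprintf("Archaea;Halobacteriota;Methanomicrobia;;%s;;",
                         sample(.methanogen_families, 1L)),
          pmoA = lin_of(.methanotroph_families),
          mmoX = lin_of(.methanotroph_families),
          mbnT = lin_of("Methylocystaceae",
                        sample(c("Methylomicrobium", "Methylocystis", "Methylosinus"), 1L)),
          dsrA = "Bacteria;Desulfobacterota;;;Desulfobacteraceae;;",
          "Bacteria;;;;Geobacteraceae;;")
        score <- switch(fam, dsrA = stats::runif(1, 400, 550),
                        mbnT = stats::runif(1, 240, 400),
                        stats::runif(1, 150, 400))
        add_row(id, fam, "true", NA_character_, score,
                10^stats::runif(1, -40, -8), tl, lin)
      }
      for (i in seq_len(n_decoy)) {
        id <- sprintf("%s_decoy_%03d", fam, i)
        stage <- switch(fam, mcrA = "title", pmoA = "taxon", mmoX = "title",
                        dsrA = "score", mbnT = "taxon", iron_reduction = "evalue")
        tl <- switch(fam,
          mcrA = "hypothetical protein",
          # ambiguous pmoA/amoA-family annotation: passes the title keyword,
          # so the taxon allow-list is the discriminating gate
          pmoA = "putative methane monooxygenase / ammonia monooxygenase subunit A",
          mmoX = "hypothetical oxidoreductase",
          NA_character_)
        lin <- switch(fam,
          pmoA = "Bacteria;Proteobacteria;Gammaproteobacteria;Nitrosomonadales;Nitrosomonadaceae;Nitrosomonas;",
          mbnT = lin_of("Xanthomonadaceae", "Xanthomonas"),
          "Bacteria;;;;;;")
        score <- switch(fam, dsrA = stats::runif(1, 250, 392.8),
                        mbnT = stats::runif(1, 240, 400),
                        stats::runif(1, 150, 400))
        ev <- if (stage == "evalue") 10^stats::runif(1, -4, -2)
              else 10^stats::runif(1, -40, -8)
        add_row(id, fam, "decoy", stage, score, ev, tl, lin)
      }
    }
    # motif-validated families from the marker-protein truth
    guild_cycle <- names(.hgca_guild_lineages)
    k <- 0L
    for (j in seq_len(nrow(markers$truth))) {
      id <- markers$truth$orf_id[j]
      fam <- markers$truth$gene_family[j]
      label <- markers$truth$label[j]
      lin <- if (fam == "hgcA" && label == "true") {
        k <- k + 1L
        .hgca_guild_lineages[[guild_cycle[(k - 1L) %% length(guild_cycle) + 1L]]]
      } else "Bacteria;;;;;;"
      add_row(id, fam, label, if (label == "decoy") "motif" else NA_character_,
              stats::runif(1, 150, 400), 10^stats::runif(1, -40, -8),
              NA_character_, lin)
    }
    hmm <- do.call(rbind, c(unname(rows), list(make.row.names = FALSE)))
    truth <- do.call(rbind, c(unname(truth), list(make.row.names = FALSE)))
    coverage <- data.frame(orf_id = hmm$orf_id,
                           coverage = stats::rlnorm(nrow(hmm), log(2), 0.5),
                           stringsAsFactors = FALSE)
    sample_assign <- meta$sample_id[(seq_len(nrow(hmm)) - 1L) %% nrow(meta) + 1L]
    coverage$sample_id <- sample_assign
    list(hmm = hmm,
         blast = do.call(rbind, c(unname(blast), list(make.row.names = FALSE))),
         lineage = do.call(rbind, c(unname(lineage), list(make.row.names = FALSE))),
         coverage = coverage, meta = meta, truth = truth,
         sequences = markers$sequences)
  })
}

#' Assemble a validated-input hit table from simulated fixtures
#'
#' @param fx Output of [make_search_fixtures()].
#' @return A `gene_hits` data frame covering every simulated family.
#' @export
sim_gene_hits <- function(fx) {
  fams <- unique(fx$hmm$hmm_name)
  hits <- lapply(fams, function(fam) {
    sub <- fx$hmm[fx$hmm$hmm_name == fam, , drop = FALSE]
    sid <- fx$coverage$sample_id[match(sub$orf_id, fx$coverage$orf_id)]
    assemble_gene_hits(sub, gene_family = fam, sample_id = sid,
                       blast = fx$blast, lineage = fx$lineage,
                       coverage = fx$coverage, proteins = fx$sequences)
  })
  out <- do.call(rbind, hits)
  gene_hits(out)
}

#' Generate the guild-abundance / geochemistry / metadata panel
#'
#' Samples are the full site x compartment x time-point grid (66 by
#' default). Guild coverages are log-normal at the ~1e-8 normalized-coverage
#' magnitude, with methanogen and methanotroph log-abundances coupled at
#' correlation `rho_coupling` and an optional site-level spread. MeHg is
#' generated as
#' `baseline + site_offset + compartment_offset + beta_F1*z(F1Hg) +
#'  beta_hgca*z(hgcA_total) + beta_methanogen*z(methanogen) +
#'  beta_interaction*z(methanogen)*z(methanotroph)*flooded + Normal(0, noise_sd)`,
#' where `z()` is within-dataset standardization and `flooded` is
#' `day <= flooded_cutoff_day`. A pure-noise covariate (`noise_cov`) is
#' always included. The ground-truth coefficients are returned.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_panel`: `guilds` (samples x guild columns,
#'   incl. `hgcA_total`), `geochem`, `meta`, `truth` (coefficient table).
#' @export
make_panel <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 303), {
    days <- as.integer((seq_len(cfg$n_timepoints) - 1L) * cfg$day_step)
    grid <- expand.grid(day = days, compartment = cfg$compartments,
                        site = cfg$sites, stringsAsFactors = FALSE)
    n <- nrow(grid)
    meta <- data.frame(
      sample_id = sprintf("%s_%s_d%03d", grid$site,
                          substr(grid$compartment, 1, 1), grid$day),
      site = grid$site, compartment = grid$compartment, day = grid$day,
      flooded = grid$day <= cfg$flooded_cutoff_day,
      total_reads = round(stats::runif(n, cfg$total_reads_range[1],
                                       cfg$total_reads_range[2])),
      stringsAsFactors = FALSE)

    site_eff <- function() {
      if (cfg$guild_site_sd > 0)
        stats::rnorm(length(cfg$sites), 0, cfg$guild_site_sd)[match(meta$site, cfg$sites)]
      else rep(0, n)
    }
    lnorm_guild <- function() {
      exp(cfg$abundance_meanlog + site_eff() +
            stats::rnorm(n, 0, cfg$abundance_sdlog))
    }
    # coupled methanogen / methanotroph log-abundances
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    l_gen <- z1
    l_oto <- cfg$rho_coupling * z1 + sqrt(1 - cfg$rho_coupling^2) * z2
    methanogen <- exp(cfg$abundance_meanlog + site_eff() + cfg$abundance_sdlog * l_gen)
    # methanotrophs sit roughly an order of magnitude below methanogens
    methanotroph <- exp(cfg$abundance_meanlog - log(10) + site_eff() +
                          cfg$abundance_sdlog * l_oto)
    guilds <- data.frame(
      sample_id = meta$sample_id,
      methanogen = methanogen,
      methanotroph = methanotroph,
      hgcA_methanogen = lnorm_guild(),
      hgcA_SRB = lnorm_guild(),
      hgcA_IRB = lnorm_guild(),
      hgcA_syntroph = 0.1 * lnorm_guild(),
      merB = lnorm_guild(),
      dsrA_SRB = lnorm_guild(),
      IRB = lnorm_guild(),
      mbnT_demethylator = 0.2 * lnorm_guild(),
      stringsAsFactors = FALSE)
    guilds$hgcA_total <- guilds$hgcA_methanogen + guilds$hgcA_SRB +
      guilds$hgcA_IRB + guilds$hgcA_syntroph

    F1Hg <- stats::rlnorm(n, log(30), 0.6)
    thg_mean <- c(HX = 0.17, GX = 21.41, SK = 42.03)
    geochem <- data.frame(
      sample_id = meta$sample_id,
      THg = stats::rlnorm(n, log(thg_mean[meta$site]), 0.3),
      MeHg = NA_real_,
      F1Hg = F1Hg,
      DOM = stats::rlnorm(n, log(20), 0.4),
      SUVA254 = stats::rlnorm(n, log(2), 0.3),
      sulfate = stats::rlnorm(n, log(150), 0.5),
      nitrate = stats::rlnorm(n, log(10), 0.5),
      Fe2_to_totalFe = stats::runif(n),
      pH = stats::rnorm(n, 6.5, 0.4),
      noise_cov = stats::rnorm(n),
      stringsAsFactors = FALSE)

    zf <- zscore(F1Hg, "F1Hg")
    zh <- zscore(guilds$hgcA_total, "hgcA_total")
    zg <- zscore(guilds$methanogen, "methanogen")
    zo <- zscore(guilds$methanotroph, "methanotroph")
    eps <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else rep(0, n)
    geochem$MeHg <- cfg$mehg_baseline +
      cfg$site_offsets[meta$site] +
      cfg$compartment_offset * (meta$compartment == "rhizosphere") +
      cfg$beta_F1 * zf + cfg$beta_hgca * zh + cfg$beta_methanogen * zg +
      cfg$beta_interaction * zg * zo * meta$flooded + eps
    geochem$MeHg <- as.numeric(geochem$MeHg)

    truth <- data.frame(
      term = c("baseline", paste0("site_", cfg$sites), "compartment_rhizosphere",
               "z_F1Hg", "z_hgcA_total", "z_methanogen",
               "z_methanogen_x_z_methanotroph_flooded", "noise_sd"),
      value = c(cfg$mehg_baseline, unname(cfg$site_offsets[cfg$sites]),
                cfg$compartment_offset, cfg$beta_F1, cfg$beta_hgca,
                cfg$beta_methanogen, cfg$beta_interaction, cfg$noise_sd),
      stringsAsFactors = FALSE)
    structure(list(guilds = guilds, geochem = geochem, meta = meta,
                   truth = truth), class = "sim_panel")
  })
}

#' Generate lagged time series with known delays
#'
#' Builds a target (MeHg-like) series of length `n_timepoints` and a set of
#' abundance series: `n_lagged` series are delayed, optionally sign-flipped,
#' noised copies of the target (`series[t] = sign * target[t - d] + noise`,
#' delay `d` drawn from `lag_delays`; the first `d` points are independent
#' noise), and `n_null_series` are independent. Truth lists the true delay
#' and sign per series; null series have delay `NA`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_lagged`: `target` (numeric), `series`
#'   (matrix time x series), `truth` (data frame `series_id`, `delay`,
#'   `sign`, `label`).
#' @export
make_lagged_series <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 404), {
    nt <- cfg$n_timepoints
    target <- stats::rnorm(nt)
    n_series <- cfg$n_lagged + cfg$n_null_series
    series <- matrix(NA_real_, nt, n_series)
    truth <- data.frame(series_id = sprintf("MAG%03d", seq_len(n_series)),
                        delay = NA_integer_, sign = NA_integer_,
                        label = rep(c("lagged", "null"),
                                    c(cfg$n_lagged, cfg$n_null_series)),
                        stringsAsFactors = FALSE)
    for (i in seq_len(cfg$n_lagged)) {
      d <- cfg$lag_delays[(i - 1L) %% length(cfg$lag_delays) + 1L]
      sgn <- if (stats::runif(1) < cfg$neg_sign_prob) -1L else 1L
      s <- stats::rnorm(nt)  # independent fill for the first d points
      if (d < nt) {
        idx <- (d + 1L):nt
        s[idx] <- sgn * target[idx - d] +
          if (cfg$lag_noise_sd > 0) stats::rnorm(length(idx), 0, cfg$lag_noise_sd) else 0
      }
      series[, i] <- s
      truth$delay[i] <- as.integer(d)
      truth$sign[i] <- sgn
    }
    for (i in seq_len(cfg$n_null_series)) {
      series[, cfg$n_lagged + i] <- stats::rnorm(nt)
    }
    colnames(series) <- truth$series_id
    structure(list(target = target, series = series, truth = truth),
              class = "sim_lagged")
  })
}

# --- writers: emit the exact dialects the io readers consume -------------

.format_domtbl <- function(hmm) {
  vapply(seq_len(nrow(hmm)), function(i) {
    r <- hmm[i, ]
    paste(r$orf_id, "-", r$hmm_length + 10L, r$hmm_name, "-", r$hmm_length,
          format(r$hmm_evalue, digits = 3), format(r$hmm_score, digits = 6),
          "0.1", "1", "1",
          format(r$dom_evalue, digits = 3), format(r$dom_evalue, digits = 3),
          format(r$dom_score, digits = 6), "0.1",
          "1", r$hmm_length, "1", r$hmm_length, "1", r$hmm_length, "0.90",
          r$description, sep = " ")
  }, "")
}

#' Write simulated fixtures in the pipeline's input dialects
#'
#' Emits a protein FASTA, an hmmsearch-style `--domtblout` table, a BLAST
#' `outfmt "6 std stitle"` table, and lineage / coverage / metadata TSVs.
#'
#' @param fx Output of [make_search_fixtures()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_search_fixtures <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "proteins.faa"),
    hmm = file.path(dir, "hits.domtblout"),
    blast = file.path(dir, "hits.blastp.tsv"),
    lineage = file.path(dir, "lineage.tsv"),
    coverage = file.path(dir, "coverage.tsv"),
    meta = file.path(dir, "sample_meta.tsv"))
  write_fasta(fx$sequences, paths[["fasta"]])
  writeLines(c("# target name -- simulated per-domain table",
               .format_domtbl(fx$hmm)), paths[["hmm"]])
  blast <- fx$blast
  blast_lines <- sprintf("%s\t%s\t98.0\t200\t2\t0\t1\t200\t1\t200\t1e-50\t400\t%s",
                         blast$orf_id, blast$hit_id, blast$title)
  writeLines(blast_lines, paths[["blast"]])
  write_table(fx$lineage, paths[["lineage"]])
  write_table(fx$coverage, paths[["coverage"]])
  write_table(fx$meta, paths[["meta"]])
  invisible(paths)
}

#' Write a simulated panel as TSV files
#'
#' @param panel Output of [make_panel()].
#' @param dir Output directory.
#' @return Named character vector of written paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(guilds = file.path(dir, "guild_abundance.tsv"),
             geochem = file.path(dir, "geochem.tsv"),
             meta = file.path(dir, "panel_meta.tsv"),
             truth = file.path(dir, "panel_truth.tsv"))
  write_table(panel$guilds, paths[["guilds"]])
  write_table(panel$geochem, paths[["geochem"]])
  write_table(panel$meta, paths[["meta"]])
  write_table(panel$truth, paths[["truth"]])
  invisible(paths)
}
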