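# Coverage normalization and guild aggregation for gene-centric
# quantification: per-sample taxon coverages are scaled by the effective
# library size and the HMM length, so values are dimensionless and
# comparable across samples (typical magnitude ~1e-8).

#' Normalized taxon coverage
#'
#' `taxon_coverage / (total_reads * hmm_length)`: the summed per-ORF mean
#' read coverage attributed to a taxon for one gene family, scaled by the
#' sample's (effective) library size and the length of the HMM used to
#' retrieve the family.
#'
#' @param taxon_coverage Non-negative coverage sum(s).
#' @param total_reads Positive library size(s).
#' @param hmm_length Positive HMM match-state length(s), in amino acids.
#' @return Numeric vector of normalized coverages.
#' @export
normalized_coverage <- function(taxon_coverage, total_reads, hmm_length) {
  if (any(total_reads <= 0)) stop_domain("total_reads must be > 0")
  if (any(hmm_length <= 0)) stop_domain("hmm_length must be > 0")
  if (any(taxon_coverage < 0)) stop_domain("taxon_coverage must be >= 0")
  taxon_coverage / (total_reads * hmm_length)
}

#' Effective library sizes by trimmed mean of M-values
#'
#' Computes TMM normalization factors with [edgeR::calcNormFactors()]
#' (factors are rescaled to geometric mean 1; the reference sample is the
#' one whose upper-quartile count fraction is closest to the mean of those
#' fractions) and returns `raw library size x factor` per sample.
#'
#' @param counts Non-negative integer matrix or data frame, genes x samples.
#' @param trim_M Trim fraction for log-ratios (default 0.3).
#' @param trim_A Trim fraction for average log-intensities (default 0.05).
#' @return Named numeric vector of effective library sizes.
#' @export
effective_library_sizes <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop_domain("need at least 2 samples for TMM")
  if (any(counts < 0)) stop_domain("counts must be non-negative")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop_data("sample(s) with all-zero counts: %s",
              paste(colnames(counts)[libsize == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  out <- libsize * f
  names(out) <- colnames(counts)
  out
}

# resolve a lineage matrix to a guild using the most specific mapped rank
.lineage_guild <- function(lineage, map) {
  ranks <- parse_lineage(lineage)
  out <- rep("unclassified", nrow(ranks))
  for (rk in rev(.lineage_ranks)) {  # species -> domain: most specific wins
    hit <- match(ranks[, rk], map$taxon)
    take <- out == "unclassified" & !is.na(hit)
    out[take] <- map$guild[hit[take]]
  }
  out
}

#' Load the hgcA metabolic-guild lineage map
#'
#' Maps lineage taxa (any rank; most specific rank wins) to the four
#' classical Hg-methylating guilds: SRB, IRB, methanogen, syntroph.
#' The packaged default is user-replaceable.
#'
#' @param path Optional path to a TSV with columns `taxon`, `guild`.
#' @return Data frame `taxon`, `guild`.
#' @export
load_guild_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hgca_guild_map.tsv", package = "paddyMeHg",
                        mustWork = TRUE)
  }
  read_table_schema(path, c(taxon = "character", guild = "character"))
}

#' Aggregate validated hits into a guild-abundance table
#'
#' Per sample and gene family, sums the per-ORF coverages of validated hits
#' and applies [normalized_coverage()] with the sample's `total_reads` (use
#' effective library sizes there for cross-sample comparability). Guild
#' columns: `methanogen` (mcrA, with Methanoperedenaceae/ANME hits excluded
#' by default), `methanotroph` (pmoA and mmoX with per-ORF deduplication, an
#' ORF hit by both HMMs is counted once under its higher-scoring family),
#' `hgcA_total` plus its split by the metabolic-guild lineage map
#' (`hgcA_methanogen`, `hgcA_SRB`, `hgcA_IRB`, `hgcA_syntroph`; unclassified
#' hgcA is retained in the total), `merB`, `dsrA_SRB`, `mbnT_demethylator`,
#' and `IRB` (iron_reduction family) when present. A per-taxon long table at
#' the requested rank is also returned, with empty ranks pooled as
#' `"Unclassified"`.
#'
#' @param hits Validated `gene_hits` (output `retained` of [validate_all()]),
#'   with non-missing `coverage`.
#' @param meta Sample metadata (see [read_sample_meta()]); every output row
#'   corresponds to one metadata sample.
#' @param hmm_lengths Optional named vector family -> HMM length; defaults to
#'   the `hmm_length` carried on the hits.
#' @param rank Taxonomic rank for the per-taxon table (default `"family"`).
#' @param guild_map hgcA guild map (default packaged, see [load_guild_map()]).
#' @param include_anme Keep Methanoperedenaceae mcrA hits in the methanogen
#'   guild (default `FALSE`).
#' @return List of class `guild_abundance`: `guilds` (samples x guild
#'   columns) and `taxa` (long data frame `sample_id`, `gene_family`,
#'   `taxon`, `value`).
#' @export
aggregate_guilds <- function(hits, meta, hmm_lengths = NULL, rank = "family",
                             guild_map = load_guild_map(),
                             include_anme = FALSE) {
  hits <- as.data.frame(hits)
  if (nrow(hits) && anyNA(hits$coverage))
    stop_data("hits carry missing coverage values; aggregation needs coverage")
  extra <- setdiff(unique(hits$sample_id), meta$sample_id)
  if (length(extra)) {
    stop_data("hit sample_id(s) absent from metadata: %s",
              paste(extra, collapse = ", "))
  }
  if (!rank %in% .lineage_ranks) stop_config("unknown rank '%s'", rank)
  if (is.null(hmm_lengths)) {
    hmm_lengths <- tapply(hits$hmm_length, hits$gene_family, function(x) x[1])
  }
  miss <- setdiff(unique(hits$gene_family), names(hmm_lengths))
  if (length(miss)) stop_config("no hmm_length for family/families: %s",
                                paste(miss, collapse = ", "))
  samples <- meta$sample_id
  reads <- stats::setNames(meta$total_reads, samples)

  # per-ORF deduplication across the two methanotroph marker families
  mt <- hits$gene_family %in% c("pmoA", "mmoX")
  if (any(mt)) {
    sub <- hits[mt, , drop = FALSE]
    key <- paste(sub$sample_id, sub$orf_id)
    ord <- order(key, -sub$hmm_score)
    sub <- sub[ord, , drop = FALSE]
    sub <- sub[!duplicated(paste(sub$sample_id, sub$orf_id)), , drop = FALSE]
    hits <- rbind(hits[!mt, , drop = FALSE], sub)
  }

  # ANME flagging: Methanoperedenaceae mcrA excluded from the methanogen guild
  fam_rank <- parse_lineage(hits$lineage)[, "family", drop = TRUE]
  anme <- hits$gene_family == "mcrA" & fam_rank == "Methanoperedenaceae"
  if (any(anme)) {
    log_msg("info", "flagged %d Methanoperedenaceae (ANME) mcrA hit(s)%s",
            sum(anme), if (include_anme) " (included)" else " (excluded from methanogen guild)")
  }

  norm_sum <- function(sub) {
    # per (sample, family) normalized coverage, summed over families
    out <- stats::setNames(rep(0, length(samples)), samples)
    if (!nrow(sub)) return(out)
    for (fam in unique(sub$gene_family)) {
      ss <- sub[sub$gene_family == fam, , drop = FALSE]
      cov <- tapply(ss$coverage, factor(ss$sample_id, levels = samples), sum,
                    default = 0)
      out <- out + normalized_coverage(as.numeric(cov), reads[samples],
                                       hmm_lengths[[fam]])
    }
    out
  }

  hg <- hits[hits$gene_family == "hgcA", , drop = FALSE]
  hg_guild <- .lineage_guild(hg$lineage, guild_map)
  mcra_keep <- hits$gene_family == "mcrA" & (include_anme | !anme)

  guilds <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  guilds$methanogen <- norm_sum(hits[mcra_keep, , drop = FALSE])
  guilds$methanotroph <- norm_sum(hits[hits$gene_family %in% c("pmoA", "mmoX"), , drop = FALSE])
  guilds$hgcA_total <- norm_sum(hg)
  for (g in c("methanogen", "SRB", "IRB", "syntroph")) {
    guilds[[paste0("hgcA_", g)]] <- norm_sum(hg[hg_guild == g, , drop = FALSE])
  }
  guilds$merB <- norm_sum(hits[hits$gene_family == "merB", , drop = FALSE])
  guilds$dsrA_SRB <- norm_sum(hits[hits$gene_family == "dsrA", , drop = FALSE])
  guilds$mbnT_demethylator <- norm_sum(hits[hits$gene_family == "mbnT", , drop = FALSE])
  if (any(hits$gene_family == "iron_reduction")) {
    guilds$IRB <- norm_sum(hits[hits$gene_family == "iron_reduction", , drop = FALSE])
  }
  rownames(guilds) <- NULL

  taxon <- parse_lineage(hits$lineage)[, rank, drop = TRUE]
  taxon[!nzchar(taxon) | is.na(taxon)] <- "Unclassified"
  taxa <- do.call(rbind, lapply(unique(hits$gene_family), function(fam) {
    sub <- hits[hits$gene_family == fam, , drop = FALSE]
    tx <- taxon[hits$gene_family == fam]
    agg <- stats::aggregate(sub$coverage,
                            by = list(sample_id = sub$sample_id, taxon = tx), sum)
    data.frame(sample_id = agg$sample_id, gene_family = fam, taxon = agg$taxon,
               value = normalized_coverage(agg$x, reads[agg$sample_id],
                                           hmm_lengths[[fam]]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(guilds = guilds, taxa = taxa), class = "guild_abundance")
}

#' Iron-reducer abundance normalized to coding-sequence counts
#'
#' Sums the coverages of all identified iron-reduction genes per sample and
#' divides by the sample's total CDS count.
#'
#' @param iron_gene_hits `gene_hits` rows for iron-reduction genes.
#' @param total_cds_counts Named vector sample_id -> total CDS count (> 0).
#' @return Named numeric vector, one value per entry of `total_cds_counts`
#'   (0 for samples without hits).
#' @export
irb_abundance <- function(iron_gene_hits, total_cds_counts) {
  if (any(total_cds_counts <= 0)) stop_domain("total CDS counts must be > 0")
  hits <- as.data.frame(iron_gene_hits)
  out <- stats::setNames(rep(0, length(total_cds_counts)), names(total_cds_counts))
  if (nrow(hits)) {
    extra <- setdiff(unique(hits$sample_id), names(total_cds_counts))
    if (length(extra)) {
      stop_data("iron-gene sample_id(s) without CDS counts: %s",
                paste(extra, collapse = ", "))
    }
    s <- tapply(hits$coverage, hits$sample_id, sum)
    out[names(s)] <- as.numeric(s) / total_cds_counts[names(s)]
  }
  out
}
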