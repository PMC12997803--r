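# Marker-gene hit validation: score/E-value gates, BLAST-title keywords,
# taxon allow-lists, conserved-motif matching, and methanobactin cluster
# typing.

.gene_families <- c("mcrA", "pmoA", "mmoX", "hgcA", "hgcB", "merB", "dsrA",
                    "mbnT", "iron_reduction")
.mbn_genes <- c("mbnA", "mbnB", "mbnC", "mbnD", "mbnE", "mbnF", "mbnM",
                "mbnN", "mbnS", "mbnT", "mbnX")

#' Construct a validation rule
#'
#' A rule bundles every criterion applied to one gene family: a minimum bit
#' score, a maximum E-value, case-insensitive BLAST-title keywords, lineage
#' allow-list entries, and amino-acid motif patterns. Motif patterns use
#' exact per-position character classes (e.g. `N[VI]WCA[AG]GK`): only plain
#' residue letters and square-bracket classes are allowed, no gaps or
#' mismatch tolerance.
#'
#' @param gene_family Gene family name.
#' @param min_score Minimum full-sequence bit score, or `NULL`.
#' @param max_evalue Maximum E-value, or `NULL`.
#' @param title_keywords Character vector of keywords, or `NULL`.
#' @param allowed_taxa Character vector of lineage allow-list entries
#'   (optionally rank-prefixed, e.g. `"f__Methylomonadaceae"`), or `NULL`.
#' @param motif_patterns Character vector of character-class patterns, or `NULL`.
#' @return An object of class `validation_rule`.
#' @export
validation_rule <- function(gene_family, min_score = NULL, max_evalue = NULL,
                            title_keywords = NULL, allowed_taxa = NULL,
                            motif_patterns = NULL) {
  if (is.null(min_score) && is.null(max_evalue) && is.null(title_keywords) &&
      is.null(allowed_taxa) && is.null(motif_patterns)) {
    stop_config("rule for '%s' has no criteria", gene_family)
  }
  if (!is.null(motif_patterns)) {
    bad <- !grepl("^([A-Z]|\\[[A-Z]+\\])+$", motif_patterns)
    if (any(bad)) {
      stop_config("invalid motif pattern(s) for '%s': %s", gene_family,
                  paste(motif_patterns[bad], collapse = ", "))
    }
  }
  structure(list(gene_family = gene_family, min_score = min_score,
                 max_evalue = max_evalue, title_keywords = title_keywords,
                 allowed_taxa = allowed_taxa, motif_patterns = motif_patterns),
            class = "validation_rule")
}

#' Load a validation rule set
#'
#' Reads the packaged (or a user-supplied) rule table: one row per gene
#' family with pipe-separated multi-valued fields. The packaged defaults
#' encode the hgcA cap-helix motif `N[VI]WCA[AG]GK`, the hgcB motif
#' `C[MI]ECGA`, the dsrA (392.9) and mbnT (223.5) bit-score cutoffs, the
#' methanotroph family allow-list for pmoA, the demethylating-genus
#' allow-list for mbnT, and synthetic stand-in MerB residue signatures.
#'
#' @param path Path to a rules TSV; default: the packaged rule file.
#' @return Named list of [validation_rule()] objects, class `validation_rules`.
#' @export
load_validation_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "validation_rules.tsv", package = "paddyMeHg",
                        mustWork = TRUE)
  }
  df <- read_table_schema(path, c(gene_family = "character"))
  split_field <- function(x) {
    if (is.na(x) || x == "NA" || !nzchar(x)) NULL
    else strsplit(x, "|", fixed = TRUE)[[1L]]
  }
  num_field <- function(x) {
    if (is.na(x) || x == "NA" || !nzchar(x)) NULL else as.numeric(x)
  }
  rules <- lapply(seq_len(nrow(df)), function(i) {
    validation_rule(
      gene_family = df$gene_family[i],
      min_score = num_field(df$min_score[i]),
      max_evalue = num_field(df$max_evalue[i]),
      title_keywords = split_field(df$title_keywords[i]),
      allowed_taxa = split_field(df$allowed_taxa[i]),
      motif_patterns = split_field(df$motif_patterns[i])
    )
  })
  names(rules) <- df$gene_family
  structure(rules, class = "validation_rules")
}

# one hit as a named list, whether given a list or a 1-row data frame
.as_hit <- function(hit) {
  if (is.data.frame(hit)) {
    if (nrow(hit) != 1L) stop_config("expected a single hit, got %d rows", nrow(hit))
    hit <- as.list(hit)
  }
  hit
}

#' Test conserved-motif patterns against a hit's protein sequence
#'
#' Returns `TRUE` iff *every* pattern in the rule matches somewhere in the
#' sequence. Matching is unanchored but exact per position: each pattern
#' position is a residue letter or a character class, with no gaps and no
#' mismatch tolerance (a hamming-distance-1 near-motif does not match).
#'
#' @param hit A single hit (list or one-row `gene_hits` data frame) with a
#'   `protein_seq` field.
#' @param rule A [validation_rule()] with non-empty `motif_patterns`.
#' @return Logical scalar.
#' @export
validate_motif <- function(hit, rule) {
  hit <- .as_hit(hit)
  seq <- hit$protein_seq
  if (is.null(seq) || is.na(seq) || !nzchar(seq)) {
    stop_data("hit '%s' has no protein sequence; motif rule for '%s' cannot be adjudicated",
              hit$orf_id %||% "?", rule$gene_family)
  }
  all(vapply(rule$motif_patterns, function(p) grepl(p, seq), TRUE))
}

#' Test BLAST-title keywords
#'
#' `TRUE` iff any rule keyword is a case-insensitive substring of the hit's
#' best-hit title. A missing title yields `FALSE` with a logged warning (the
#' hit had no homolog), never an error.
#'
#' @inheritParams validate_motif
#' @return Logical scalar.
#' @export
validate_title <- function(hit, rule) {
  hit <- .as_hit(hit)
  title <- hit$blast_title
  if (is.null(title) || is.na(title) || !nzchar(title)) {
    log_msg("warn", "hit '%s' has no BLAST title; failing title rule for '%s'",
            hit$orf_id %||% "?", rule$gene_family)
    return(FALSE)
  }
  any(vapply(rule$title_keywords,
             function(k) grepl(k, title, ignore.case = TRUE, fixed = FALSE),
             TRUE))
}

# does one allow-list entry match a parsed lineage row?
.taxon_entry_matches <- function(entry, ranks) {
  has_prefix <- grepl("^[dpcofgs]__", entry)
  if (has_prefix) {
    rank <- c(d = "domain", p = "phylum", c = "class", o = "order",
              f = "family", g = "genus", s = "species")[[substr(entry, 1, 1)]]
    name <- sub("^[dpcofgs]__", "", entry)
    identical(unname(ranks[[rank]]), name)
  } else if (grepl(";", entry, fixed = TRUE)) {
    want <- parse_lineage(entry)[1L, ]
    want <- want[nzchar(want)]
    all(ranks[seq_along(want)] == want)
  } else {
    entry %in% ranks
  }
}

#' Test a taxon allow-list
#'
#' `TRUE` iff any allow-list entry matches the hit's lineage: rank-prefixed
#' entries (`f__X`) must equal the lineage at that rank, semicolon paths must
#' be a lineage prefix, and bare names may match at any rank. An empty or
#' missing lineage fails.
#'
#' @inheritParams validate_motif
#' @return Logical scalar.
#' @export
validate_taxon <- function(hit, rule) {
  hit <- .as_hit(hit)
  if (is.null(rule$allowed_taxa) || !length(rule$allowed_taxa)) {
    stop_config("taxon rule for '%s' has an empty allow-list", rule$gene_family)
  }
  lin <- hit$lineage
  if (is.null(lin) || is.na(lin) || !nzchar(lin)) return(FALSE)
  ranks <- parse_lineage(lin)[1L, ]
  any(vapply(rule$allowed_taxa, .taxon_entry_matches, TRUE, ranks = ranks))
}

#' Validate a MerB candidate against residue-signature motifs
#'
#' MerB (organomercurial lyase) hits are accepted only when all configured
#' cysteine/aspartate residue-context signatures match the protein. The
#' packaged default signatures are synthetic stand-ins (the curated residue
#' positions are not part of the package); supply a replacement rule for
#' curated signatures.
#'
#' @inheritParams validate_motif
#' @return Logical scalar.
#' @export
validate_merb <- function(hit, rule) {
  validate_motif(hit, rule)
}

#' Apply the full validation cascade to a hit table
#'
#' Criteria are applied per gene family in a fixed, observable order —
#' score/E-value, then BLAST title, then taxon allow-list, then motifs —
#' and each rejected hit carries the first failing criterion as a reason
#' code (`score`, `evalue`, `title`, `taxon`, `motif`). Hits whose motif
#' rule cannot be adjudicated for lack of a sequence raise an error rather
#' than being silently dropped.
#'
#' @param hits A `gene_hits` data frame (see [gene_hits()]).
#' @param rules A `validation_rules` list covering every family present.
#' @return List with elements `retained` (a `gene_hits` data frame) and
#'   `rejected` (the same plus a `reason` column); the two partition the
#'   input.
#' @export
validate_all <- function(hits, rules) {
  hits <- gene_hits(as.data.frame(hits))
  fams <- unique(hits$gene_family)
  unknown <- setdiff(fams, names(rules))
  if (length(unknown)) {
    stop_config("no validation rule for gene family/families: %s",
                paste(unknown, collapse = ", "))
  }
  n <- nrow(hits)
  reason <- rep(NA_character_, n)
  for (fam in fams) {
    idx <- which(hits$gene_family == fam)
    rule <- rules[[fam]]
    for (i in idx) {
      hit <- as.list(hits[i, ])
      r <- NA_character_
      if (!is.null(rule$min_score) && hit$hmm_score < rule$min_score) {
        r <- "score"
      } else if (!is.null(rule$max_evalue) && hit$hmm_evalue > rule$max_evalue) {
        r <- "evalue"
      } else if (!is.null(rule$title_keywords) && !validate_title(hit, rule)) {
        r <- "title"
      } else if (!is.null(rule$allowed_taxa) && !validate_taxon(hit, rule)) {
        r <- "taxon"
      } else if (!is.null(rule$motif_patterns) && !validate_motif(hit, rule)) {
        r <- "motif"
      }
      reason[i] <- r
    }
  }
  keep <- is.na(reason)
  retained <- hits[keep, , drop = FALSE]
  rejected <- hits[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  class(retained) <- c("gene_hits", "data.frame")
  log_msg("info", "validate_all: %d hits in, %d retained, %d rejected",
          n, nrow(retained), nrow(rejected))
  list(retained = retained, rejected = rejected)
}

#' Type methanobactin gene clusters
#'
#' Classifies genomes by their methanobactin-related gene content:
#' `producer` when the core biosynthesis genes mbnA, mbnB, mbnC are all
#' present; otherwise `uptake_only` when the TonB-dependent transporter gene
#' mbnT is present; otherwise `none`. An optional override list adds genes
#' per genome (e.g. a biosynthesis gene present only as a pseudogene missed
#' by HMM search but confirmed by annotation).
#'
#' @param genome_hits Named list: genome id -> character vector of mbn gene
#'   names passing their per-gene thresholds.
#' @param overrides Optional named list: genome id -> extra gene names to
#'   treat as present.
#' @return Data frame with columns `genome_id`, `genes`
#'   (comma-separated), `class`.
#' @export
profile_mbn <- function(genome_hits, overrides = NULL) {
  if (length(genome_hits) && is.null(names(genome_hits)))
    stop_config("genome_hits must be a named list")
  rows <- lapply(names(genome_hits), function(g) {
    genes <- union(as.character(genome_hits[[g]]),
                   as.character(overrides[[g]] %||% character()))
    unknown <- setdiff(genes, .mbn_genes)
    if (length(unknown)) {
      stop_config("genome '%s' has unknown mbn gene name(s): %s", g,
                  paste(unknown, collapse = ", "))
    }
    cls <- if (all(c("mbnA", "mbnB", "mbnC") %in% genes)) "producer"
           else if ("mbnT" %in% genes) "uptake_only"
           else "none"
    data.frame(genome_id = g,
               genes = paste(sort(genes), collapse = ","),
               class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE))) %||%
    data.frame(genome_id = character(), genes = character(),
               class = character(), stringsAsFactors = FALSE)
}
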