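#' Read a protein FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] with up-front structural
#' validation (so malformed input fails with a line-numbered format error),
#' sequence uppercasing, and removal of a terminal `*` stop character.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of uppercased sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop_format("empty FASTA file: %s (line 1)", path)
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop_format("malformed FASTA header in %s: line %d does not start with '>'",
                path, first)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop_format("no records in FASTA file: %s (line 1)", path)
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  # keep only the first whitespace token of each header as the id
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Write a protein FASTA file
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Fixed column layout of hmmsearch --domtblout (22 columns + free-text
# description). The full-sequence score/E-value live in columns 8/7; the
# per-domain score and independent E-value in columns 14/13.
.domtbl_cols <- 22L

#' Read an hmmsearch per-domain table (`--domtblout`)
#'
#' Parses the whitespace-delimited per-domain tabular output of `hmmsearch`,
#' skipping `#` comment lines, and optionally filters rows on the bit score
#' (kept when `score >= score_cutoff`) and E-value (kept when
#' `evalue <= evalue_cutoff`). By default the full-sequence score and
#' full-sequence E-value are the filtering fields; set
#' `score_type = "domain"` to filter on the per-domain score and independent
#' E-value instead.
#'
#' @param path Path to a `--domtblout` file.
#' @param score_cutoff Minimum bit score, or `NULL` for no score filter.
#' @param evalue_cutoff Maximum E-value, or `NULL` for no E-value filter.
#' @param score_type `"full"` (default) or `"domain"`.
#' @return A data frame with columns `orf_id`, `hmm_name`, `hmm_length`,
#'   `hmm_evalue`, `hmm_score`, `dom_evalue`, `dom_score`, `description`,
#'   one row per retained table row, in file order.
#' @export
read_hmm_table <- function(path, score_cutoff = NULL, evalue_cutoff = NULL,
                           score_type = c("full", "domain")) {
  score_type <- match.arg(score_type)
  if (!file.exists(path)) stop_format("hmm table does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  out <- data.frame(orf_id = character(), hmm_name = character(),
                    hmm_length = integer(), hmm_evalue = numeric(),
                    hmm_score = numeric(), dom_evalue = numeric(),
                    dom_score = numeric(), description = character(),
                    stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(out)
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) < .domtbl_cols)
  if (length(bad)) {
    stop_format("hmm table %s: row %d has fewer than %d columns",
                path, bad[1L], .domtbl_cols)
  }
  getf <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(getf(i)))
    if (anyNA(v)) {
      stop_format("hmm table %s: non-numeric %s in row %d",
                  path, what, which(is.na(v))[1L])
    }
    v
  }
  out <- data.frame(
    orf_id      = getf(1L),
    hmm_name    = getf(4L),
    hmm_length  = as.integer(num(6L, "query length")),
    hmm_evalue  = num(7L, "E-value"),
    hmm_score   = num(8L, "score"),
    dom_evalue  = num(13L, "domain E-value"),
    dom_score   = num(14L, "domain score"),
    description = vapply(fields, function(f) {
      if (length(f) > .domtbl_cols) paste(f[(.domtbl_cols + 1L):length(f)], collapse = " ")
      else ""
    }, ""),
    stringsAsFactors = FALSE
  )
  sc <- if (score_type == "full") out$hmm_score else out$dom_score
  ev <- if (score_type == "full") out$hmm_evalue else out$dom_evalue
  keep <- rep(TRUE, nrow(out))
  if (!is.null(score_cutoff)) keep <- keep & sc >= score_cutoff
  if (!is.null(evalue_cutoff)) keep <- keep & ev <= evalue_cutoff
  out[keep, , drop = FALSE]
}

#' Read a tabular BLAST result (`-outfmt "6 std stitle"`)
#'
#' Expects the 12 standard columns plus a subject-title column. Multiple rows
#' per query are collapsed to the first row in file order (BLAST emits the
#' best hit first; ties are not re-sorted).
#'
#' @param path Path to a tab-separated BLAST table.
#' @return Data frame with one row per query: `orf_id`, `hit_id`, `title`.
#' @export
read_blast_table <- function(path) {
  if (!file.exists(path)) stop_format("BLAST table does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) {
    return(data.frame(orf_id = character(), hit_id = character(),
                      title = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 13L)
  if (length(bad)) {
    stop_format("BLAST table %s: row %d lacks the subject-title column (needs >= 13 columns)",
                path, bad[1L])
  }
  df <- data.frame(
    orf_id = vapply(fields, `[[`, "", 1L),
    hit_id = vapply(fields, `[[`, "", 2L),
    title  = vapply(fields, function(f) paste(f[13L:length(f)], collapse = "\t"), ""),
    stringsAsFactors = FALSE
  )
  df[!duplicated(df$orf_id), , drop = FALSE]
}

#' Read a typed TSV table against a column schema
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Named character vector mapping required column names to types
#'   (`"character"`, `"numeric"`, `"integer"`, `"logical"`). Extra columns are
#'   kept as character. Empty cells and `"NA"` become `NA`, never zero.
#' @return Data frame with typed columns.
#' @export
read_table_schema <- function(path, schema) {
  if (!file.exists(path)) stop_format("table does not exist: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop_schema("table %s is missing required column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      character = df[[col]],
      numeric = {
        v <- suppressWarnings(as.numeric(df[[col]]))
        if (any(is.na(v) & !is.na(df[[col]])))
          stop_format("table %s: non-numeric value in column '%s'", path, col)
        v
      },
      integer = {
        v <- suppressWarnings(as.integer(df[[col]]))
        if (any(is.na(v) & !is.na(df[[col]])))
          stop_format("table %s: non-integer value in column '%s'", path, col)
        v
      },
      logical = as.logical(df[[col]]),
      stop_config("unknown schema type '%s' for column '%s'", schema[[col]], col)
    )
  }
  df
}

#' Write a data frame as TSV
#'
#' Writes with `NA` for missing cells so that [read_table_schema()] round-trips
#' valid tables cell-identically.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.geochem_schema <- c(sample_id = "character", MeHg = "numeric")
.geochem_numeric <- c("THg", "MeHg", "F1Hg", "DOM", "SUVA254", "sulfide",
                      "sulfate", "nitrate", "Fe2_to_totalFe", "ORP", "pH")

#' Read a per-sample geochemistry panel
#'
#' Requires `sample_id` and `MeHg`; the remaining geochemical fields (THg,
#' F1Hg, DOM, SUVA254, sulfide, sulfate, nitrate, Fe2_to_totalFe, ORP, pH) are
#' typed numeric when present and may contain missing values. Concentrations
#' must be non-negative and fractions within \[0, 1\].
#'
#' @param path Path to a TSV file.
#' @return Data frame, one row per sample.
#' @export
read_geochem <- function(path) {
  df <- read_table_schema(path, .geochem_schema)
  for (col in intersect(.geochem_numeric, names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  conc <- setdiff(intersect(.geochem_numeric, names(df)), c("ORP", "pH", "MeHg"))
  for (col in conc) {
    v <- df[[col]]
    if (any(v < 0, na.rm = TRUE))
      stop_domain("geochemistry column '%s' has negative concentrations", col)
  }
  if ("Fe2_to_totalFe" %in% names(df) &&
      any(df$Fe2_to_totalFe > 1, na.rm = TRUE)) {
    stop_domain("Fe2_to_totalFe must lie in [0, 1]")
  }
  df
}

#' Read sample metadata
#'
#' @param path Path to a TSV file with columns `sample_id`, `site`,
#'   `compartment`, `day`, `flooded`, `total_reads`.
#' @return Data frame, one row per sample.
#' @export
read_sample_meta <- function(path) {
  df <- read_table_schema(path, c(sample_id = "character", site = "character",
                                  compartment = "character", day = "integer",
                                  flooded = "logical", total_reads = "numeric"))
  if (anyDuplicated(df$sample_id))
    stop_schema("sample metadata has duplicated sample_id values")
  if (any(df$total_reads <= 0, na.rm = TRUE))
    stop_domain("total_reads must be positive for every sample")
  df
}

# --- lineages -----------------------------------------------------------

.lineage_ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Split a semicolon-delimited lineage into its seven ranks
#'
#' Accepts (and strips) GTDB-style rank prefixes (`d__`, `p__`, ...); missing
#' trailing ranks are empty strings.
#'
#' @param lineage Character vector of lineage strings.
#' @return Character matrix with one row per lineage and the seven canonical
#'   rank columns domain..species.
#' @export
parse_lineage <- function(lineage) {
  lineage <- as.character(lineage)
  lineage[is.na(lineage)] <- ""
  if (length(lineage) == 0L) {
    return(matrix(character(0), 0, 7, dimnames = list(NULL, .lineage_ranks)))
  }
  parts <- strsplit(lineage, ";", fixed = TRUE)
  m <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[dpcofgs]__", "", p)
    length(p) <- 7L
    p[is.na(p)] <- ""
    p
  }, character(7L)))
  colnames(m) <- .lineage_ranks
  m
}

#' Assemble candidate gene hits from parsed search results
#'
#' Joins an hmmsearch table with optional BLAST best-hit titles, lineages,
#' per-ORF coverages, and protein sequences into the hit table consumed by
#' [validate_all()] and [aggregate_guilds()].
#'
#' @param hmm Data frame from [read_hmm_table()].
#' @param gene_family Gene family label for all rows (e.g. `"mcrA"`).
#' @param sample_id Sample identifier, one value or one per row. When `NULL`,
#'   the sample is parsed from the ORF id prefix before the first `"|"`.
#' @param blast Optional data frame from [read_blast_table()].
#' @param lineage Optional data frame with columns `orf_id`, `lineage`.
#' @param coverage Optional data frame with columns `orf_id`, `coverage`.
#' @param proteins Optional named character vector from [read_fasta()].
#' @return A `gene_hits` data frame with columns `orf_id`, `sample_id`,
#'   `gene_family`, `hmm_score`, `hmm_evalue`, `hmm_length`, `protein_seq`,
#'   `blast_title`, `lineage`, `coverage`.
#' @export
assemble_gene_hits <- function(hmm, gene_family, sample_id = NULL, blast = NULL,
                               lineage = NULL, coverage = NULL, proteins = NULL) {
  n <- nrow(hmm)
  if (is.null(sample_id)) {
    sample_id <- sub("\\|.*$", "", hmm$orf_id)
  }
  hits <- data.frame(
    orf_id = hmm$orf_id,
    sample_id = rep_len(sample_id, n),
    gene_family = rep_len(gene_family, n),
    hmm_score = hmm$hmm_score,
    hmm_evalue = hmm$hmm_evalue,
    hmm_length = hmm$hmm_length,
    protein_seq = NA_character_,
    blast_title = NA_character_,
    lineage = NA_character_,
    coverage = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(blast)) {
    hits$blast_title <- blast$title[match(hits$orf_id, blast$orf_id)]
  }
  if (!is.null(lineage)) {
    hits$lineage <- lineage$lineage[match(hits$orf_id, lineage$orf_id)]
  }
  if (!is.null(coverage)) {
    hits$coverage <- coverage$coverage[match(hits$orf_id, coverage$orf_id)]
  }
  if (!is.null(proteins)) {
    hits$protein_seq <- unname(proteins[hits$orf_id])
  }
  gene_hits(hits)
}

#' Validate and class a gene-hit table
#'
#' @param hits Data frame with at least `orf_id`, `sample_id`, `gene_family`,
#'   `hmm_score`, `hmm_evalue`, `hmm_length`; optional `protein_seq`,
#'   `blast_title`, `lineage`, `coverage`.
#' @return The same data frame with class `gene_hits`, invariants checked.
#' @export
gene_hits <- function(hits) {
  req <- c("orf_id", "sample_id", "gene_family", "hmm_score", "hmm_evalue",
           "hmm_length")
  missing <- setdiff(req, names(hits))
  if (length(missing))
    stop_schema("gene hits table missing column(s): %s", paste(missing, collapse = ", "))
  for (opt in c("protein_seq", "blast_title", "lineage")) {
    if (!opt %in% names(hits)) hits[[opt]] <- NA_character_
  }
  if (!"coverage" %in% names(hits)) hits$coverage <- NA_real_
  if (nrow(hits)) {
    if (any(hits$hmm_evalue < 0)) stop_domain("hmm_evalue must be >= 0")
    if (any(hits$hmm_length <= 0)) stop_domain("hmm_length must be > 0")
    if (any(hits$coverage < 0, na.rm = TRUE)) stop_domain("coverage must be >= 0")
  }
  class(hits) <- c("gene_hits", "data.frame")
  hits
}
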