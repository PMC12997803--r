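rules <- load_validation_rules()

hit <- function(...) {
  defaults <- list(orf_id = "o1", sample_id = "s1", gene_family = "hgcA",
                   hmm_score = 300, hmm_evalue = 1e-20, hmm_length = 300,
                   protein_seq = NA_character_, blast_title = NA_character_,
                   lineage = NA_character_, coverage = 1)
  utils::modifyList(defaults, list(...))
}

test_that("motif matching is exact per position with character classes", {
  rule <- rules$hgcA
  expect_true(validate_motif(hit(protein_seq = "AAANVWCAAGKAAA"), rule))
  expect_true(validate_motif(hit(protein_seq = "AAANIWCAGGKAAA"), rule))
  # hamming-distance-1 violation of the A/G class at position 6
  expect_false(validate_motif(hit(protein_seq = "AAANVWCATGKAAA"), rule))
  expect_error(validate_motif(hit(protein_seq = NA_character_), rule),
               class = "paddyMeHg_data_error")
})

test_that("title keywords match case-insensitively as substrings", {
  expect_true(validate_title(
    hit(gene_family = "pmoA",
        blast_title = "particulate methane monooxygenase subunit A"),
    rules$pmoA))
  expect_true(validate_title(
    hit(gene_family = "mcrA",
        blast_title = "Methyl coenzyme M reductase alpha"),
    rules$mcrA))
  expect_false(validate_title(
    hit(gene_family = "mcrA", blast_title = "hypothetical protein"),
    rules$mcrA))
  expect_message(
    expect_false(validate_title(hit(gene_family = "mcrA"), rules$mcrA)),
    "no BLAST title")
})

test_that("taxon allow-lists match at the prefix's rank depth", {
  methano <- hit(gene_family = "pmoA",
                 lineage = "Bacteria;Proteobacteria;Gammaproteobacteria;Methylococcales;Methylomonadaceae;;")
  amoa <- hit(gene_family = "pmoA",
              lineage = "Bacteria;Proteobacteria;Gammaproteobacteria;Nitrosomonadales;Nitrosomonadaceae;Nitrosomonas;")
  expect_true(validate_taxon(methano, rules$pmoA))
  expect_false(validate_taxon(amoa, rules$pmoA))
  # demethylating-genus allow-list for mbnT
  expect_true(validate_taxon(
    hit(gene_family = "mbnT", lineage = "Bacteria;;;;Methylocystaceae;Methylocystis;"),
    rules$mbnT))
  expect_false(validate_taxon(hit(gene_family = "mbnT", lineage = ""), rules$mbnT))
})

test_that("validate_all recovers exactly the truth-positive set on labeled data", {
  cfg <- sim_config(seed = 21, preset = "small", n_true_seqs = 15, n_decoy_seqs = 15)
  fx <- make_search_fixtures(cfg = cfg)
  hits <- sim_gene_hits(fx)
  val <- validate_all(hits, rules)
  truth_pos <- fx$truth$orf_id[fx$truth$label == "true"]
  expect_setequal(val$retained$orf_id, truth_pos)
  # reason codes equal the designated failure stage
  m <- merge(val$rejected, fx$truth, by = "orf_id")
  expect_identical(m$reason, m$fail_stage)
  # partition
  expect_identical(sort(c(val$retained$orf_id, val$rejected$orf_id)),
                   sort(hits$orf_id))
  # idempotence and input-order insensitivity
  again <- validate_all(val$retained, rules)
  expect_setequal(again$retained$orf_id, truth_pos)
  expect_identical(nrow(again$rejected), 0L)
  shuf <- hits[rev(seq_len(nrow(hits))), ]
  expect_setequal(validate_all(gene_hits(shuf), rules)$retained$orf_id, truth_pos)
})

test_that("criteria are applied in order score/evalue -> title -> taxon -> motif", {
  # fails both the score gate and the taxon gate: reason must be the cheaper one
  bad <- gene_hits(as.data.frame(hit(gene_family = "mbnT", hmm_score = 100,
                                     lineage = "Bacteria;;;;;Xanthomonas;")))
  expect_identical(validate_all(bad, rules)$rejected$reason, "score")
})

test_that("mbn cluster typing reproduces the reference genome classes", {
  profiles <- profile_mbn(list(
    OB3b = c("mbnA", "mbnB", "mbnC", "mbnD", "mbnE", "mbnM", "mbnN", "mbnT"),
    BG8 = "mbnT",
    Rockwell = "mbnT",
    Bath = character()))
  expect_identical(profiles$class,
                   c("producer", "uptake_only", "uptake_only", "none"))
})

test_that("mbn class is monotone under adding genes, overrides work", {
  # pseudogene override completes the biosynthesis core
  p <- profile_mbn(list(g = c("mbnA", "mbnC", "mbnT")),
                   overrides = list(g = "mbnB"))
  expect_identical(p$class, "producer")
  expect_identical(profile_mbn(list(g = character()))$class, "none")
  expect_identical(profile_mbn(list(g = "mbnT"))$class, "uptake_only")
  expect_identical(profile_mbn(list(g = c("mbnT", "mbnA", "mbnB", "mbnC")))$class,
                   "producer")
  expect_error(profile_mbn(list(g = "mbnZ")), "unknown",
               class = "paddyMeHg_config_error")
})
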