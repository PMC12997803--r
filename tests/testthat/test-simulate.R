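test_that("marker-protein generation is label-exact and byte-reproducible", {
  cfg <- sim_config(seed = 5, n_true_seqs = 10, n_decoy_seqs = 10)
  mp <- make_marker_proteins(cfg)
  expect_identical(nrow(mp$truth), 60L)  # 3 families x 20
  # exactly the true hgcA sequences match the cap-helix motif
  hg <- mp$truth[mp$truth$gene_family == "hgcA", ]
  match_motif <- vapply(mp$sequences[hg$orf_id], grepl,
                        pattern = "N[VI]WCA[AG]GK", TRUE)
  expect_identical(unname(match_motif), hg$label == "true")
  # byte-identical regeneration under the same seed
  mp2 <- make_marker_proteins(cfg)
  expect_identical(mp$sequences, mp2$sequences)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(mp$sequences, f1); write_fasta(mp2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a fifth or more of decoys carry hamming-distance-1 near-motifs", {
  cfg <- sim_config(seed = 5, n_true_seqs = 5, n_decoy_seqs = 20)
  mp <- make_marker_proteins(cfg, families = "hgcA")
  decoys <- mp$sequences[mp$truth$orf_id[mp$truth$label == "decoy"]]
  # enumerate all single-position corruptions of the motif classes
  tokens <- c("N", "[VI]", "W", "C", "A", "[AG]", "G", "K")
  class_chars <- lapply(tokens, function(t) {
    if (startsWith(t, "[")) strsplit(substr(t, 2, nchar(t) - 1), "")[[1]] else t
  })
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  near_patterns <- unlist(lapply(seq_along(tokens), function(i) {
    bad <- setdiff(aa, class_chars[[i]])
    vapply(bad, function(b) {
      toks <- tokens; toks[i] <- b; paste(toks, collapse = "")
    }, "")
  }))
  has_near <- vapply(decoys, function(s)
    any(vapply(near_patterns, grepl, TRUE, x = s)), TRUE)
  expect_gte(mean(has_near), 0.2)
})

test_that("search fixtures encode their designated failure stages", {
  cfg <- sim_config(seed = 8, preset = "small", n_amoa = 2)
  fx <- make_search_fixtures(cfg = cfg)
  # exactly 2 pmoA confounders with non-methanotroph lineage
  pmoa_decoys <- fx$truth$orf_id[fx$truth$gene_family == "pmoA" &
                                   fx$truth$label == "decoy"]
  expect_identical(length(pmoa_decoys), 2L)
  lin <- fx$lineage$lineage[match(pmoa_decoys, fx$lineage$orf_id)]
  expect_true(all(grepl("Nitrosomonadaceae", lin)))
  # every true McrA row is titled with the identifying keyword
  mcra_true <- fx$truth$orf_id[fx$truth$gene_family == "mcrA" &
                                 fx$truth$label == "true"]
  titles <- fx$blast$title[match(mcra_true, fx$blast$orf_id)]
  expect_true(all(grepl("methyl coenzyme M reductase", titles)))
  # dsrA decoys sit below the 392.9 bit-score cutoff
  dsra_decoy <- fx$hmm[fx$hmm$hmm_name == "dsrA" &
                         grepl("decoy", fx$hmm$orf_id), ]
  expect_true(all(dsra_decoy$hmm_score < 392.9))
  # seeded reproducibility
  fx2 <- make_search_fixtures(cfg = cfg)
  expect_identical(fx$hmm, fx2$hmm)
  expect_identical(fx$blast, fx2$blast)
})

test_that("written fixtures round-trip through the io readers", {
  cfg <- sim_config(seed = 8, preset = "small")
  fx <- make_search_fixtures(cfg = cfg)
  d <- withr::local_tempdir()
  paths <- write_search_fixtures(fx, d)
  hmm <- read_hmm_table(paths[["hmm"]])
  expect_identical(hmm$orf_id, fx$hmm$orf_id)
  expect_equal(hmm$hmm_score, fx$hmm$hmm_score, tolerance = 1e-4)
  blast <- read_blast_table(paths[["blast"]])
  expect_identical(blast$title, fx$blast$title)
  prot <- read_fasta(paths[["fasta"]])
  expect_identical(unname(prot), unname(fx$sequences))
})

test_that("panel generative model reduces to site offsets when effects vanish", {
  cfg <- sim_config(seed = 4, beta_F1 = 0, beta_methanogen = 0,
                    beta_interaction = 0, beta_hgca = 0, noise_sd = 0,
                    compartment_offset = 0)
  p <- make_panel(cfg)
  expected <- cfg$mehg_baseline + cfg$site_offsets[p$meta$site]
  expect_equal(unname(p$geochem$MeHg), unname(expected), tolerance = 1e-12)
  # seeded reproducibility
  p2 <- make_panel(cfg)
  expect_identical(p$geochem, p2$geochem)
  expect_identical(p$guilds, p2$guilds)
})

test_that("methanogen and methanotroph series are positively coupled", {
  pos <- vapply(1:100, function(s) {
    p <- make_panel(sim_config(seed = s))
    stats::cor(log(p$guilds$methanogen), log(p$guilds$methanotroph)) > 0
  }, TRUE)
  expect_gte(mean(pos), 0.95)
})

test_that("lagged series equal delayed target copies when noise is zero", {
  cfg <- sim_config(seed = 12, lag_noise_sd = 0, neg_sign_prob = 0,
                    lag_delays = 1L, n_lagged = 1L)
  lg <- make_lagged_series(cfg)
  nt <- cfg$n_timepoints
  expect_identical(lg$series[2:nt, 1], lg$target[1:(nt - 1)])
  expect_identical(lg$truth$delay[1], 1L)
  expect_identical(lg$truth$label, c("lagged", rep("null", 10)))
  expect_identical(make_lagged_series(cfg)$series, lg$series)
})
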