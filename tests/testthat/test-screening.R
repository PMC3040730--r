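test_that("fragment extraction keeps only stop-terminated stretches", {
  fr <- extract_fragments("MAAC.KKC.GG")
  expect_identical(fr$seq, c("MAAC.", "KKC."))
  expect_identical(fr$aa_start, c(1L, 6L))
  expect_identical(fr$aa_end, c(5L, 9L))
  # empty fragments between consecutive stops are dropped
  expect_identical(nrow(extract_fragments("...")), 0L)
  # no stop at all: everything is rejected as partially identified
  expect_identical(nrow(extract_fragments("MAAC")), 0L)
  expect_identical(nrow(extract_fragments("MAACDEF.KK", min_len = 5)), 1L)
  # fragment partition: accepted fragments + trailing run tile the frame
  set.seed(19)
  for (i in 1:40) {
    ch <- sample(c("A", "C", "K", "."), sample(5:60, 1), replace = TRUE,
                 prob = c(4, 2, 2, 1))
    s <- paste(ch, collapse = "")
    fr <- extract_fragments(s)
    if (nrow(fr) > 0) {
      expect_false(any(grepl("\\..", fr$seq)))  # no internal stops
      expect_true(all(endsWith(fr$seq, ".")))
      expect_identical(fr$seq, substring(s, fr$aa_start, fr$aa_end))
    }
  }
})

test_that("scan_record finds a planted precursor in its frame only", {
  tp <- tiny_planted_bank(seed = 21)
  hits <- scan_record(as.character(tp$bank[["planted"]]), id = "planted",
                      min_len = 30)
  m1 <- hits[hits$motif_id == "motif 1", ]
  expect_gte(nrow(m1), 1L)
  expect_true(all(m1$frame == tp$frame))
  expect_true(any(grepl(tp$mature, m1$fragment_seq, fixed = TRUE)))
  # nt coordinates are consistent with aa_to_nt
  L <- S4Vectors::width(tp$bank)[1]
  expect_identical(m1$nt_start[1],
                   min(aa_to_nt(m1$aa_start[1], m1$frame[1], L),
                       aa_to_nt(m1$aa_end[1], m1$frame[1], L)))
})

test_that("a motif split by an internal stop is never reported", {
  set.seed(33)
  reg <- default_registry()
  mature <- sample_mature_for_motif(reg$motifs[["motif 1"]])
  cpos <- which(strsplit(mature, "")[[1]] == "C")
  broken <- paste0(substr(mature, 1, cpos[3]), ".",
                   substring(mature, cpos[3] + 1))
  frame_seq <- paste0("AAA", broken, ".")
  frags <- extract_fragments(frame_seq)
  pats <- srda_convert(frags$seq, key_spec("C."))
  expect_false(any(match_motif(reg$motifs[["motif 1"]], pats)$matched))
  # the same peptide without the stop matches
  intact <- srda_convert(paste0("AAA", mature, "."), key_spec("C."))
  expect_true(match_motif(reg$motifs[["motif 1"]], intact)$matched)
})

test_that("bank scans are deterministic and honor the manifest", {
  gen <- generate_bank(generator_config(
    n_noise = 40, planted_per_motif = c("motif 1" = 3, "motif 2" = 3),
    n_decoy_split = 4, n_decoy_nosignal = 4, seed = 27))
  s1 <- scan_bank(gen$bank, min_len = 30)
  s2 <- scan_bank(gen$bank, min_len = 30)
  expect_identical(s1$hits, s2$hits)
  pl <- gen$manifest[gen$manifest$class == "planted", ]
  key <- paste(s1$hits$record_id, s1$hits$motif_id)
  expect_true(all(paste(pl$record_id, pl$motif_id) %in% key))
  # planted hits are reported in the planted frame
  for (i in seq_len(nrow(pl))) {
    h <- s1$hits[s1$hits$record_id == pl$record_id[i] &
                 s1$hits$motif_id == pl$motif_id[i], ]
    expect_true(pl$frame[i] %in% h$frame)
  }
  # a record with no C and no K yields no hits
  noc <- scan_bank(Biostrings::DNAStringSet(c(x = strrep("GGAGAT", 30))),
                   min_len = 0)
  expect_identical(nrow(noc$hits), 0L)
})

test_that("protein-mode scanning strips stops and agrees with EST mode", {
  reg <- default_registry()
  set.seed(41)
  mature <- sample_mature_for_motif(reg$motifs[["motif 2"]])
  hits <- scan_protein_set(c(tox = mature), reg)
  expect_true("motif 2" %in% hits$motif_id)
  expect_error(scan_protein_set(c(bad = "ACD.E"), reg), "EST")
  # agreement: protein-mode match iff EST-mode match on the stop-appended seq
  for (i in 1:25) {
    s <- random_aa_seq(enrich_c = TRUE)
    pro <- scan_protein_set(stats::setNames(s, "s"), reg)
    pat <- srda_convert(paste0(s, "."), key_spec("C."))
    for (q in Filter(function(m) m$enabled && m$type == "line",
                     reg$motifs)) {
      est_hit <- match_motif(q, pat)$matched
      pro_hit <- q$id %in% pro$motif_id
      if (est_hit) expect_true(pro_hit)
    }
  }
})

test_that("stage reports count a record once per motif", {
  hits <- data.frame(
    record_id = c("a", "a", "b"), frame = c(1L, 2L, 1L),
    motif_id = rep("motif 1", 3), aa_start = 1L, aa_end = 5L,
    nt_start = 1L, nt_end = 15L, fragment_seq = "MAAC.", pattern = "3C.",
    stringsAsFactors = FALSE)
  rep1 <- stage_report(default_registry(), hits)
  expect_identical(rep1$retrieved[rep1$motif_id == "motif 1"], 2L)
  expect_true(all(is.na(rep1$signal_approved)))
})
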