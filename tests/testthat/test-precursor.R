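test_that("signal heuristic accepts a hydrophobic core with an A-x-A site", {
  frag <- paste0("M", strrep("L", 12), "ASA", "DDEEQNGSDDE", ".")
  sig <- signal_from(frag)
  expect_true(sig$accepted)
  expect_identical(sig$met_pos, 1L)
  expect_identical(sig$cleavage_after, 16L)  # after the second A of ASA
  # acidic "core": score stays below threshold
  bad <- signal_from(paste0("M", strrep("D", 20), "ASAKRGG", "."))
  expect_false(bad$accepted)
  # no Met within limitMet: no-call
  expect_null(signal_from(paste0(strrep("A", 35), "MLLLLLLLL.")))
  # format selectors mirror the historical spreadsheet interface
  expect_identical(signal_from(frag, format = 1), 1L)
  expect_identical(signal_from(frag, format = 3), 16L)
  expect_identical(signal_from(frag, format = 9), sig$score)
  expect_identical(signal_from(frag, format = 1,
                               frame = 1, record_length = 300), 1L)
})

test_that("signal scoring is an exhaustive arg-max over Met and cleavage", {
  # independent oracle: enumerate every (met, window, cleavage) combination
  oracle <- function(seq, p = signal_params()) {
    seq <- sub("\\.$", "", seq)
    ch <- strsplit(seq, "")[[1]]
    kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
            E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
            M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
            Y = -1.3, V = 4.2, X = 0)
    best <- NULL
    for (m in which(ch == "M")) {
      if (m > p$limitMet) next
      core <- -Inf
      for (o in p$core_span[1]:p$core_span[2]) {
        s <- m + o - 1L
        if (s + p$core_window - 1L > length(ch)) next
        core <- max(core, sum(kd[ch[s:(s + p$core_window - 1L)]]))
      }
      ind <- -1; cl <- NA_integer_
      for (o in p$cleave_span[1]:p$cleave_span[2]) {
        cpos <- m + o - 1L
        if (cpos >= length(ch) || cpos - 2L <= m) next
        v <- (ch[cpos] %in% p$small_set) / 2 +
             (ch[cpos - 2L] %in% p$small_set) / 2
        if (v > ind) { ind <- v; cl <- cpos }
      }
      if (ind < 0) { ind <- 0; cl <- NA_integer_ }
      sc <- p$w_hydro * core + p$w_cleave * ind
      if (is.null(best) || sc > best$score) {
        best <- list(met = m, cl = cl, score = sc)
      }
    }
    best
  }
  set.seed(43)
  for (i in 1:60) {
    seq <- paste0(random_aa_seq(sample(40:90, 1)), ".")
    got <- signal_from(seq)
    want <- oracle(seq)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_identical(got$met_pos, want$met)
      expect_identical(got$cleavage_after, want$cl)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("mature_chain stops at the first downstream terminator", {
  mc <- mature_chain("MAACD.", 4)
  expect_identical(mc$seq, "CD")
  expect_identical(mc$end, 5L)
  expect_identical(mature_chain("MAACD.", 1)$seq, "MAACD")
  expect_error(mature_chain("MAACD", 2), "partially identified")
})

test_that("mature-start prediction applies dibasic and E..R rules", {
  expect_identical(predict_mature_start("EAKRGVCC"), 5L)  # dibasic KR
  expect_identical(predict_mature_start("EAGRSVCC"), 5L)  # R with E at -3
  expect_identical(predict_mature_start("GGGGCC"), 1L)    # fallback
  expect_identical(predict_mature_start("AKKG"), 4L)      # dibasic KK
  # nearest site to the signal cleavage wins
  expect_identical(predict_mature_start("KRAAKRCC"), 3L)
})

test_that("SignalP short output parses and overrides the heuristic", {
  f <- withr::local_tempfile()
  writeLines(c(
    "# SignalP-4.1 euk predictions",
    "frag1  0.83  17  0.85  17  0.91  12  0.78  0.82  Y  0.45  SignalP-noTM",
    "frag2  0.11  22  0.10  22  0.12  11  0.09  0.10  N  0.45  SignalP-noTM"),
    f)
  sp <- load_signalp_output(f)
  expect_identical(length(sp), 2L)
  expect_true(sp[["frag1"]]$accepted)
  expect_identical(sp[["frag1"]]$cleavage_after, 16L)
  expect_false(sp[["frag2"]]$accepted)
  empty <- withr::local_tempfile()
  writeLines("# nothing", empty)
  expect_identical(load_signalp_output(empty), list())
  bad <- withr::local_tempfile()
  writeLines("frag3 not a number", bad)
  expect_error(load_signalp_output(bad), "line 1")
})

test_that("dedup collapses identical mature domains, first seen wins", {
  calls <- data.frame(
    record_id = c("r1", "r2", "r3"),
    mature_seq = c("GCKC", "GCKC", "ACDC"),
    signal_seq = c("MLLA", "MVVA", "MIIA"),
    stringsAsFactors = FALSE)
  dd <- dedup_matures(calls)
  expect_identical(nrow(dd), 2L)
  expect_identical(dd$record_id, c("r1", "r3"))
  expect_identical(dd$multiplicity, c(2L, 1L))
  empty <- calls[0, ]
  expect_identical(nrow(dedup_matures(empty)), 0L)
})

test_that("precursor calling reconstructs and filters hits", {
  gen <- generate_bank(generator_config(
    n_noise = 30, planted_per_motif = c("motif 1" = 4, "motif 3" = 4),
    n_decoy_split = 3, n_decoy_nosignal = 6, seed = 37))
  scan <- scan_bank(gen$bank, min_len = 30)
  out <- call_precursors(scan$hits)
  # signal + propeptide + mature reconstitute the fragment
  for (i in seq_len(nrow(out$all_calls))) {
    cl <- out$all_calls[i, ]
    h <- scan$hits[scan$hits$record_id == cl$record_id &
                   scan$hits$frame == cl$frame &
                   scan$hits$motif_id == cl$motif_id &
                   scan$hits$aa_start == cl$aa_start, ][1, ]
    frag <- sub("\\.$", "", h$fragment_seq)
    expect_identical(paste0(cl$signal_seq, cl$propeptide_seq, cl$mature_seq),
                     substring(frag, cl$met_pos))
  }
  # signal-less decoys never survive the signal stage
  nosig <- gen$manifest$record_id[gen$manifest$class == "decoy_nosignal"]
  expect_false(any(out$all_calls$record_id %in% nosig))
  # planted mature domains are recovered exactly
  pl <- gen$manifest[gen$manifest$class == "planted", ]
  idx <- match(paste(pl$record_id, pl$motif_id),
               paste(out$all_calls$record_id, out$all_calls$motif_id))
  expect_false(anyNA(idx))
  expect_identical(out$all_calls$mature_seq[idx], pl$mature_seq)
  # empty input gives an all-zero report
  zero <- call_precursors(scan$hits[0, ])
  expect_identical(nrow(zero$calls), 0L)
  expect_true(all(zero$report$retrieved == 0L))
})

test_that("per-motif stage counts never increase along the pipeline", {
  gen <- generate_bank(generator_config(
    n_noise = 50, planted_per_motif = c("motif 2" = 3, "motif 4" = 3),
    n_decoy_split = 3, n_decoy_nosignal = 3, seed = 53))
  res <- run_pipeline(gen$bank, min_len = 30)
  expect_true(all(res$report$retrieved >= res$report$signal_approved))
  expect_true(all(res$report$signal_approved >= res$report$deduplicated))
})
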