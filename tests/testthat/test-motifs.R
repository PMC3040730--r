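test_that("motif parsing validates the wildcard grammar", {
  m <- parse_motif("C1C##C6C#CC", id = "motif 1")
  expect_identical(m$type, "line")
  expect_identical(m$line, "C1C##C6C#CC")
  expect_error(parse_motif("C**C"), "doubled gap")
  expect_error(parse_motif("C1c"), "illegal character 'c'")
  k <- parse_motif("K > = 6 AND C < = 2", id = "motif K")
  expect_identical(k$type, "compound")
  expect_identical(k$predicates[[1]],
                   list(residue = "K", op = ">=", threshold = 6L))
  expect_identical(k$predicates[[2]],
                   list(residue = "C", op = "<=", threshold = 2L))
})

test_that("line matching has substring VBA-Like semantics", {
  expect_true(match_motif("###.", "175.")$matched)
  m <- match_motif("C1C##C6C#CC", "22C1C13C6C2CC7.")
  expect_true(m$matched)
  expect_identical(c(m$start, m$end), c(3L, 13L))
  expect_false(match_motif("C1C##C6C#CC", "22C1C5C6C2CC7.")$matched)
  expect_false(match_motif("CC", "1C2C3.")$matched)
  # '*' can span zero characters
  expect_true(match_motif("C*C", "CC")$matched)
  expect_true(match_motif("C8C#C*C3C#C.", "12C8C1C7C3C2C.")$matched)
})

test_that("matching agrees with the regex oracle on random pairs", {
  set.seed(17)
  n <- 2000
  for (i in seq_len(n)) {
    line <- random_motif_line()
    pat <- srda_convert(paste0(random_aa_seq(), "."), key_spec("C."))
    got <- match_motif(line, pat)
    want <- oracle_match(line, pat)
    expect_identical(got$matched, want)
    if (want) expect_identical(got$start, oracle_start(line, pat))
  }
})

test_that("wildcard substitution is monotone: '#' and '*' only widen", {
  set.seed(23)
  for (i in 1:200) {
    line <- random_motif_line()
    pat <- srda_convert(paste0(random_aa_seq(enrich_c = TRUE), "."),
                        key_spec("C."))
    if (!match_motif(line, pat)$matched) next
    ch <- strsplit(line, "")[[1]]
    dig <- which(ch %in% as.character(0:9))
    if (length(dig) > 0) {
      ch[dig[sample.int(length(dig), 1)]] <- "#"
      expect_true(match_motif(paste(ch, collapse = ""), pat)$matched)
    }
    ch2 <- strsplit(line, "")[[1]]
    j <- sample(length(ch2), 1)
    ch2[j] <- "*"
    gen <- gsub("\\*{2,}", "*", paste(ch2, collapse = ""))
    expect_true(match_motif(gen, pat)$matched)
  }
})

test_that("compound motif K applies residue-count thresholds with AND", {
  k <- parse_motif("K>=6 AND C<=2", id = "motif K")
  expect_true(match_compound(k, "MKKKKAKKCAD.")$matched)   # 7 K, 1 C
  expect_true(match_compound(k, "KKKKKKCC.")$matched)      # boundary: 6 K, 2 C
  expect_false(match_compound(k, "KKKKKA.")$matched)       # 5 K
  expect_false(match_compound(k, "KKKKKKCCC.")$matched)    # 3 C
})

test_that("stop stripping produces the protein-mode motif variant", {
  expect_identical(strip_stops(parse_motif("C1C##C9C#CC#."))$line,
                   "C1C##C9C#CC#")
  expect_identical(strip_stops(parse_motif("###."))$line, "###")
  q <- parse_motif("C6C*C*C*C6C#.")
  expect_identical(strip_stops(strip_stops(q))$line, strip_stops(q)$line)
  k <- parse_motif("K>=6 AND C<=2")
  expect_identical(strip_stops(k), k)
})

test_that("the shipped registry matches the published screening lines", {
  expected <- c(
    "motif 1"  = "C1C##C6C#CC",
    "motif 2"  = "C1C##C9C#CC#.",
    "motif 3"  = "C8C#C*C3C#C.",
    "motif 4"  = "C8C*C#C*C3C",
    "motif 5"  = "C8C#C*C1C#C#.",
    "motif 6"  = "CC#C#CC*C1C*C.",
    "motif 7"  = "CC1C*C*C*C*C1C#.",
    "motif 8"  = "CC1C#C5C*C#.",
    "motif 9"  = "C6C*C*C*C6C#.",
    "motif 10" = "C8C3C#C.",
    "motif 11" = "C#C#C#C#C#C#C#C#.",
    "motif 12" = "C6C#C#C1C*C1C",
    "motif 13" = "C#C#C#C#.",
    "motif 0"  = "###.",
    "motif 14" = "##C")
  reg <- default_registry()
  for (id in names(expected)) {
    expect_identical(reg$motifs[[id]]$line, unname(expected[id]))
  }
  # degenerate cytolysin lines ship disabled; compound motif K replaces them
  expect_false(reg$motifs[["motif 0"]]$enabled)
  expect_false(reg$motifs[["motif 14"]]$enabled)
  expect_true(reg$motifs[["motif K"]]$enabled)
  expect_identical(reg$motifs[["motif K"]]$type, "compound")
  expect_identical(length(reg$motifs), 16L)
})

test_that("pattern generalization derives consensus screening lines", {
  expect_identical(generalize_patterns(c("C1C12C6C2CC", "C1C13C6C3CC")),
                   "C1C##C6C#CC")
  expect_identical(generalize_patterns(c("3C.", "3C.")), "3C.")
  expect_identical(generalize_patterns(c("C5C", "C12C")), "C*C")
  # order independence
  expect_identical(generalize_patterns(c("C1C13C6C3CC", "C1C12C6C2CC")),
                   "C1C##C6C#CC")
  expect_error(generalize_patterns(character(0)), "at least one")
  # the consensus matches everything it was derived from
  set.seed(31)
  for (i in 1:30) {
    pats <- vapply(1:3, function(j)
      srda_convert(paste0(random_aa_seq(enrich_c = TRUE), "."),
                   key_spec("C.")), "")
    cons <- generalize_patterns(pats)
    for (p in pats) expect_true(match_motif(cons, p)$matched)
  }
})

test_that("specificity evaluation tabulates per-motif retrieval", {
  reg <- motif_registry(list(parse_motif("CC#C", id = "m")))
  seqs <- c(t1 = "ACCACAC", t2 = "CCAC", o1 = "ACACA", o2 = "ACAAAC")
  groups <- c("anemone", "anemone", "other", "other")
  res <- evaluate_specificity(reg, seqs, groups, target = "anemone")
  row <- res[res$motif_id == "m", ]
  expect_identical(row$total, 2L)      # t1 ("1CC1C1C"), t2 ("CC1C")
  expect_identical(row$target, 2L)
  expect_identical(row$specificity_pct, 100)
  expect_identical(res$total[res$motif_id == "distinct"], 2L)
})
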