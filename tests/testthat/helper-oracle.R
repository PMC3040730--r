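# Independent brute-force oracle for screening-line matching: compile the
# motif token-by-token into a regular expression and search with the regex
# engine. Deliberately shares no code with the package matcher.
motif_to_regex <- function(line) {
  ch <- strsplit(line, "")[[1]]
  parts <- vapply(ch, function(c) {
    switch(c,
           "?" = ".",
           "#" = "[0-9]",
           "*" = ".*",
           "." = "\\.",
           c)
  }, "", USE.NAMES = FALSE)
  paste(parts, collapse = "")
}

oracle_match <- function(line, text) {
  grepl(motif_to_regex(line), text, perl = TRUE)
}

oracle_start <- function(line, text) {
  m <- regexpr(motif_to_regex(line), text, perl = TRUE)
  if (m == -1L) NA_integer_ else as.integer(m)
}

# Random screening line over the registry grammar: key letters alternating
# with spacer elements (literal counts, '#' runs, '?', '*'), optional
# terminal '.'.
random_motif_line <- function() {
  n_keys <- sample(2:6, 1)
  spacers <- c("#", "##", "?", "*", as.character(sample(1:12, 3)))
  parts <- character(0)
  for (i in seq_len(n_keys)) {
    parts <- c(parts, "C")
    if (i < n_keys && runif(1) < 0.8) {
      parts <- c(parts, sample(spacers, 1))
    }
  }
  if (runif(1) < 0.4) {
    parts <- c(parts, sample(c("#", as.character(sample(1:9, 1))), 1), ".")
  }
  line <- paste(parts, collapse = "")
  gsub("\\*{2,}", "*", line)
}

# Random amino acid sequence; about half the draws are cysteine-enriched so
# motif matches actually occur.
random_aa_seq <- function(len = sample(20:120, 1), enrich_c = NA) {
  if (is.na(enrich_c)) enrich_c <- runif(1) < 0.5
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  w <- rep(1, 20)
  if (enrich_c) w[alpha == "C"] <- 8
  paste(sample(alpha, len, replace = TRUE, prob = w), collapse = "")
}

random_dna_seq <- function(len = sample(30:300, 1)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A tiny in-memory bank with one planted motif-1 precursor.
tiny_planted_bank <- function(seed = 5L, motif = "motif 1") {
  set.seed(seed)
  reg <- default_registry()
  mature <- sample_mature_for_motif(reg$motifs[[motif]])
  pc <- build_precursor(mature)
  emb <- embed_as_est(pc$precursor, frame = 2L, strand = "+")
  bank <- Biostrings::DNAStringSet(c(planted = emb$seq,
                                     noise1 = random_dna_seq(300),
                                     noise2 = random_dna_seq(300)))
  list(bank = bank, mature = mature, precursor = pc, frame = emb$frame)
}
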