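# Residue alphabets for synthetic sequence construction. Non-key positions
# of mature domains avoid C (the key residue of the shipped registry) and M
# (so the planted initiator Met stays the best signal candidate).
.NONKEY_AA <- setdiff(.AA20, c("C", "M"))
# A is excluded from the signal core: as a -3/-1-class small residue it
# could fabricate a competing cleavage candidate one position early.
.HYDROPHOBIC <- c("L", "V", "I", "F")
.ACIDIC <- c("D", "E", "N", "Q", "G", "S")

# Codons of the standard genetic code, grouped by amino acid; stops under ".".
.codon_table <- function() {
  gc <- Biostrings::getGeneticCode("1")
  aa <- chartr("*", ".", unname(gc))
  split(names(gc), aa)
}

#' Sample a mature-domain sequence instantiating a screening line
#'
#' Inverts the matching relation: literal digits stay, each `'#'` becomes a
#' random digit (no leading zero in a count), `'*'` becomes a short random
#' run of alternating counts and key letters, and every Count token is then
#' expanded into that many random non-key residues. The result's SRDA
#' pattern is checked to match the motif before returning.
#'
#' @param q A line [parse_motif()] object or screening-line text.
#' @param max_gap_tokens Upper bound on tokens instantiating one `'*'`.
#' @param spec [key_spec()] the motif is written for.
#' @return An amino acid string whose `srda_convert()` pattern matches `q`.
#'   Motifs ending in `'.'` describe the fragment end: the returned peptide
#'   excludes that terminal stop.
#' @examples
#' set.seed(1)
#' pep <- sample_mature_for_motif("C1C##C6C#CC")
#' match_motif("C1C##C6C#CC", srda_convert(pep, key_spec("C.")))$matched
#' @export
sample_mature_for_motif <- function(q, max_gap_tokens = 3L,
                                    spec = key_spec("C.")) {
  if (is.character(q)) q <- parse_motif(q)
  stopifnot(inherits(q, "srda_motif"))
  if (q$type != "line") {
    stop("sample_mature_for_motif requires a line motif", call. = FALSE)
  }
  key_letters <- unique(strsplit(gsub("[^A-Z]", "", q$line), "")[[1]])
  key <- if (length(key_letters) > 0L) key_letters[1] else "C"
  for (attempt in 1:50) {
    toks <- .instantiate_line(q$line, key, max_gap_tokens)
    pep <- .tokens_to_seq(toks, spec)
    pat <- srda_convert(paste0(pep, "."), spec)
    if (match_motif(q, pat)$matched) return(pep)
  }
  stop("could not instantiate motif '", q$id, "' within the length bound",
       call. = FALSE)
}

# Expand a screening line into concrete pattern tokens (counts, keys, '.').
.instantiate_line <- function(line, key, max_gap_tokens) {
  m <- gregexpr("[0-9#]+|[^0-9#]", line)[[1]]
  raw <- regmatches(line, list(m))[[1]]
  toks <- character(0)
  for (t in raw) {
    if (grepl("^[0-9#]+$", t)) {
      # a count template: literal digits fixed, '#' random, no leading zero
      digs <- strsplit(t, "")[[1]]
      for (i in seq_along(digs)) {
        if (digs[i] == "#") {
          digs[i] <- as.character(
            if (i == 1L && length(digs) > 1L) sample(1:9, 1)
            else if (i == 1L) sample(1:9, 1)
            else sample(0:9, 1))
        }
      }
      if (digs[1] == "0") digs[1] <- as.character(sample(1:9, 1))
      toks <- c(toks, paste(digs, collapse = ""))
    } else if (t == "*") {
      n <- sample(0:max_gap_tokens, 1)
      if (n > 0L) {
        # alternate count / key starting at random phase
        start_key <- sample(c(TRUE, FALSE), 1)
        for (j in seq_len(n)) {
          is_key <- xor(start_key, j %% 2L == 0L)
          toks <- c(toks, if (is_key) key else as.character(sample(1:9, 1)))
        }
      }
    } else if (t == "?") {
      toks <- c(toks, if (stats::runif(1) < 0.5) key
                else as.character(sample(1:9, 1)))
    } else {
      toks <- c(toks, t)  # key letter or '.'
    }
  }
  # merge adjacent count tokens produced by '*' instantiation
  out <- character(0)
  for (t in toks) {
    if (length(out) > 0L && grepl("^[0-9]+$", t) &&
        grepl("^[0-9]+$", out[length(out)])) {
      out[length(out)] <- paste0(out[length(out)], t)
    } else {
      out <- c(out, t)
    }
  }
  out
}

# Expand pattern tokens into a concrete peptide (terminal '.' dropped).
.tokens_to_seq <- function(toks, spec) {
  nonkey <- setdiff(.NONKEY_AA, spec$keys)
  parts <- vapply(toks, function(t) {
    if (grepl("^[0-9]+$", t)) {
      paste(sample(nonkey, as.integer(t), replace = TRUE), collapse = "")
    } else if (t == ".") {
      ""
    } else {
      t
    }
  }, "", USE.NAMES = FALSE)
  paste(parts, collapse = "")
}

#' Assemble a full precursor around a mature domain
#'
#' Emulates the canonical secreted-precursor architecture: initiator Met,
#' hydrophobic signal peptide ending in an A-x-A signal-peptidase site,
#' then a short acidic propeptide terminated by a dibasic KR processing
#' site, then the mature domain. The construction satisfies the default
#' [signal_params()] heuristic and [predict_mature_start()] by design.
#'
#' @param mature Mature-domain amino acid string.
#' @param prop_len Propeptide body length (acidic residues before `KR`).
#' @return A list: `precursor`, `signal_end` (last signal residue),
#'   `mature_start` (first mature residue), `mature`.
#' @examples
#' set.seed(1)
#' p <- build_precursor("GCKCDDGYCC")
#' substr(p$precursor, 1, p$signal_end)
#' @export
build_precursor <- function(mature, prop_len = sample(3:7, 1)) {
  stopifnot(nchar(mature) > 0L)
  signal <- paste0("M",
                   paste(sample(.HYDROPHOBIC, 12, replace = TRUE),
                         collapse = ""),
                   "ASA")
  prop <- paste0(paste(sample(.ACIDIC, prop_len, replace = TRUE),
                       collapse = ""), "KR")
  precursor <- paste0(signal, prop, mature)
  list(precursor = precursor,
       signal_end = nchar(signal),
       mature_start = nchar(signal) + nchar(prop) + 1L,
       mature = mature)
}

#' Embed a peptide in a synthetic EST record
#'
#' Reverse-translates the peptide with uniformly random synonymous codons,
#' appends a stop codon, and pads with random untranslated regions sized so
#' the open reading frame sits in the requested frame. An in-frame stop
#' codon closes the 5' side, so the translated fragment starts exactly at
#' the peptide. On the minus strand the whole construct is
#' reverse-complemented.
#'
#' @param peptide Amino acid string; may contain internal `'.'` (planted as
#'   in-frame stop codons, used for decoy construction).
#' @param frame Target frame 1, 2 or 3 (of the output record for `+`, of
#'   its reverse complement for `-`).
#' @param strand `"+"` or `"-"`.
#' @param utr5,utr3 Approximate untranslated-region lengths in nt.
#' @return A list: `seq` (DNA string), `frame` (signed frame the peptide
#'   translates in), `orf_nt_start` (first codon position in `seq`
#'   coordinates of the plus strand of the emitted record).
#' @export
embed_as_est <- function(peptide, frame = 1L, strand = "+",
                         utr5 = 60L, utr3 = 90L) {
  stopifnot(frame %in% 1:3, strand %in% c("+", "-"))
  codons <- .codon_table()
  aa <- strsplit(peptide, "")[[1]]
  orf <- paste(vapply(c(aa, "."), function(a) {
    opts <- codons[[a]]
    opts[sample.int(length(opts), 1)]
  }, ""), collapse = "")
  # 5' UTR: random nt, closed by an in-frame stop codon; total length must
  # leave the ORF start congruent to the requested frame.
  lead <- max(utr5 + sample(-10:10, 1), 6L)
  lead <- lead - ((lead - (frame - 1L)) %% 3L)
  u5 <- paste0(.random_dna(lead - 3L),
               codons[["."]][sample.int(3L, 1)])
  u3 <- .random_dna(max(utr3 + sample(-20:20, 1), 0L))
  sense <- paste0(u5, orf, u3)
  if (strand == "+") {
    list(seq = sense, frame = frame, orf_nt_start = nchar(u5) + 1L)
  } else {
    rec <- reverse_complement(sense)
    # the peptide reads on the minus strand of `rec` in frame -frame
    list(seq = rec, frame = -frame,
         orf_nt_start = nchar(rec) - nchar(u5) - nchar(orf) + 1L)
  }
}

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Configuration for the synthetic EST bank generator
#'
#' @param n_noise Number of random-DNA noise records.
#' @param planted_per_motif Named integer vector: planted precursor count
#'   per screening-line motif id.
#' @param n_decoy_split Stop-split decoys: motif-shaped cysteine runs broken
#'   by an internal stop codon, which the fragment rule must reject.
#' @param n_decoy_nosignal Signal-less decoys: motif-carrying ORFs with no
#'   initiator Met, which the signal stage must reject.
#' @param family_size_range Range of clone-family sizes for planted
#'   precursors (members of one family share a mature scaffold).
#' @param mutation_rate Probability that a family member's mature domain
#'   carries a point substitution (at a non-key position, preserving the
#'   pattern), emulating natural combinatorial libraries.
#' @param noise_len_range Noise record length range in nt.
#' @param seed RNG seed; the same seed reproduces the bank byte-for-byte.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_noise = 200L,
                             planted_per_motif = c("motif 1" = 5L,
                                                   "motif 2" = 5L,
                                                   "motif 3" = 5L,
                                                   "motif 4" = 5L),
                             n_decoy_split = 10L,
                             n_decoy_nosignal = 10L,
                             family_size_range = c(1L, 3L),
                             mutation_rate = 0.5,
                             noise_len_range = c(200L, 700L),
                             seed = 1L) {
  stopifnot(n_noise >= 0L, all(planted_per_motif >= 0L),
            n_decoy_split >= 0L, n_decoy_nosignal >= 0L,
            mutation_rate >= 0, mutation_rate <= 1,
            !is.null(names(planted_per_motif)))
  structure(list(n_noise = as.integer(n_noise),
                 planted_per_motif = planted_per_motif,
                 n_decoy_split = as.integer(n_decoy_split),
                 n_decoy_nosignal = as.integer(n_decoy_nosignal),
                 family_size_range = as.integer(family_size_range),
                 mutation_rate = mutation_rate,
                 noise_len_range = as.integer(noise_len_range),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Point-mutate one non-key position of a mature domain (pattern-preserving).
.mutate_mature <- function(mature, spec) {
  ch <- strsplit(mature, "")[[1]]
  nonkey_pos <- which(!ch %in% c(spec$keys, "."))
  if (length(nonkey_pos) == 0L) return(mature)
  i <- nonkey_pos[sample.int(length(nonkey_pos), 1)]
  ch[i] <- sample(setdiff(.NONKEY_AA, c(ch[i], spec$keys)), 1)
  paste(ch, collapse = "")
}

#' Generate a synthetic EST bank with a planting manifest
#'
#' Builds a bank of random-DNA noise records, decoys, and planted secreted
#' precursors whose mature domains instantiate screening-line motifs.
#' Planted precursors come in clone families; family members may carry
#' pattern-preserving point substitutions, so identical mature domains
#' collapse predictably under [dedup_matures()]. The manifest suffices to
#' recompute every expected hit and precursor call.
#'
#' @param cfg A [generator_config()].
#' @param registry Registry supplying the motif lines to instantiate.
#' @param spec [key_spec()] for the internal self-checks.
#' @param fasta_path,manifest_path Optional output paths (FASTA bank and
#'   TSV manifest); written atomically when given.
#' @return A list: `bank` (`DNAStringSet`), `manifest` (data.frame with one
#'   row per record: `record_id`, `class` = noise/planted/decoy_split/
#'   decoy_nosignal, `motif_id`, `frame`, `strand`, `precursor`,
#'   `signal_end`, `mature_start`, `mature_seq`, `orf_nt_start`), `cfg`.
#' @examples
#' gen <- generate_bank(generator_config(n_noise = 5,
#'   planted_per_motif = c("motif 1" = 2), n_decoy_split = 1,
#'   n_decoy_nosignal = 1, seed = 7))
#' table(gen$manifest$class)
#' @export
generate_bank <- function(cfg = generator_config(),
                          registry = default_registry(),
                          spec = key_spec("C."),
                          fasta_path = NULL, manifest_path = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  rows <- list()
  seqs <- character(0)
  add <- function(id, class, motif_id, frame, strand, precursor,
                  signal_end, mature_start, mature_seq, orf_nt_start, dna) {
    rows[[length(rows) + 1L]] <<- data.frame(
      record_id = id, class = class, motif_id = motif_id, frame = frame,
      strand = strand, precursor = precursor, signal_end = signal_end,
      mature_start = mature_start, mature_seq = mature_seq,
      orf_nt_start = orf_nt_start, stringsAsFactors = FALSE)
    seqs[id] <<- dna
  }
  # planted precursors, in clone families
  for (mid in names(cfg$planted_per_motif)) {
    q <- registry$motifs[[mid]]
    if (is.null(q)) stop("motif '", mid, "' not in registry", call. = FALSE)
    n_left <- cfg$planted_per_motif[[mid]]
    fam <- 0L
    while (n_left > 0L) {
      fam <- fam + 1L
      fs <- min(sample(cfg$family_size_range[1]:cfg$family_size_range[2], 1),
                n_left)
      base_mature <- sample_mature_for_motif(q, spec = spec)
      for (member in seq_len(fs)) {
        mature <- base_mature
        if (member > 1L && stats::runif(1) < cfg$mutation_rate) {
          mature <- .mutate_mature(mature, spec)
        }
        pc <- build_precursor(mature)
        frame <- sample(1:3, 1)
        strand <- sample(c("+", "-"), 1)
        emb <- embed_as_est(pc$precursor, frame, strand)
        id <- sprintf("planted|%s|f%d|m%d", gsub(" ", "", mid), fam, member)
        add(id, "planted", mid, emb$frame, strand, pc$precursor,
            pc$signal_end, pc$mature_start, mature, emb$orf_nt_start,
            emb$seq)
        n_left <- n_left - 1L
      }
    }
  }
  # stop-split decoys: break the first motif's worth of cysteines in two
  split_motifs <- names(cfg$planted_per_motif)
  for (i in seq_len(cfg$n_decoy_split)) {
    mid <- split_motifs[1L + (i - 1L) %% length(split_motifs)]
    mature <- sample_mature_for_motif(registry$motifs[[mid]], spec = spec)
    broken <- .split_with_stop(mature)
    frame <- sample(1:3, 1)
    strand <- sample(c("+", "-"), 1)
    emb <- embed_as_est(broken, frame, strand)
    add(sprintf("decoySplit|%s|%d", gsub(" ", "", mid), i), "decoy_split",
        mid, emb$frame, strand, broken, NA_integer_, NA_integer_,
        NA_character_, emb$orf_nt_start, emb$seq)
  }
  # signal-less decoys: the mature scaffold alone, no Met anywhere near it
  for (i in seq_len(cfg$n_decoy_nosignal)) {
    mid <- split_motifs[1L + (i - 1L) %% length(split_motifs)]
    mature <- sample_mature_for_motif(registry$motifs[[mid]], spec = spec)
    frame <- sample(1:3, 1)
    strand <- sample(c("+", "-"), 1)
    emb <- embed_as_est(mature, frame, strand)
    add(sprintf("decoyNoSig|%s|%d", gsub(" ", "", mid), i),
        "decoy_nosignal", mid, emb$frame, strand, mature, NA_integer_,
        NA_integer_, NA_character_, emb$orf_nt_start, emb$seq)
  }
  # noise
  for (i in seq_len(cfg$n_noise)) {
    len <- sample(cfg$noise_len_range[1]:cfg$noise_len_range[2], 1)
    add(sprintf("noise|%05d", i), "noise", NA_character_, NA_integer_,
        NA_character_, NA_character_, NA_integer_, NA_integer_,
        NA_character_, NA_integer_, .random_dna(len))
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  bank <- Biostrings::DNAStringSet(seqs)
  if (!is.null(fasta_path)) write_fasta(bank, fasta_path)
  if (!is.null(manifest_path)) {
    tmp <- tempfile(tmpdir = dirname(manifest_path))
    utils::write.table(manifest, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file.rename(tmp, manifest_path)
  }
  list(bank = bank, manifest = manifest, cfg = cfg)
}

# Insert an in-frame stop between two cysteines near the middle of a mature
# scaffold, so its pattern only matches the motif across the stop.
.split_with_stop <- function(mature) {
  cpos <- which(strsplit(mature, "")[[1]] == "C")
  if (length(cpos) < 2L) {
    return(paste0(substr(mature, 1, nchar(mature) %/% 2), ".",
                  substring(mature, nchar(mature) %/% 2 + 1L)))
  }
  k <- length(cpos) %/% 2L
  at <- cpos[k]  # right after the k-th cysteine
  paste0(substr(mature, 1, at), ".", substring(mature, at + 1L))
}

#' Expected deduplicated multiplicities from a planting manifest
#'
#' @param manifest Manifest from [generate_bank()].
#' @return data.frame `motif_id`, `mature_seq`, `multiplicity` for planted
#'   records.
#' @export
manifest_multiplicities <- function(manifest) {
  pl <- manifest[manifest$class == "planted", , drop = FALSE]
  agg <- stats::aggregate(list(multiplicity = pl$record_id),
                          by = list(motif_id = pl$motif_id,
                                    mature_seq = pl$mature_seq),
                          FUN = length)
  agg[order(agg$motif_id, agg$mature_seq), , drop = FALSE]
}
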