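#' Extract stop-bounded fragments from a translated frame
#'
#' Fragments are the only units in which motif matches are allowed: maximal
#' stop-free stretches that start at the frame beginning or right after a
#' stop, and end with a stop symbol. The terminating `'.'` is part of the
#' fragment. A trailing stretch with no terminating stop is rejected as
#' partially identified; fragments with fewer than `min_len` residues
#' (excluding the stop) are dropped.
#'
#' @param aa_seq A translated-frame amino acid string (may contain `'.'`).
#' @param min_len Minimum fragment length in residues, stop excluded.
#' @return A data.frame with columns `aa_start`, `aa_end` (1-based, closed,
#'   including the terminal stop) and `seq`.
#' @examples
#' extract_fragments("MAAC.KKC.GG")  # two fragments; trailing "GG" rejected
#' @export
extract_fragments <- function(aa_seq, min_len = 0L) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L)
  if (nchar(aa_seq) == 0L) {
    return(data.frame(aa_start = integer(0), aa_end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[^.]*\\.", aa_seq)[[1]]
  if (m[1] == -1L) {
    return(data.frame(aa_start = integer(0), aa_end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  keep <- (lens - 1L) >= max(min_len, 1L)
  starts <- starts[keep]
  lens <- lens[keep]
  if (length(starts) == 0L) {
    return(data.frame(aa_start = integer(0), aa_end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    aa_start = starts,
    aa_end = starts + lens - 1L,
    seq = substring(aa_seq, starts, starts + lens - 1L),
    stringsAsFactors = FALSE
  )
}

# Fragment table for one whole bank: record_id, frame, aa_start, aa_end,
# seq, pattern. Vectorized over frames.
.bank_fragments <- function(bank, spec, min_len = 0L, code_id = 1L) {
  frames6 <- .six_frames_set(bank, code_id)
  out <- vector("list", 6L)
  k <- 0L
  for (f in names(frames6)) {
    aa <- frames6[[f]]
    fr <- lapply(seq_along(aa), function(i) {
      d <- extract_fragments(aa[i], min_len)
      if (nrow(d) > 0L) d$row <- i
      d
    })
    fr <- fr[vapply(fr, nrow, 0L) > 0L]
    k <- k + 1L
    if (length(fr) == 0L) {
      out[[k]] <- NULL
      next
    }
    d <- do.call(rbind, fr)
    d$record_id <- names(bank)[d$row]
    d$frame <- as.integer(f)
    d$row <- NULL
    out[[k]] <- d
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(data.frame(aa_start = integer(0), aa_end = integer(0),
                      seq = character(0), record_id = character(0),
                      frame = integer(0), pattern = character(0),
                      stringsAsFactors = FALSE))
  }
  d <- do.call(rbind, out)
  d$pattern <- srda_convert(d$seq, spec)
  rownames(d) <- NULL
  d
}

# Match every enabled motif against a fragment table; returns the hit table.
.match_fragments <- function(frags, registry, widths) {
  hit_list <- lapply(.enabled_motifs(registry), function(q) {
    if (q$type == "line") {
      m <- match_motif(q, frags$pattern)
      idx <- which(m$matched)
    } else {
      idx <- which(match_compound(q, frags$seq)$matched)
    }
    if (length(idx) == 0L) return(NULL)
    h <- frags[idx, , drop = FALSE]
    h$motif_id <- q$id
    h
  })
  hit_list <- hit_list[!vapply(hit_list, is.null, TRUE)]
  if (length(hit_list) == 0L) {
    return(data.frame(record_id = character(0), frame = integer(0),
                      motif_id = character(0), aa_start = integer(0),
                      aa_end = integer(0), nt_start = integer(0),
                      nt_end = integer(0), fragment_seq = character(0),
                      pattern = character(0), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hit_list)
  L <- widths[h$record_id]
  p1 <- aa_to_nt(h$aa_start, h$frame, L)
  p2 <- aa_to_nt(h$aa_end, h$frame, L)
  h$nt_start <- pmin(p1, p2)
  h$nt_end <- pmax(p1, p2) + 2L
  res <- data.frame(record_id = h$record_id, frame = h$frame,
                    motif_id = h$motif_id, aa_start = h$aa_start,
                    aa_end = h$aa_end, nt_start = h$nt_start,
                    nt_end = h$nt_end, fragment_seq = h$seq,
                    pattern = h$pattern, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Scan a single nucleotide record for motif hits
#'
#' Translates the record in six frames, extracts stop-bounded fragments,
#' converts them to SRDA patterns and matches every enabled motif: line
#' motifs against the pattern, compound motifs against the fragment's amino
#' acid sequence.
#'
#' @param seq DNA string of the record.
#' @param id Record identifier used in the hit table.
#' @param registry A [motif_registry()].
#' @param spec A [key_spec()]; the registry ships for `SRDA("C.")`.
#' @param min_len Minimum fragment length in residues.
#' @return A hit data.frame: `record_id`, `frame`, `motif_id`, `aa_start`,
#'   `aa_end`, `nt_start`, `nt_end`, `fragment_seq`, `pattern`.
#' @export
scan_record <- function(seq, id = "record", registry = default_registry(),
                        spec = key_spec("C."), min_len = 0L) {
  bank <- Biostrings::DNAStringSet(stats::setNames(toupper(seq), id))
  scan_bank(bank, registry, spec, min_len)$hits
}

#' Scan a whole EST bank for motif hits
#'
#' @param bank A `DNAStringSet` (see [read_fasta()]) or a path to a FASTA
#'   file.
#' @param registry A [motif_registry()].
#' @param spec A [key_spec()].
#' @param min_len Minimum fragment length in residues (stop excluded). The
#'   default keeps every stop-terminated fragment; 30 is a practical floor
#'   when mining secreted precursors (a signal peptide alone occupies
#'   15-45 residues).
#' @param code_id Genetic code table id.
#' @return A list with `hits` (one row per record/frame/fragment/motif) and
#'   `report` (per-motif distinct-record counts at the retrieval stage).
#' @examples
#' bank <- Biostrings::DNAStringSet(c(e1 = "ATGTGCAAATGCTGA"))
#' scan_bank(bank, min_len = 0)$report
#' @export
scan_bank <- function(bank, registry = default_registry(),
                      spec = key_spec("C."), min_len = 0L, code_id = 1L) {
  if (is.character(bank) && length(bank) == 1L && file.exists(bank)) {
    bank <- read_fasta(bank)
  }
  stopifnot(methods::is(bank, "DNAStringSet"))
  if (length(.enabled_motifs(registry)) == 0L) {
    stop("motif registry has no enabled motifs", call. = FALSE)
  }
  if (is.null(names(bank))) {
    stop("bank records must be named", call. = FALSE)
  }
  frags <- .bank_fragments(bank, spec, min_len, code_id)
  widths <- stats::setNames(S4Vectors::width(bank), names(bank))
  hits <- .match_fragments(frags, registry, widths)
  list(hits = hits, report = stage_report(registry, hits))
}

#' Scan a protein reference set
#'
#' Each whole sequence is treated as a single fragment; screening lines are
#' stripped of their stop symbols first ([strip_stops()]) and compound
#' motifs are applied to the whole sequence.
#'
#' @param seqs Named character vector (or `AAStringSet`) of protein
#'   sequences; must contain no `'.'`.
#' @param registry A [motif_registry()].
#' @param spec A [key_spec()]; its `include_stop` flag is irrelevant here.
#' @return A hit data.frame with columns `record_id`, `motif_id`, `start`,
#'   `end` (span within the pattern; NA for compound motifs), `pattern`.
#' @export
scan_protein_set <- function(seqs, registry = default_registry(),
                             spec = key_spec("C.")) {
  if (methods::is(seqs, "AAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (any(grepl(".", seqs, fixed = TRUE))) {
    stop("protein sequences contain '.': use scan_bank for EST fragments",
         call. = FALSE)
  }
  patterns <- srda_convert(seqs, spec)
  out <- lapply(.enabled_motifs(registry), function(q) {
    if (q$type == "line") {
      m <- match_motif(strip_stops(q), patterns)
      idx <- which(m$matched)
      if (length(idx) == 0L) return(NULL)
      data.frame(record_id = names(seqs)[idx], motif_id = q$id,
                 start = m$start[idx], end = m$end[idx],
                 pattern = patterns[idx], stringsAsFactors = FALSE)
    } else {
      idx <- which(match_compound(q, seqs)$matched)
      if (length(idx) == 0L) return(NULL)
      data.frame(record_id = names(seqs)[idx], motif_id = q$id,
                 start = NA_integer_, end = NA_integer_,
                 pattern = patterns[idx], stringsAsFactors = FALSE)
    }
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(data.frame(record_id = character(0), motif_id = character(0),
                      start = integer(0), end = integer(0),
                      pattern = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-motif stage report
#'
#' Counts distinct records per motif at each pipeline stage: `retrieved`
#' (motif hit in any frame/fragment), `signal_approved` (at least one
#' accepted signal-peptide call) and `deduplicated` (unique mature domains
#' among the motif's calls). A record counts once per motif regardless of
#' how many frames or fragments hit. Counts are non-increasing across
#' stages by construction.
#'
#' @param registry A [motif_registry()].
#' @param hits Hit table from [scan_bank()].
#' @param calls Optional precursor call table from [call_precursors()];
#'   when absent the later stage columns are NA.
#' @return A data.frame with one row per enabled motif plus a `total` row
#'   (in record-by-motif units at the first two stages, unique mature
#'   domains across all motifs at the last).
#' @export
stage_report <- function(registry, hits, calls = NULL) {
  motifs <- names(.enabled_motifs(registry))
  rows <- lapply(motifs, function(id) {
    h <- hits[hits$motif_id == id, , drop = FALSE]
    retrieved <- length(unique(h$record_id))
    if (is.null(calls)) {
      sig <- NA_integer_
      ded <- NA_integer_
    } else {
      cl <- calls[calls$motif_id == id, , drop = FALSE]
      sig <- length(unique(cl$record_id))
      ded <- length(unique(cl$mature_seq))
    }
    data.frame(motif_id = id, retrieved = retrieved, signal_approved = sig,
               deduplicated = ded, stringsAsFactors = FALSE)
  })
  # totals in record x motif units, so the chain stays non-increasing even
  # when one record carries different matures under different motifs
  tot <- data.frame(
    motif_id = "total",
    retrieved = nrow(unique(hits[c("record_id", "motif_id")])),
    signal_approved = if (is.null(calls)) NA_integer_ else nrow(calls),
    deduplicated = if (is.null(calls)) NA_integer_
                   else length(unique(calls$mature_seq)),
    stringsAsFactors = FALSE)
  res <- do.call(rbind, c(rows, list(tot), make.row.names = FALSE))
  res
}
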