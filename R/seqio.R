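#' Read a nucleotide FASTA bank
#'
#' Reads a FASTA file of EST (or any nucleotide) records. The record id is
#' the header token up to the first whitespace; the remainder of the header
#' is kept as the description. Sequences are upper-cased and whitespace is
#' stripped.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, with the free-text
#'   description stored in `mcols(x)$description`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">est1 first", "ATGTGA", ">est2", "acgtacgt"), fa)
#' bank <- read_fasta(fa)
#' names(bank)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(x) == 0L) {
    warning("FASTA file contains no records: ", path, call. = FALSE)
    return(x)
  }
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    stop("FASTA record with empty id at position ",
         which(ids == "")[1L], call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate FASTA record id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  names(x) <- ids
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(description = desc)
  x
}

#' Write a nucleotide or amino acid FASTA file
#'
#' Writes atomically: the content goes to a temporary file in the target
#' directory which is then renamed, so an interrupted run leaves no partial
#' output.
#'
#' @param x A named character vector or an `XStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    stopifnot(!is.null(names(x)))
    lines <- as.vector(rbind(paste0(">", names(x)), unname(x)))
    tmp <- tempfile(tmpdir = dirname(path))
    writeLines(lines, tmp)
  } else {
    tmp <- tempfile(tmpdir = dirname(path))
    Biostrings::writeXStringSet(x, tmp)
  }
  file.rename(tmp, path)
  invisible(path)
}

.check_dna <- function(seq) {
  bad <- regexpr("[^ACGTN]", seq)
  if (bad != -1L) {
    stop("invalid nucleotide '", substr(seq, bad, bad), "' at position ",
         bad, call. = FALSE)
  }
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' @param seq A DNA string over `ACGTN` (lowercase tolerated).
#' @return The Watson-Crick reverse complement (upper case); `N` maps to `N`.
#' @examples
#' reverse_complement("ATGTGA")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) return("")
  .check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a DNA string in one reading frame
#'
#' Conceptual translation under the standard genetic code (NCBI table 1).
#' Stop codons are rendered as `'.'`; a codon containing `N` translates to
#' the unambiguous amino acid when every resolution of the `N` agrees
#' (e.g. `GGN` -> `G`) and to `'X'` otherwise. A trailing partial codon is
#' dropped. Negative frames translate the reverse complement in frame
#' `|frame|`. `frame = 0` is a compatibility mode returning the reverse
#' complement nucleotide string itself.
#'
#' @param seq DNA string over `ACGTN`.
#' @param frame Integer in `{0, 1, 2, 3, -1, -2, -3}`.
#' @param code_id NCBI genetic code table id (default 1, the standard code).
#' @return Amino acid string over the 20 standard letters, `'X'` and `'.'`
#'   (or a DNA string when `frame = 0`).
#' @examples
#' translate_frame("ATGTGA", 1)   # "M."
#' translate_frame("ATGTGA", -1)  # "SH"
#' translate_frame("ATGTGA", 2)   # "C"
#' @export
translate_frame <- function(seq, frame, code_id = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!frame %in% c(0L, 1L, 2L, 3L, -1L, -2L, -3L)) {
    stop("invalid frame: ", frame,
         " (acceptable values are 0, 1, 2, 3, -1, -2, -3)", call. = FALSE)
  }
  seq <- toupper(seq)
  if (nchar(seq) > 0L) .check_dna(seq)
  if (frame == 0L) {
    if (nchar(seq) == 0L) return("")
    return(reverse_complement(seq))
  }
  if (frame < 0L) {
    seq <- if (nchar(seq) == 0L) "" else reverse_complement(seq)
    frame <- -frame
  }
  offset <- frame - 1L
  n_codons <- max((nchar(seq) - offset) %/% 3L, 0L)
  if (n_codons == 0L) return("")
  sub <- substr(seq, offset + 1L, offset + 3L * n_codons)
  gc <- Biostrings::getGeneticCode(as.character(code_id))
  aa <- Biostrings::translate(Biostrings::DNAString(sub),
                              genetic.code = gc,
                              if.fuzzy.codon = "solve")
  chartr("*", ".", as.character(aa))
}

#' Six-frame conceptual translation
#'
#' @param seq DNA string over `ACGTN`.
#' @param code_id Genetic code table id, see [translate_frame()].
#' @return Named character vector of the six translations, frames in the
#'   order `1, 2, 3, -1, -2, -3`.
#' @examples
#' six_frames("ATGTGA")
#' @export
six_frames <- function(seq, code_id = 1L) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  if (nchar(gsub("\\s", "", seq)) < 3L) {
    warning("record shorter than 3 nt: all frames empty", call. = FALSE)
  }
  out <- vapply(frames, function(f) translate_frame(seq, f, code_id), "")
  names(out) <- as.character(frames)
  out
}

# Vectorized six-frame translation of a whole bank; used by scan_bank so
# translation stays a few Biostrings calls rather than 6 * n_records.
.six_frames_set <- function(bank, code_id = 1L) {
  gc <- Biostrings::getGeneticCode(as.character(code_id))
  rc <- Biostrings::reverseComplement(bank)
  one <- function(set, f) {
    w <- S4Vectors::width(set)
    start <- pmin(f, w + 1L)
    len <- pmax((w - (f - 1L)) %/% 3L, 0L)
    sub <- Biostrings::subseq(set, start = start, width = 3L * len)
    aa <- Biostrings::translate(sub, genetic.code = gc,
                                if.fuzzy.codon = "solve")
    chartr("*", ".", as.character(aa))
  }
  res <- list()
  for (f in 1:3) {
    res[[as.character(f)]] <- one(bank, f)
    res[[as.character(-f)]] <- one(rc, f)
  }
  res[c("1", "2", "3", "-1", "-2", "-3")]
}

#' Map an amino acid position back to the nucleotide coordinate
#'
#' Returns the 1-based position, on the original strand, of the first
#' nucleotide of the codon encoding residue `aa_pos` of the given frame.
#' For minus frames the codon is read on the minus strand; the returned
#' coordinate is the smallest original-strand position the codon occupies.
#'
#' @param aa_pos 1-based amino acid position within the translated frame.
#' @param frame Integer in `{1, 2, 3, -1, -2, -3}`.
#' @param record_length Length of the nucleotide record in nt.
#' @return 1-based nucleotide position of the codon start.
#' @examples
#' aa_to_nt(1, 1, 60)   # 1
#' aa_to_nt(2, 3, 60)   # 6
#' aa_to_nt(1, -1, 6)   # 4: the last minus-strand codon occupies nt 4..6
#' @export
aa_to_nt <- function(aa_pos, frame, record_length) {
  if (!all(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))) {
    stop("invalid frame: ", frame, call. = FALSE)
  }
  n_aa <- (record_length - (abs(frame) - 1L)) %/% 3L
  if (any(aa_pos < 1L | aa_pos > n_aa)) {
    stop("aa_pos ", aa_pos[which(aa_pos < 1L | aa_pos > n_aa)[1L]],
         " out of range for frame ", frame[1L], " of a ", record_length,
         " nt record", call. = FALSE)
  }
  as.integer(ifelse(frame > 0L,
                    frame + 3L * (aa_pos - 1L),
                    record_length - (abs(frame) - 1L) -
                      3L * (aa_pos - 1L) - 2L))
}

#' Export translations as a table
#'
#' @param bank A `DNAStringSet` (e.g. from [read_fasta()]).
#' @param code_id Genetic code table id.
#' @return A data.frame with columns `record_id`, `frame`, `aa_seq`.
#' @export
translate_bank <- function(bank, code_id = 1L) {
  fr <- .six_frames_set(bank, code_id)
  frames <- as.integer(names(fr))
  data.frame(
    record_id = rep(names(bank), times = 6L),
    frame = rep(frames, each = length(bank)),
    aa_seq = unlist(fr, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}
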