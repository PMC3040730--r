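# Kyte-Doolittle hydropathy index, used by the signal-peptide heuristic.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2, X = 0, "." = 0)

#' Parameters of the internal signal-peptide heuristic
#'
#' The heuristic scores each candidate initiator Met by (i) the maximal
#' Kyte-Doolittle hydropathy sum over a sliding window inside the expected
#' hydrophobic core and (ii) a small-residue indicator at the -3/-1
#' positions of the best cleavage candidate. It is a transparent,
#' reproducible stand-in for a dedicated predictor; externally computed
#' SignalP calls can override it via [load_signalp_output()].
#'
#' @param limitMet Deepest fragment position searched for the initiator Met
#'   (residues; default 30).
#' @param core_window Sliding-window length for the hydrophobic core sum
#'   (residues; default 8).
#' @param core_span Window start offsets searched, counting the Met as
#'   residue 1 (default 6..20).
#' @param cleave_span Cleavage positions searched, counting the Met as
#'   residue 1; cleavage is after the residue at that position (default
#'   15..45).
#' @param small_set Residues allowed at the -3 and -1 positions of a
#'   signal-peptidase site (default A, G, S, C, T).
#' @param w_hydro,w_cleave Weights of the two score components.
#' @param threshold Acceptance threshold on the combined score. The default
#'   requires a solidly hydrophobic core: an all-leucine window scores
#'   8 x 3.8 = 30.4, a mixed polar window scores near or below 0.
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(limitMet = 30L, core_window = 8L,
                          core_span = c(6L, 20L), cleave_span = c(15L, 45L),
                          small_set = c("A", "G", "S", "C", "T"),
                          w_hydro = 1, w_cleave = 8, threshold = 20) {
  stopifnot(limitMet >= 1L, core_window >= 1L,
            core_span[1] >= 1L, core_span[2] >= core_span[1],
            cleave_span[1] >= 2L, cleave_span[2] >= cleave_span[1],
            is.finite(threshold))
  structure(list(limitMet = as.integer(limitMet),
                 core_window = as.integer(core_window),
                 core_span = as.integer(core_span),
                 cleave_span = as.integer(cleave_span),
                 small_set = small_set,
                 w_hydro = w_hydro, w_cleave = w_cleave,
                 threshold = threshold),
            class = "signal_params")
}

#' Predict the initiator Met and signal-peptide cleavage of a fragment
#'
#' For every Met within `limitMet` of the fragment start, the score is
#' `w_hydro * max(sliding-window hydropathy over the core span) +
#' w_cleave * small-residue indicator at the best cleavage candidate`
#' (the indicator averages the -3 and -1 positions; ties resolve to the
#' cleavage nearest the Met). The best-scoring Met is returned; the call is
#' accepted when the score reaches the threshold and a cleavage candidate
#' exists.
#'
#' @param fragment_seq A stop-terminated fragment (a trailing `'.'` is
#'   tolerated and ignored for scoring).
#' @param params A [signal_params()].
#' @param format Optional output selector mirroring the historical
#'   spreadsheet interface: 0 returns the first nucleotide of the signal
#'   (requires `frame` and `record_length`), 1 the Met position, 2 the last
#'   nucleotide of the signal, 3 the last signal residue, any other number
#'   the score. `NULL` (default) returns the full call object.
#' @param frame,record_length Needed only for nucleotide-coordinate formats.
#' @return A list of class `signal_call` with `met_pos`, `cleavage_after`,
#'   `score`, `accepted` — or `NULL` (no-call) when no Met lies within
#'   `limitMet`.
#' @examples
#' sig <- signal_from(paste0("M", strrep("L", 12), "ASA",
#'                           "DDEEQNGRSDDE", "."))
#' sig$cleavage_after  # 16: after the -3/-1 A..A site
#' @export
signal_from <- function(fragment_seq, params = signal_params(),
                        format = NULL, frame = NULL, record_length = NULL) {
  stopifnot(is.character(fragment_seq), length(fragment_seq) == 1L)
  seq <- sub("\\.$", "", fragment_seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  mets <- which(ch == "M")
  mets <- mets[mets <= params$limitMet]
  if (length(mets) == 0L) return(NULL)
  hyd <- unname(.KD[ch])
  small <- ch %in% params$small_set
  best <- NULL
  for (m in mets) {
    # hydrophobic core: windows starting at offsets core_span after the Met
    w <- params$core_window
    starts <- m + (params$core_span[1]:params$core_span[2]) - 1L
    starts <- starts[starts + w - 1L <= n]
    core <- if (length(starts) == 0L) -Inf else {
      cs <- c(0, cumsum(hyd))
      max(cs[starts + w] - cs[starts])
    }
    # cleavage: -3/-1 small-residue rule over the cleavage span
    cand <- m + (params$cleave_span[1]:params$cleave_span[2]) - 1L
    cand <- cand[cand < n & cand - 2L > m]
    if (length(cand) == 0L) {
      ind <- 0
      cleave <- NA_integer_
    } else {
      ind_all <- (small[cand] + small[cand - 2L]) / 2
      cleave <- cand[which.max(ind_all)]  # ties: nearest the Met
      ind <- max(ind_all)
    }
    score <- params$w_hydro * core + params$w_cleave * ind
    if (is.null(best) || score > best$score) {
      best <- list(met_pos = m, cleavage_after = cleave, score = score,
                   accepted = is.finite(score) && !is.na(cleave) &&
                     score >= params$threshold)
    }
  }
  call <- structure(best, class = "signal_call")
  if (is.null(format)) return(call)
  if (format %in% c(0, 2) && (is.null(frame) || is.null(record_length))) {
    stop("formats 0 and 2 need frame and record_length", call. = FALSE)
  }
  switch(as.character(format),
         "0" = aa_to_nt(call$met_pos, frame, record_length),
         "1" = call$met_pos,
         "2" = {
           p <- aa_to_nt(call$cleavage_after, frame, record_length)
           if (frame > 0) p + 2L else p
         },
         "3" = call$cleavage_after,
         call$score)
}

#' Read SignalP short-format output
#'
#' Parses the classic SignalP short (one line per sequence) output and
#' returns calls that override the internal heuristic in
#' [call_precursors()]. Expected whitespace-separated columns:
#' `name Cmax pos Ymax pos Smax pos Smean D ? Dmaxcut Networks-used`,
#' with `?` being `Y`/`N`; the cleavage site is before the `Ymax` position.
#'
#' @param path Path to the output file; `#` lines are comments.
#' @return Named list of `signal_call` objects (name = sequence id).
#' @export
load_signalp_output <- function(path) {
  if (!file.exists(path)) stop("SignalP file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) return(list())
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 10L || is.na(suppressWarnings(as.numeric(f[5]))) ||
        !f[10] %in% c("Y", "N")) {
      stop("unparseable SignalP line ", i, ": ", lines[i], call. = FALSE)
    }
    out[[f[1]]] <- structure(
      list(met_pos = 1L, cleavage_after = as.integer(f[5]) - 1L,
           score = as.numeric(f[9]), accepted = f[10] == "Y"),
      class = "signal_call")
  }
  out
}

#' Extract the chain from a start position to the next stop
#'
#' @param seq Amino acid string.
#' @param start 1-based start position.
#' @return A list with `seq` (the chain, stop excluded) and `end` (position
#'   of the last residue before the stop).
#' @examples
#' mature_chain("MAACD.", 4)  # seq "CD", end 5
#' @export
mature_chain <- function(seq, start) {
  stopifnot(start >= 1L, start <= nchar(seq))
  rest <- substring(seq, start)
  dot <- regexpr(".", rest, fixed = TRUE)
  if (dot == -1L) {
    stop("no termination symbol downstream of position ", start,
         ": fragment is partially identified", call. = FALSE)
  }
  list(seq = substr(rest, 1L, dot - 1L), end = as.integer(start + dot - 2L))
}

#' Predict where the mature domain starts after the signal peptide
#'
#' Candidate processing sites are (a) immediately after a dibasic `KR`,
#' `RR` or `KK`, and (b) immediately after an `R` preceded by `E` at any of
#' positions -2..-4 (a processing-quadruplet-style rule). The site nearest
#' the signal cleavage (smallest offset) wins; with no candidate the mature
#' domain starts immediately after the signal (offset 1).
#'
#' @param precursor_after_signal Amino acid string beginning right after the
#'   signal-peptide cleavage (no `'.'`).
#' @return 1-based offset of the first mature residue within the input.
#' @examples
#' predict_mature_start("EAKRGVCC")  # 5: after the dibasic KR
#' predict_mature_start("EAGRSVCC")  # 5: R with E at -3
#' predict_mature_start("GGGGCC")    # 1: fallback
#' @export
predict_mature_start <- function(precursor_after_signal) {
  stopifnot(nchar(precursor_after_signal) > 0L)
  ch <- strsplit(precursor_after_signal, "")[[1]]
  n <- length(ch)
  cand <- integer(0)
  if (n >= 2L) {
    di <- which(paste0(ch[-n], ch[-1]) %in% c("KR", "RR", "KK"))
    cand <- c(cand, di + 2L)
  }
  for (j in which(ch == "R")) {
    back <- j - (2:4)
    back <- back[back >= 1L]
    if (length(back) > 0L && any(ch[back] == "E")) {
      cand <- c(cand, j + 1L)
    }
  }
  cand <- cand[cand <= n]
  if (length(cand) == 0L) return(1L)
  min(cand)
}

#' Collapse precursor calls with identical mature domains
#'
#' Identical mature peptide domains — ignoring any variation in the signal
#' peptide and propeptide — are collapsed to the first-seen representative.
#' Multiplicity counts EST clones: the number of distinct records sharing
#' the mature domain (overlapping motifs can hit the same clone more than
#' once without inflating it). Without a `record_id` column every row
#' counts as its own clone.
#'
#' @param calls Precursor call data.frame with a `mature_seq` column.
#' @return The deduplicated data.frame, original first-occurrence order.
#' @export
dedup_matures <- function(calls) {
  stopifnot(is.data.frame(calls), "mature_seq" %in% names(calls))
  if (nrow(calls) == 0L) {
    calls$multiplicity <- integer(0)
    return(calls)
  }
  first <- !duplicated(calls$mature_seq)
  clones <- if ("record_id" %in% names(calls)) calls$record_id
            else seq_len(nrow(calls))
  mult <- tapply(clones, calls$mature_seq,
                 function(x) length(unique(x)))
  out <- calls[first, , drop = FALSE]
  out$multiplicity <- as.integer(mult[out$mature_seq])
  rownames(out) <- NULL
  out
}

#' Call secreted precursors from motif hits
#'
#' Applies the signal-peptide stage to each hit fragment (internal
#' heuristic, or an external SignalP call when one is supplied for the
#' fragment id `record_id|frame|aa_start`), splits accepted precursors into
#' signal / propeptide / mature domains, keeps the best-scoring call per
#' (record, motif), and deduplicates identical mature domains.
#'
#' @param hits Hit table from [scan_bank()].
#' @param params A [signal_params()].
#' @param signalp Optional named list from [load_signalp_output()].
#' @param registry Registry used for the stage report (defaults to the
#'   shipped one).
#' @return A list with `calls` (deduplicated precursor calls: `record_id`,
#'   `frame`, `motif_id`, `aa_start` of the source fragment, `met_pos`,
#'   `cleavage_after`, `signal_seq`,
#'   `propeptide_seq`, `mature_seq`, `score`, `multiplicity`),
#'   `all_calls` (accepted calls before dedup) and `report` (per-motif
#'   stage counts, see [stage_report()]).
#' @export
call_precursors <- function(hits, params = signal_params(), signalp = NULL,
                            registry = default_registry()) {
  stopifnot(is.data.frame(hits))
  empty <- data.frame(record_id = character(0), frame = integer(0),
                      motif_id = character(0), aa_start = integer(0),
                      met_pos = integer(0),
                      cleavage_after = integer(0), signal_seq = character(0),
                      propeptide_seq = character(0), mature_seq = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) {
    dd <- empty
    dd$multiplicity <- integer(0)
    return(list(calls = dd, all_calls = empty,
                report = stage_report(registry, hits, empty)))
  }
  # one signal evaluation per distinct fragment
  frag_key <- paste(hits$record_id, hits$frame, hits$aa_start, sep = "|")
  uniq <- !duplicated(frag_key)
  sig_by_key <- stats::setNames(
    lapply(which(uniq), function(i) {
      k <- frag_key[i]
      if (!is.null(signalp) && !is.null(signalp[[k]])) signalp[[k]]
      else signal_from(hits$fragment_seq[i], params)
    }),
    frag_key[uniq])
  rows <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    sig <- sig_by_key[[frag_key[i]]]
    if (is.null(sig) || !isTRUE(sig$accepted)) next
    frag <- sub("\\.$", "", hits$fragment_seq[i])
    if (sig$cleavage_after >= nchar(frag)) next  # nothing left to secrete
    after <- substring(frag, sig$cleavage_after + 1L)
    ms <- predict_mature_start(after)
    rows[[i]] <- data.frame(
      record_id = hits$record_id[i], frame = hits$frame[i],
      motif_id = hits$motif_id[i], aa_start = hits$aa_start[i],
      met_pos = sig$met_pos,
      cleavage_after = sig$cleavage_after,
      signal_seq = substr(frag, sig$met_pos, sig$cleavage_after),
      propeptide_seq = if (ms > 1L) substr(after, 1L, ms - 1L) else "",
      mature_seq = substring(after, ms),
      score = sig$score, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  all_calls <- if (length(rows) == 0L) empty else do.call(rbind, rows)
  # best-scoring call per (record, motif): one precursor per clone and motif
  if (nrow(all_calls) > 0L) {
    ord <- order(all_calls$record_id, all_calls$motif_id, -all_calls$score)
    all_calls <- all_calls[ord, , drop = FALSE]
    keep <- !duplicated(all_calls[c("record_id", "motif_id")])
    all_calls <- all_calls[keep, , drop = FALSE]
    rownames(all_calls) <- NULL
  }
  deduped <- dedup_matures(all_calls)
  list(calls = deduped, all_calls = all_calls,
       report = stage_report(registry, hits, all_calls))
}

#' Write precursor calls as FASTA
#'
#' Header fields: `record_id|frame|motif_id|multiplicity signal=1-<s>
#' mature=<m>-<end>` (1-based offsets within the written precursor).
#'
#' @param calls Deduplicated call table from [call_precursors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_precursors <- function(calls, path) {
  seqs <- paste0(calls$signal_seq, calls$propeptide_seq, calls$mature_seq)
  s_end <- nchar(calls$signal_seq)
  m_start <- s_end + nchar(calls$propeptide_seq) + 1L
  hdr <- sprintf("%s|%d|%s|%d signal=1-%d mature=%d-%d",
                 calls$record_id, calls$frame, calls$motif_id,
                 calls$multiplicity, s_end, m_start, nchar(seqs))
  write_fasta(stats::setNames(seqs, hdr), path)
}
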