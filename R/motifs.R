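#' Parse a screening-line or compound motif
#'
#' A screening line is a wildcard query over SRDA pattern strings:
#' key letters, literal digits and `'.'` match themselves, `'?'` matches any
#' single symbol, `'#'` any single digit, and `'*'` a gap of zero or more
#' symbols. A compound motif is a conjunction of residue-count predicates
#' written like `"K >= 6 AND C <= 2"`, applied to the fragment's amino acid
#' sequence rather than to its pattern.
#'
#' @param text The motif text.
#' @param id Short motif name; defaults to the text itself.
#' @param enabled Whether bank scans use the motif by default.
#' @return An object of class `srda_motif` with fields `id`,
#'   `type` (`"line"` or `"compound"`), `line` or `predicates`, `enabled`.
#' @examples
#' parse_motif("C1C##C6C#CC", id = "motif 1")
#' parse_motif("K > = 6 AND C < = 2", id = "motif K")
#' @export
parse_motif <- function(text, id = NULL, enabled = TRUE) {
  stopifnot(is.character(text), length(text) == 1L, nchar(text) > 0L)
  if (is.null(id)) id <- text
  if (grepl("[<>]", text)) {
    preds <- .parse_compound(text)
    return(structure(list(id = id, type = "compound", line = NULL,
                          predicates = preds, enabled = enabled),
                     class = "srda_motif"))
  }
  bad <- regexpr("[^A-Z0-9.?#*]", text)
  if (bad != -1L) {
    stop("illegal character '", substr(text, bad, bad),
         "' in screening line at position ", bad, call. = FALSE)
  }
  if (grepl("**", text, fixed = TRUE)) {
    stop("doubled gap '**' in screening line: ", text, call. = FALSE)
  }
  structure(list(id = id, type = "line", line = text, predicates = NULL,
                 enabled = enabled),
            class = "srda_motif")
}

.parse_compound <- function(text) {
  clauses <- strsplit(text, "\\s+AND\\s+")[[1]]
  preds <- lapply(clauses, function(cl) {
    cl <- gsub("\\s", "", cl)  # tolerates the spaced table form "K > = 6"
    m <- regmatches(cl, regexec("^([A-Z])(>=|<=)([0-9]+)$", cl))[[1]]
    if (length(m) == 0L) {
      stop("cannot parse compound clause: '", cl, "'", call. = FALSE)
    }
    list(residue = m[2], op = m[3], threshold = as.integer(m[4]))
  })
  if (any(vapply(preds, function(p) p$threshold < 0L, TRUE))) {
    stop("negative threshold in compound motif", call. = FALSE)
  }
  preds
}

#' @export
print.srda_motif <- function(x, ...) {
  if (x$type == "line") {
    cat(sprintf("<motif %s> %s%s\n", x$id, x$line,
                if (!x$enabled) " (disabled)" else ""))
  } else {
    cat(sprintf("<motif %s> %s%s\n", x$id,
                paste(vapply(x$predicates,
                             function(p) paste0(p$residue, p$op, p$threshold),
                             ""), collapse = " AND "),
                if (!x$enabled) " (disabled)" else ""))
  }
  invisible(x)
}

#' Build a motif registry
#'
#' @param motifs A list of [parse_motif()] objects.
#' @param provenance Free-text note on where the motifs come from.
#' @return An object of class `motif_registry`.
#' @export
motif_registry <- function(motifs, provenance = "") {
  stopifnot(all(vapply(motifs, inherits, TRUE, "srda_motif")))
  ids <- vapply(motifs, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate motif id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(motifs = stats::setNames(motifs, ids),
                 provenance = provenance),
            class = "motif_registry")
}

#' @export
print.motif_registry <- function(x, ...) {
  cat(sprintf("SRDA motif registry: %d motifs (%d enabled)\n",
              length(x$motifs),
              sum(vapply(x$motifs, `[[`, TRUE, "enabled"))))
  for (m in x$motifs) print(m)
  invisible(x)
}

#' Read a motif registry from a TSV file
#'
#' Expected columns: `id`, `query`, `enabled` (0/1). Lines starting with `#`
#' are comments.
#'
#' @param path Registry file path.
#' @return A [motif_registry()].
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]  # '#' is a motif wildcard, so
  df <- utils::read.delim(text = lines,        # only whole-line comments
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer"))
  motifs <- lapply(seq_len(nrow(df)), function(i) {
    parse_motif(df$query[i], id = df$id[i], enabled = df$enabled[i] == 1L)
  })
  motif_registry(motifs, provenance = path)
}

#' The shipped sea anemone cysteine-scaffold motif registry
#'
#' Fifteen screening lines over SRDA("C.") patterns covering the known
#' cysteine scaffolds of sea anemone toxins, plus the compound motif K
#' (at least 6 lysines and at most 2 cysteines per fragment) targeting
#' cysteine-free cytolysins. The two degenerate lines `"###."` (motif 0)
#' and `"##C"` (motif 14) proved too unspecific for bank mining and ship
#' disabled; motif K is enabled in their place.
#'
#' @return A [motif_registry()].
#' @examples
#' reg <- default_registry()
#' reg$motifs[["motif 1"]]$line
#' @export
default_registry <- function() {
  path <- system.file("extdata", "anemone_motifs.tsv", package = "srda",
                      mustWork = TRUE)
  read_registry(path)
}

#' Match a screening-line motif against a pattern string
#'
#' Matching is character-level with VBA `Like` semantics applied as a
#' substring search (implicit `'*'` at both ends): `'?'` matches any one
#' character, `'#'` any one digit, `'*'` any run of zero or more characters;
#' letters, digits and `'.'` are literal. The leftmost match is reported.
#'
#' @param q A line [parse_motif()] object (or screening-line text).
#' @param pattern Character vector of pattern strings.
#' @return A data.frame with columns `motif_id`, `matched`, `start`, `end`
#'   (1-based span within the pattern text; NA when unmatched).
#' @examples
#' match_motif("###.", "175.")$matched
#' match_motif("C1C##C6C#CC", "22C1C13C6C2CC7.")
#' @export
match_motif <- function(q, pattern) {
  if (is.character(q)) q <- parse_motif(q)
  stopifnot(inherits(q, "srda_motif"))
  if (q$type != "line") {
    stop("match_motif requires a line motif; use match_compound for '",
         q$id, "'", call. = FALSE)
  }
  m <- .cpp_like_match(q$line, pattern)
  data.frame(motif_id = rep(q$id, nrow(m)),
             matched = !is.na(unname(m[, 1])),
             start = unname(m[, 1]), end = unname(m[, 2]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Match a compound (residue-count) motif against a fragment sequence
#'
#' @param q A compound [parse_motif()] object.
#' @param fragment_seq Character vector of fragment amino acid sequences.
#' @return A data.frame with columns `motif_id`, `matched`.
#' @examples
#' k <- parse_motif("K>=6 AND C<=2", id = "motif K")
#' match_compound(k, "MKKKAKKKCA.")$matched
#' @export
match_compound <- function(q, fragment_seq) {
  stopifnot(inherits(q, "srda_motif"), q$type == "compound")
  ok <- rep(TRUE, length(fragment_seq))
  for (p in q$predicates) {
    n <- nchar(gsub(paste0("[^", p$residue, "]"), "", fragment_seq))
    ok <- ok & if (p$op == ">=") n >= p$threshold else n <= p$threshold
  }
  data.frame(motif_id = rep(q$id, length(ok)), matched = ok,
             stringsAsFactors = FALSE)
}

#' Remove stop symbols from a motif (protein-mode variant)
#'
#' Protein reference databases hold mature sequences without translation
#' stops, so the terminal `'.'` of EST-mode screening lines is eliminated
#' before scanning them. Compound motifs are returned unchanged.
#'
#' @param q An `srda_motif`.
#' @return The motif with all `'.'` removed from its line.
#' @examples
#' strip_stops(parse_motif("C1C##C9C#CC#."))$line  # "C1C##C9C#CC#"
#' @export
strip_stops <- function(q) {
  if (is.character(q)) q <- parse_motif(q)
  stopifnot(inherits(q, "srda_motif"))
  if (q$type != "line") return(q)
  q$line <- gsub(".", "", q$line, fixed = TRUE)
  q
}

#' Derive a consensus screening line from training patterns
#'
#' Greedy consensus over tokenized patterns: tokens identical across the set
#' are kept literal; Count tokens that differ but share a digit length
#' become that many `'#'`; structurally divergent stretches collapse into a
#' single `'*'`. Patterns are canonicalized by lexicographic sort first, so
#' the result is independent of input order.
#'
#' @param patterns Character vector of at least one pattern string.
#' @return The consensus screening-line text.
#' @examples
#' generalize_patterns(c("C1C12C6C2CC", "C1C13C6C3CC"))  # "C1C##C6C#CC"
#' generalize_patterns(c("C5C", "C12C"))                 # "C*C"
#' @export
generalize_patterns <- function(patterns) {
  if (length(patterns) == 0L) {
    stop("generalize_patterns needs at least one pattern", call. = FALSE)
  }
  patterns <- sort(unique(patterns))
  toks <- lapply(patterns, tokenize_pattern)
  paste(Reduce(.consensus_pair, toks[-1], toks[[1]]), collapse = "")
}

# classify a token of a (possibly already generalized) pattern
.tok_kind <- function(t) {
  if (t == "*") "gap"
  else if (grepl("^#+$", t)) "hash"
  else if (grepl("^[0-9]+$", t)) "count"
  else "key"
}

# Consensus of two token lists. Exactly-matching key tokens anchor a simple
# alignment; between anchors, a single count-like token on both sides merges
# to '#'-runs when the digit lengths agree, and anything else becomes '*'.
.consensus_pair <- function(a, b) {
  ka <- vapply(a, .tok_kind, "")
  kb <- vapply(b, .tok_kind, "")
  # LCS over key tokens only (counts are merged between anchors)
  ia <- which(ka == "key")
  ib <- which(kb == "key")
  la <- length(ia)
  lb <- length(ib)
  L <- matrix(0L, la + 1L, lb + 1L)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      L[i + 1L, j + 1L] <- if (a[ia[i]] == b[ib[j]]) L[i, j] + 1L
                           else max(L[i, j + 1L], L[i + 1L, j])
    }
  }
  # backtrack
  pairs <- matrix(integer(0), ncol = 2)
  i <- la; j <- lb
  while (i > 0L && j > 0L) {
    if (a[ia[i]] == b[ib[j]] && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      pairs <- rbind(c(ia[i], ib[j]), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  merge_between <- function(sa, sb) {
    # sa, sb: token index ranges (possibly empty) between two anchors
    ta <- a[sa]; tb <- b[sb]
    if (length(ta) == 0L && length(tb) == 0L) return(character(0))
    if (length(ta) == 1L && length(tb) == 1L) {
      if (ta == tb) return(ta)
      kaa <- .tok_kind(ta); kbb <- .tok_kind(tb)
      if (kaa %in% c("count", "hash") && kbb %in% c("count", "hash") &&
          nchar(ta) == nchar(tb)) {
        return(strrep("#", nchar(ta)))
      }
    }
    "*"
  }
  out <- character(0)
  prev_a <- 0L; prev_b <- 0L
  if (nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      ga <- seq_len(pairs[r, 1] - prev_a - 1L) + prev_a
      gb <- seq_len(pairs[r, 2] - prev_b - 1L) + prev_b
      out <- c(out, merge_between(ga, gb), a[pairs[r, 1]])
      prev_a <- pairs[r, 1]; prev_b <- pairs[r, 2]
    }
  }
  ga <- if (prev_a < length(a)) (prev_a + 1L):length(a) else integer(0)
  gb <- if (prev_b < length(b)) (prev_b + 1L):length(b) else integer(0)
  out <- c(out, merge_between(ga, gb))
  # collapse adjacent '*'
  keep <- !(out == "*" & c("", out[-length(out)]) == "*")
  out[keep]
}

#' Evaluate motif specificity on a labeled sequence set
#'
#' Scans each sequence with every enabled motif and tabulates, per motif,
#' the number of distinct sequences retrieved, the count within the target
#' group, and the specificity as integer percent (100 * target / total).
#' A final `distinct` row counts the union across motifs.
#'
#' @param registry A [motif_registry()].
#' @param seqs Named character vector of amino acid sequences.
#' @param groups Character vector of group labels, parallel to `seqs`.
#' @param target The label counted as the target group.
#' @param mode `"protein"` (stops stripped from motifs; sequences must be
#'   stop-free) or `"est"` (sequences are stop-terminated fragments).
#' @param spec [key_spec()] used for conversion.
#' @return A data.frame with columns `motif_id`, `total`, `target`,
#'   `specificity_pct`.
#' @export
evaluate_specificity <- function(registry, seqs, groups, target,
                                 mode = c("protein", "est"),
                                 spec = key_spec("C.")) {
  mode <- match.arg(mode)
  stopifnot(inherits(registry, "motif_registry"),
            length(seqs) == length(groups), length(groups) > 0L)
  hits <- if (mode == "protein") {
    scan_protein_set(seqs, registry, spec)
  } else {
    patterns <- srda_convert(seqs, spec)
    do.call(rbind, lapply(.enabled_motifs(registry), function(q) {
      matched <- if (q$type == "line") {
        match_motif(q, patterns)$matched
      } else {
        match_compound(q, seqs)$matched
      }
      data.frame(record_id = names(seqs)[matched], motif_id = q$id,
                 stringsAsFactors = FALSE)
    }))
  }
  per_motif <- lapply(.enabled_motifs(registry), function(q) {
    ids <- unique(hits$record_id[hits$motif_id == q$id])
    tot <- length(ids)
    tgt <- sum(groups[match(ids, names(seqs))] == target)
    data.frame(motif_id = q$id, total = tot, target = tgt,
               specificity_pct = if (tot > 0L) round(100 * tgt / tot) else NA,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(per_motif, make.row.names = FALSE))
  ids <- unique(hits$record_id)
  res <- rbind(res, data.frame(
    motif_id = "distinct", total = length(ids),
    target = sum(groups[match(ids, names(seqs))] == target),
    specificity_pct = NA, stringsAsFactors = FALSE))
  res
}

.enabled_motifs <- function(registry) {
  Filter(function(m) isTRUE(m$enabled), registry$motifs)
}
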