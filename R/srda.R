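# Alphabet accepted on the amino acid side: 20 standard residues, 'X' for an
# ambiguous codon, '.' for a translation stop.
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.AA_ALPHABET <- c(.AA20, "X", ".")

#' Key-residue specification for SRDA conversion
#'
#' The key residues are the residues whose positions are preserved by the
#' conversion; everything else is collapsed into counts. Translation-stop
#' symbols (`'.'`) are carried by a separate flag, written in the field's
#' notation as e.g. `SRDA("C.")` vs `SRDA("C")`.
#'
#' @param keys Either a character vector of single-letter residue codes, or
#'   a single string such as `"C"`, `"CK"` or `"C."` (a trailing `'.'` sets
#'   `include_stop`).
#' @param include_stop Treat `'.'` as a key symbol. Defaults to `TRUE` when
#'   `keys` ends in `'.'`, otherwise `FALSE`.
#' @return An object of class `key_spec`.
#' @examples
#' key_spec("C.")          # cysteines + stops
#' key_spec(c("C", "K"))   # two key residues, no stops
#' @export
key_spec <- function(keys = "C.", include_stop = NULL) {
  if (length(keys) == 1L && nchar(keys) != 1L) {
    keys <- strsplit(keys, "")[[1]]
  }
  has_dot <- "." %in% keys
  keys <- setdiff(toupper(keys), ".")
  if (is.null(include_stop)) include_stop <- has_dot
  if (length(keys) == 0L && !include_stop) {
    stop("key_spec needs at least one key residue or include_stop = TRUE",
         call. = FALSE)
  }
  bad <- setdiff(keys, .AA20)
  if (length(bad) > 0L) {
    stop("invalid key residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(keys = keys, include_stop = include_stop),
            class = "key_spec")
}

#' @export
print.key_spec <- function(x, ...) {
  cat(sprintf("SRDA key spec (\"%s%s\")\n",
              paste(x$keys, collapse = ""),
              if (x$include_stop) "." else ""))
  invisible(x)
}

.key_symbols <- function(spec) {
  c(spec$keys, if (spec$include_stop) ".")
}

#' Convert amino acid sequences into SRDA pattern strings
#'
#' Left-to-right scan: key residues (and `'.'` when the spec includes stops)
#' are emitted verbatim; each maximal run of non-key residues is emitted as
#' its length in plain decimal. Runs of length zero emit nothing, so
#' adjacent key residues are juxtaposed (`"CC"`). A trailing non-key run is
#' emitted as a trailing number. `'X'` (ambiguous codon) counts as a
#' nonconserved residue.
#'
#' @param seq Character vector of amino acid sequences (may contain `'.'`).
#' @param spec A [key_spec()].
#' @return Character vector of pattern strings, same length as `seq`.
#' @examples
#' srda_convert("MKACCGA", key_spec("C"))        # "3CC2"
#' srda_convert("ACADCA.", key_spec("C."))       # "1C3C1."
#' srda_convert("MKKAAK.", key_spec("K."))       # "1KK2K."
#' @export
srda_convert <- function(seq, spec = key_spec("C.")) {
  stopifnot(inherits(spec, "key_spec"))
  keyset <- .key_symbols(spec)
  pat <- paste0("[^", gsub("\\.", "\\\\.", paste(.AA_ALPHABET, collapse = "")),
                "]")
  bad <- regexpr(pat, seq)
  if (any(bad != -1L)) {
    i <- which(bad != -1L)[1L]
    stop("invalid character '", substr(seq[i], bad[i], bad[i]),
         "' at position ", bad[i], " of sequence ", i, call. = FALSE)
  }
  vapply(seq, function(s) {
    if (nchar(s) == 0L) return("")
    ch <- strsplit(s, "")[[1]]
    isk <- ch %in% keyset
    r <- rle(isk)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    parts <- character(length(r$lengths))
    for (i in seq_along(r$lengths)) {
      parts[i] <- if (r$values[i]) {
        paste(ch[starts[i]:ends[i]], collapse = "")
      } else {
        as.character(r$lengths[i])
      }
    }
    paste(parts, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Tokenize a pattern string
#'
#' Splits a pattern into Count and Key tokens: maximal digit runs become
#' single Count tokens, everything else one Key token per character.
#' Joining the tokens reconstructs the input text exactly.
#'
#' @param text A single pattern string.
#' @return Character vector of tokens; counts keep their decimal text.
#' @examples
#' tokenize_pattern("3CC2")  # "3" "C" "C" "2"
#' tokenize_pattern("12C.")  # "12" "C" "."
#' @export
tokenize_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) == 0L) return(character(0))
  if (grepl("(^|[^0-9])0", text)) {
    stop("leading-zero count in pattern: ", text, call. = FALSE)
  }
  m <- gregexpr("[0-9]+|[^0-9]", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (paste(toks, collapse = "") != text) {
    stop("pattern text failed to tokenize: ", text, call. = FALSE)
  }
  toks
}

#' Residue counts of an amino acid sequence
#'
#' Exact multiset counts of the residues; the stop symbol `'.'` is excluded.
#'
#' @param seq A single amino acid string.
#' @return Named integer vector, one entry per residue present.
#' @examples
#' residue_counts("KKCK.")  # K: 3, C: 1
#' @export
residue_counts <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(gsub(".", "", seq, fixed = TRUE), "")[[1]]
  if (length(ch) == 0L) return(integer(0))
  tab <- table(ch)
  stats::setNames(as.integer(tab), names(tab))
}
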