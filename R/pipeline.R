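#' Run the full SRDA mining pipeline on an EST bank
#'
#' Chains the analysis stages: six-frame translation, stop-bounded fragment
#' extraction, SRDA conversion, screening-line matching, signal-peptide
#' filtering, mature-domain assignment and deduplication. Analysis is fully
#' deterministic. When `out_dir` is given, writes `hits.tsv`,
#' `precursors.fasta` and `report.tsv` (all atomically).
#'
#' @param bank A `DNAStringSet` or path to a FASTA bank.
#' @param registry A [motif_registry()].
#' @param spec A [key_spec()].
#' @param min_len Minimum fragment length in residues, see [scan_bank()].
#' @param params A [signal_params()].
#' @param signalp_path Optional SignalP short-format file whose calls
#'   override the internal heuristic (ids `record_id|frame|aa_start`).
#' @param out_dir Optional output directory (created if absent).
#' @param verbose Log per-stage counts to stderr.
#' @return A list: `hits`, `calls` (deduplicated), `all_calls`, `report`.
#' @examples
#' gen <- generate_bank(generator_config(n_noise = 10,
#'   planted_per_motif = c("motif 1" = 2), n_decoy_split = 0,
#'   n_decoy_nosignal = 0, seed = 3))
#' res <- run_pipeline(gen$bank, min_len = 30)
#' res$report
#' @export
run_pipeline <- function(bank, registry = default_registry(),
                         spec = key_spec("C."), min_len = 0L,
                         params = signal_params(), signalp_path = NULL,
                         out_dir = NULL, verbose = FALSE) {
  if (!is.null(signalp_path) && !file.exists(signalp_path)) {
    stop("SignalP file not found: ", signalp_path, call. = FALSE)
  }
  signalp <- if (!is.null(signalp_path)) load_signalp_output(signalp_path)
             else NULL
  say <- function(...) if (verbose) message(sprintf(...))
  scan <- scan_bank(bank, registry, spec, min_len)
  say("scan: %d hits over %d records", nrow(scan$hits),
      length(unique(scan$hits$record_id)))
  called <- call_precursors(scan$hits, params, signalp, registry)
  say("signal: %d accepted calls; dedup: %d unique mature domains",
      nrow(called$all_calls), nrow(called$calls))
  res <- list(hits = scan$hits, calls = called$calls,
              all_calls = called$all_calls, report = called$report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(res$hits, file.path(out_dir, "hits.tsv"))
    .write_tsv(res$report, file.path(out_dir, "report.tsv"))
    if (nrow(res$calls) > 0L) {
      write_precursors(res$calls, file.path(out_dir, "precursors.fasta"))
    }
  }
  res
}

.write_tsv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}
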