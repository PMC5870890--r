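# Demultiplexing: segregate sample reads by comparing each index read
# against the key. Reads and index reads are positionally paired (read i of
# R1 goes with read i of I1, as emitted by Illumina bcl conversion).

hamming_to <- function(strings, target) {
  # all strings assumed the same nchar as target
  n <- length(strings)
  if (n == 0) return(integer(0))
  w <- nchar(target)
  m <- matrix(utf8ToInt(paste(strings, collapse = "")), nrow = w)
  colSums(m != utf8ToInt(target))
}

#' Demultiplex reads by index read
#'
#' Assigns read `i` to the sample whose key index equals the first
#' `nchar(index)` bases of index read `i`. With `max_mismatches = 0`
#' (the default) matching is exact; with a positive tolerance a read is
#' assigned only when a single key entry is strictly closest within the
#' tolerance — ties leave the read unassigned. Unassigned reads are counted,
#' not kept.
#'
#' @param reads Tibble of sample reads (`identifier`, `sequence`, `quality`).
#' @param index_reads Tibble of index reads, positionally paired with
#'   `reads`. Index reads may carry extra cycles beyond the index length;
#'   only the first `nchar(index)` bases are compared.
#' @param key Demultiplexing key as returned by [parse_demux_key()].
#' @param max_mismatches Maximum Hamming distance for an assignment.
#' @return An object of class `demux_result`: a list with `per_sample`
#'   (named list of read tibbles, one entry per key row, possibly empty),
#'   `unassigned_count` and `total_count`.
#' @export
demultiplex <- function(reads, index_reads, key, max_mismatches = 0L) {
  if (nrow(reads) != nrow(index_reads)) {
    stop(sprintf("read stream (%d) and index stream (%d) have different lengths",
                 nrow(reads), nrow(index_reads)), call. = FALSE)
  }
  idx_len <- nchar(key$index_sequence[1])
  prefix <- substr(index_reads$sequence, 1L, idx_len)
  if (max_mismatches == 0L) {
    assignment <- match(prefix, key$index_sequence)
  } else {
    d <- vapply(key$index_sequence, function(k) hamming_to(prefix, k),
                numeric(nrow(reads)))
    d <- matrix(d, nrow = nrow(reads))
    if (nrow(reads) == 0) {
      assignment <- integer(0)
    } else {
      best <- apply(d, 1, which.min)
      bestd <- d[cbind(seq_len(nrow(d)), best)]
      unique_best <- rowSums(d == bestd) == 1
      assignment <- ifelse(bestd <= max_mismatches & unique_best, best, NA_integer_)
    }
  }
  per_sample <- lapply(seq_len(nrow(key)), function(j) {
    reads[which(!is.na(assignment) & assignment == j), , drop = FALSE]
  })
  names(per_sample) <- key$sample_name
  res <- list(per_sample = per_sample,
              unassigned_count = sum(is.na(assignment)),
              total_count = nrow(reads))
  stopifnot(sum(vapply(per_sample, nrow, 0L)) + res$unassigned_count ==
              res$total_count)
  class(res) <- "demux_result"
  res
}

#' @export
print.demux_result <- function(x, ...) {
  cat("Demultiplexing result:", x$total_count, "reads,",
      x$unassigned_count, "unassigned\n")
  for (s in names(x$per_sample)) {
    cat(sprintf("  %s: %d reads\n", s, nrow(x$per_sample[[s]])))
  }
  invisible(x)
}

#' Demultiplex FASTQ files on disk
#'
#' File-level wrapper around [demultiplex()]: reads the R1/I1 pair and the
#' key, writes `<sample_name>.fastq` into `out_dir` for every key entry
#' (empty files for samples with no reads), and appends per-sample counts to
#' a log.
#'
#' @param r1_path,i1_path Paths to sample reads and index reads FASTQ.
#' @param key_path Path to the tab-separated demultiplexing key.
#' @param out_dir Output directory (created if needed).
#' @param max_mismatches Passed to [demultiplex()].
#' @param log_path Optional path for the demultiplexing log.
#' @return The `demux_result`, invisibly.
#' @export
demultiplex_files <- function(r1_path, i1_path, key_path, out_dir,
                              max_mismatches = 0L,
                              log_path = file.path(out_dir, "demultiplexLog.txt")) {
  key <- parse_demux_key(key_path)
  res <- demultiplex(read_fastq(r1_path), read_fastq(i1_path), key,
                     max_mismatches = max_mismatches)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in key$sample_name) {
    write_fastq(res$per_sample[[s]], file.path(out_dir, paste0(s, ".fastq")))
  }
  log <- c(sprintf("stage=demux total_reads=%d unassigned=%d max_mismatches=%d",
                   res$total_count, res$unassigned_count, max_mismatches),
           sprintf("stage=demux sample=%s reads=%d", key$sample_name,
                   vapply(res$per_sample, nrow, 0L)))
  writeLines(log, log_path)
  invisible(res)
}
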