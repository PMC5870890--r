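# Adapter trimming and UMI-based duplicate collapsing.
#
# Library molecules read as: insert + 6-nt random hexamer (UMI) + constant 3'
# adapter. Locating the adapter exposes the precisely captured RNA 3' end;
# collapsing identical insert+UMI strings removes PCR duplicates so every
# surviving record corresponds to a distinct RNA molecule.

#' Constant portion of the pre-adenylated 3' adapter oligo
#' @export
CRRNA_ADAPTER <- "AGATCGGAAGAGCACACGTCT"

#' Locate the 3' adapter in reads
#'
#' Returns the 0-based start of the leftmost acceptable adapter match in each
#' sequence. A match at position `p` aligns the first
#' `k = min(nchar(adapter), nchar(seq) - p)` adapter bases against the read
#' and is acceptable when `k >= min_overlap` and it has at most
#' `floor(max_error_rate * k)` substitutions; partial matches must (and by
#' construction do) reach the read 3' end. Indels are not modeled.
#'
#' @param sequences Character vector of read sequences.
#' @param adapter Adapter sequence (default: the constant portion of the
#'   protocol's 3' adapter oligo).
#' @param max_error_rate Maximum substitution fraction per aligned length.
#' @param min_overlap Minimum aligned adapter bases at the read 3' end.
#' @return Integer vector of 0-based match positions, `NA` where no
#'   acceptable match exists.
#' @export
locate_adapter <- function(sequences, adapter = CRRNA_ADAPTER,
                           max_error_rate = 0.1, min_overlap = 3L) {
  if (!is.character(adapter) || length(adapter) != 1 || nchar(adapter) == 0) {
    stop("adapter must be a single non-empty string", call. = FALSE)
  }
  locate_adapter_cpp(as.character(sequences), adapter, max_error_rate,
                     as.integer(min_overlap))
}

#' Trim the 3' adapter from reads
#'
#' Keeps, for each read in which the adapter is found at offset `p >= 7`, the
#' prefix before the adapter (the insert plus the 6-nt UMI; at least one
#' insert base). Reads with no acceptable adapter match, or in which the
#' prefix would be shorter than 7 nt, are discarded and counted: without the
#' adapter the RNA 3' end is not captured and the UMI cannot be identified.
#'
#' @param reads Tibble with `identifier`, `sequence`, `quality`.
#' @inheritParams locate_adapter
#' @return A list with `trimmed` (tibble: `identifier`, `insert_plus_umi`,
#'   `adapter_offset`, `quality` truncated to the kept prefix) and `stats`
#'   (named counts: `input`, `adapter_found`, `no_adapter`, `too_short`).
#' @export
trim_reads <- function(reads, adapter = CRRNA_ADAPTER, max_error_rate = 0.1,
                       min_overlap = 3L) {
  p <- locate_adapter(reads$sequence, adapter, max_error_rate, min_overlap)
  found <- !is.na(p)
  keep <- found & p >= 7L
  trimmed <- tibble::tibble(
    identifier = reads$identifier[keep],
    insert_plus_umi = substr(reads$sequence[keep], 1L, p[keep]),
    adapter_offset = as.integer(p[keep]),
    quality = substr(reads$quality[keep], 1L, p[keep])
  )
  list(trimmed = trimmed,
       stats = c(input = nrow(reads),
                 adapter_found = sum(found),
                 no_adapter = sum(!found),
                 too_short = sum(found & p < 7L)))
}

#' Split insert and UMI
#'
#' The random hexamer ligated with the 3' adapter occupies the last 6 bases
#' of the trimmed prefix; the remainder is the RNA insert (first base = RNA
#' 5' end, last base = RNA 3' end).
#'
#' @param insert_plus_umi Character vector, each element at least 7 nt.
#' @return A list with character vectors `insert` and `umi`.
#' @export
strip_umi <- function(insert_plus_umi) {
  n <- nchar(insert_plus_umi)
  if (any(n <= 6)) {
    stop("insert_plus_umi must be longer than 6 nt (UMI plus at least one insert base)",
         call. = FALSE)
  }
  list(insert = substr(insert_plus_umi, 1L, n - 6L),
       umi = substr(insert_plus_umi, n - 5L, n))
}

#' Collapse PCR duplicates by exact insert+UMI identity
#'
#' Groups trimmed reads by their exact `insert_plus_umi` string (no mismatch
#' tolerance: the hexamer makes distinct molecules distinct by construction),
#' emits one record per distinct string with the group size as `count`, then
#' splits off the UMI. Output order is order of first occurrence; the
#' identifier and quality of the first read in each group are carried.
#'
#' @param trimmed Tibble as produced by [trim_reads()] (`insert_plus_umi`
#'   required; `identifier` and `quality` used when present).
#' @return Tibble with `identifier`, `insert`, `umi`, `count`, `quality`
#'   (quality truncated to the insert).
#' @export
collapse_reads <- function(trimmed) {
  x <- trimmed$insert_plus_umi
  if (length(x) == 0) {
    return(tibble::tibble(identifier = character(0), insert = character(0),
                          umi = character(0), count = integer(0),
                          quality = character(0)))
  }
  f <- factor(x, levels = unique(x))
  first <- !duplicated(x)
  uniq <- x[first]
  parts <- strip_umi(uniq)
  ids <- if ("identifier" %in% names(trimmed)) trimmed$identifier[first] else
    paste0("collapsed", seq_along(uniq))
  qual <- if ("quality" %in% names(trimmed)) {
    substr(trimmed$quality[first], 1L, nchar(parts$insert))
  } else strrep("I", nchar(parts$insert))
  out <- tibble::tibble(identifier = ids, insert = parts$insert,
                        umi = parts$umi, count = tabulate(f, nbins = length(uniq)),
                        quality = qual)
  stopifnot(sum(out$count) == length(x))
  out
}

#' Trim and collapse one sample FASTQ on disk
#'
#' Runs [trim_reads()] then [collapse_reads()] on a demultiplexed sample
#' file, writing a FASTQ of UMI-stripped inserts whose headers encode the
#' duplicate count and UMI (`<id>_x<count>_umi:<UMI>`), plus log lines with
#' the stage counters.
#'
#' @param in_path Input per-sample FASTQ.
#' @param out_path Output trimmed+collapsed FASTQ (default: input path with
#'   `.fastq` replaced by `.trimmed.collapsed.fastq`).
#' @param max_read_length Reads longer than this are rejected with an error
#'   (guards against feeding the wrong run configuration; default 80 cycles).
#' @inheritParams locate_adapter
#' @param log_path Optional path; log lines are appended when given.
#' @return Tibble of collapsed reads, invisibly.
#' @export
trim_collapse_file <- function(in_path,
                               out_path = sub("\\.fastq$", ".trimmed.collapsed.fastq",
                                              in_path),
                               max_read_length = 80L,
                               adapter = CRRNA_ADAPTER, max_error_rate = 0.1,
                               min_overlap = 3L, log_path = NULL) {
  reads <- read_fastq(in_path)
  too_long <- nchar(reads$sequence) > max_read_length
  if (any(too_long)) {
    stop(sprintf("%s: read %d is longer (%d nt) than max_read_length = %d",
                 in_path, which(too_long)[1],
                 nchar(reads$sequence[which(too_long)[1]]), max_read_length),
         call. = FALSE)
  }
  tr <- trim_reads(reads, adapter, max_error_rate, min_overlap)
  collapsed <- collapse_reads(tr$trimmed)
  out <- tibble::tibble(
    identifier = sprintf("%s_x%d_umi:%s", collapsed$identifier,
                         collapsed$count, collapsed$umi),
    sequence = collapsed$insert,
    quality = collapsed$quality
  )
  write_fastq(out, out_path)
  if (!is.null(log_path)) {
    cat(sprintf(paste0("stage=trim_collapse file=%s input=%d adapter_found=%d",
                       " discarded_no_adapter=%d discarded_short=%d",
                       " distinct_after_collapse=%d\n"),
                basename(in_path), tr$stats[["input"]],
                tr$stats[["adapter_found"]], tr$stats[["no_adapter"]],
                tr$stats[["too_short"]], nrow(collapsed)),
        file = log_path, append = TRUE)
  }
  invisible(collapsed)
}
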