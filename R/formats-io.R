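# Readers/writers for the sequence formats the pipeline touches, parsers for
# the pipeline's own small text inputs, and basic sequence utilities.

#' Normalize a nucleotide sequence
#'
#' Uppercases and converts RNA U to DNA T, so RNA-derived sequences compare
#' equal to DNA-space references. Applied at every sequence entry point.
#'
#' @param x Character vector of sequences.
#' @param what Label used in error messages (e.g. the file being parsed).
#' @return Normalized character vector over the alphabet `{A,C,G,T,N}`.
#' @export
normalize_sequence <- function(x, what = "sequence") {
  x <- chartr("U", "T", toupper(x))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-nucleotide characters (record %d: %s)",
                 what, which(bad)[1], x[which(bad)[1]]), call. = FALSE)
  }
  x
}

strip_cr <- function(lines) sub("\r$", "", lines)

#' Read a 4-line FASTQ file
#'
#' Parses single-end Illumina FASTQ (Phred+33). Sequences are normalized to
#' uppercase with U converted to T. Qualities are carried verbatim but never
#' interpreted downstream (the pipeline performs no quality filtering).
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `identifier` (header without the leading
#'   `@`), `sequence`, and `quality`, one row per read, in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- strip_cr(readLines(path))
  if (length(lines) == 0) {
    return(tibble::tibble(identifier = character(0), sequence = character(0),
                          quality = character(0)))
  }
  if (length(lines) %% 4 != 0) {
    stop(sprintf("FASTQ parse error in %s: truncated record %d (file has %d lines)",
                 path, length(lines) %/% 4 + 1, length(lines)), call. = FALSE)
  }
  m <- matrix(lines, nrow = 4)
  bad_at <- !startsWith(m[1, ], "@")
  if (any(bad_at)) {
    stop(sprintf("FASTQ parse error in %s: record %d does not start with '@'",
                 path, which(bad_at)[1]), call. = FALSE)
  }
  bad_plus <- !startsWith(m[3, ], "+")
  if (any(bad_plus)) {
    stop(sprintf("FASTQ parse error in %s: record %d is missing the '+' line",
                 path, which(bad_plus)[1]), call. = FALSE)
  }
  sequence <- normalize_sequence(m[2, ], what = path)
  bad_len <- nchar(m[4, ]) != nchar(sequence)
  if (any(bad_len)) {
    stop(sprintf("FASTQ parse error in %s: record %d sequence/quality length mismatch",
                 path, which(bad_len)[1]), call. = FALSE)
  }
  tibble::tibble(identifier = substring(m[1, ], 2), sequence = sequence,
                 quality = m[4, ])
}

#' Write reads as 4-line FASTQ
#'
#' Inverse of [read_fastq()]: `read_fastq(write_fastq(x, p))` recovers `x`
#' for any valid set of reads.
#'
#' @param reads Tibble with columns `identifier`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("identifier", "sequence", "quality") %in% names(reads)))
  n <- nrow(reads)
  if (n == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- character(4L * n)
  out[seq(1, by = 4, length.out = n)] <- paste0("@", reads$identifier)
  out[seq(2, by = 4, length.out = n)] <- reads$sequence
  out[seq(3, by = 4, length.out = n)] <- "+"
  out[seq(4, by = 4, length.out = n)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] (so multi-line records are handled)
#' and applies the package's sequence normalization.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `identifier` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop(sprintf("FASTA parse error in %s: %s",
                                 path, conditionMessage(e)), call. = FALSE)
                  })
  tibble::tibble(identifier = names(set),
                 sequence = normalize_sequence(unname(as.character(set)),
                                               what = path))
}

#' Write sequences as FASTA
#'
#' FASTQ to FASTA conversion drops qualities only; identifiers are preserved.
#'
#' @param seqs Tibble with columns `identifier` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("identifier", "sequence") %in% names(seqs)))
  if (nrow(seqs) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- character(2L * nrow(seqs))
  out[seq(1, by = 2, length.out = nrow(seqs))] <- paste0(">", seqs$identifier)
  out[seq(2, by = 2, length.out = nrow(seqs))] <- seqs$sequence
  writeLines(out, path)
  invisible(path)
}

#' Convert a FASTQ file to FASTA
#'
#' @param in_path Input FASTQ path.
#' @param out_path Output FASTA path.
#' @return `out_path`, invisibly.
#' @export
fastq_to_fasta <- function(in_path, out_path) {
  write_fasta(read_fastq(in_path), out_path)
}

#' Parse a demultiplexing key
#'
#' The key is a tab-separated text file: first column the sample name, second
#' column the sequence expected in the index read (for Illumina TruSeq LT
#' libraries, the reverse complement of the indexing-primer barcode).
#'
#' @param path Path to the key file.
#' @return A tibble with columns `sample_name` and `index_sequence`, in file
#'   order.
#' @export
parse_demux_key <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- strip_cr(readLines(path))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("demultiplexing key is empty: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 2)) {
    stop(sprintf("demultiplexing key parse error in %s: line %d has %d columns (expected 2)",
                 path, which(nc != 2)[1], nc[which(nc != 2)[1]]), call. = FALSE)
  }
  sample_name <- trimws(vapply(parts, `[[`, "", 1))
  index_sequence <- normalize_sequence(trimws(vapply(parts, `[[`, "", 2)),
                                       what = path)
  if (any(!nzchar(sample_name))) {
    stop("demultiplexing key has an empty sample name: ", path, call. = FALSE)
  }
  if (anyDuplicated(sample_name)) {
    stop("demultiplexing key has duplicate sample names: ",
         sample_name[duplicated(sample_name)][1], call. = FALSE)
  }
  if (anyDuplicated(index_sequence)) {
    stop("demultiplexing key has duplicate index sequences: ",
         index_sequence[duplicated(index_sequence)][1], call. = FALSE)
  }
  if (length(unique(nchar(index_sequence))) != 1) {
    stop("demultiplexing key index sequences have unequal lengths: ", path,
         call. = FALSE)
  }
  tibble::tibble(sample_name = sample_name, index_sequence = index_sequence)
}

#' Parse the 3-line profiling parameters file
#'
#' Line 1: the CRISPR direct repeat (5'->3'). Line 2: the reference gene
#' sequence (sense strand) used for normalization. Line 3: an arbitrary
#' positive scaling factor for plot bar heights.
#'
#' The repeat must be at least 12 nt (the minimum processed-repeat length the
#' filter can retain) and the reference at least 25 nt (the substring length
#' used for reference counting); shorter inputs would make those rules
#' unreachable and are rejected.
#'
#' @param path Path to the parameters file.
#' @return A list with elements `repeat_seq`, `reference_seq`, `y_scale`.
#' @export
parse_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(strip_cr(readLines(path)))
  lines <- lines[nzchar(lines)]
  if (length(lines) != 3) {
    stop(sprintf("parameters file %s must have exactly 3 non-empty lines (found %d)",
                 path, length(lines)), call. = FALSE)
  }
  repeat_seq <- normalize_sequence(lines[1], what = paste0(path, " line 1"))
  reference_seq <- normalize_sequence(lines[2], what = paste0(path, " line 2"))
  y_scale <- suppressWarnings(as.numeric(lines[3]))
  if (is.na(y_scale) || y_scale <= 0) {
    stop("parameters file line 3 (y_scale) must be a positive number, got: ",
         lines[3], call. = FALSE)
  }
  if (nchar(repeat_seq) < 12) {
    stop("CRISPR repeat must be at least 12 nt (got ", nchar(repeat_seq),
         "): reads can only qualify with >= 12 repeat bases", call. = FALSE)
  }
  if (nchar(reference_seq) < 25) {
    stop("reference gene must be at least 25 nt (got ", nchar(reference_seq),
         "): reference reads are counted by 25-nt substring containment",
         call. = FALSE)
  }
  list(repeat_seq = repeat_seq, reference_seq = reference_seq, y_scale = y_scale)
}

#' Parse a spacer-endings file
#'
#' One 5-mer per line; `#` starts a comment; blank lines ignored. The set
#' holds the last five bases of every native spacer in the CRISPR array, used
#' to rescue short processed repeats that span the spacer-repeat junction.
#'
#' @param path Path to the spacer-endings file.
#' @return A character vector of unique uppercase 5-mers.
#' @export
parse_spacer_ends <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- strip_cr(readLines(path))
  entries <- trimws(sub("#.*$", "", raw))
  keep <- nzchar(entries)
  entries <- normalize_sequence(entries[keep], what = path)
  lineno <- which(keep)
  bad <- nchar(entries) != 5
  if (any(bad)) {
    stop(sprintf("spacer-endings file %s line %d: entry '%s' is not a 5-mer",
                 path, lineno[which(bad)[1]], entries[which(bad)[1]]),
         call. = FALSE)
  }
  unique(entries)
}

#' Reverse complement
#'
#' @param seq Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Reverse complement of each element (N maps to N).
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_sequence(seq)
  if (length(seq) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Library molarity from mass concentration
#'
#' Standard dsDNA conversion used when pooling samples for sequencing:
#' `nM = ng_per_ul / (660 g/mol/bp * mean_length_bp) * 1e6`.
#'
#' @param ng_per_ul Measured concentration in ng/microlitre.
#' @param mean_length_bp Average library length in base pairs.
#' @return Concentration in nM.
#' @export
library_molarity <- function(ng_per_ul, mean_length_bp) {
  if (any(!is.finite(mean_length_bp)) || any(mean_length_bp <= 0)) {
    stop("mean_length_bp must be positive", call. = FALSE)
  }
  if (any(!is.finite(ng_per_ul)) || any(ng_per_ul < 0)) {
    stop("ng_per_ul must be non-negative", call. = FALSE)
  }
  ng_per_ul / (660 * mean_length_bp) * 1e6
}
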