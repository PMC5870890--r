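# Repeat-anchored identification of crRNA-derived reads, reference-gene
# counting, and the normalized 3'-end profile.
#
# A mature crRNA carries its spacer followed by a 5' portion of the CRISPR
# direct repeat; the 3' end of the molecule falls inside the repeat at the
# Cas6 cleavage site. The filter anchors each read at the first occurrence
# of the repeat's first five bases (the seed), removes everything upstream,
# and requires the remaining "processed repeat" to be long enough (>= 12
# repeat bases) or rescued by the spacer-repeat junction (a known 5-nt
# spacer ending immediately upstream of the 5-nt seed, 10 matching bases
# across the junction), and to be an exact left-anchored prefix of the
# repeat. The length of the processed repeat marks the 3'-end position.

MIN_REPEAT_BASES <- 12L
SEED_LENGTH <- 5L
JUNCTION_SPACER_BASES <- 5L
REFERENCE_KMER <- 25L

#' Find the repeat seed in an insert
#'
#' Returns the 0-based position of the leftmost exact occurrence of the
#' repeat's first five bases in each insert; `NA` when absent. `N` never
#' matches.
#'
#' @param inserts Character vector of insert sequences.
#' @param repeat_seq The CRISPR direct repeat (>= 5 nt).
#' @return Integer vector of 0-based seed offsets, `NA` where not found.
#' @export
find_repeat_start <- function(inserts, repeat_seq) {
  if (nchar(repeat_seq) < SEED_LENGTH) {
    stop("repeat must be at least ", SEED_LENGTH, " nt", call. = FALSE)
  }
  seed <- substr(repeat_seq, 1L, SEED_LENGTH)
  if (grepl("N", seed, fixed = TRUE)) {
    # a seed containing N can never produce a valid match
    return(rep(NA_integer_, length(inserts)))
  }
  pos <- regexpr(seed, inserts, fixed = TRUE)
  ifelse(pos > 0L, as.integer(pos) - 1L, NA_integer_)
}

#' Spacer-repeat junction check
#'
#' True when the upstream sequence is at least 5 nt and its last 5 bases are
#' one of the native spacer endings.
#'
#' @param upstream Character vector: the insert bases before the seed.
#' @param spacer_ends Character vector of 5-mers ([parse_spacer_ends()]).
#' @return Logical vector.
#' @export
check_junction <- function(upstream, spacer_ends) {
  n <- nchar(upstream)
  n >= JUNCTION_SPACER_BASES &
    substr(upstream, n - JUNCTION_SPACER_BASES + 1L, n) %in% spacer_ends
}

#' Left-anchored fidelity check
#'
#' True when the processed repeat is an exact prefix of the CRISPR repeat
#' (it may be shorter, but it must match at the 5' end with no mismatches;
#' reads running through the repeat into the next spacer fail).
#'
#' @param processed_repeat Character vector.
#' @param repeat_seq The CRISPR direct repeat.
#' @return Logical vector.
#' @export
check_fidelity <- function(processed_repeat, repeat_seq) {
  n <- nchar(processed_repeat)
  n <= nchar(repeat_seq) & processed_repeat == substring(repeat_seq, 1L, n)
}

#' Qualify inserts as crRNA-derived reads
#'
#' Applies the full repeat-anchored filter to each insert:
#' 1. find the leftmost seed match; none: rejected (`no_seed`);
#' 2. split the insert at the seed into `upstream` (removed) and
#'    `processed_repeat` (seed to insert 3' end);
#' 3. if the processed repeat is shorter than 12 nt, require the junction
#'    rescue: at least 5 upstream bases (`upstream_too_short` otherwise)
#'    whose last 5 match a native spacer ending (`too_short_no_junction`
#'    otherwise); the qualifying route is then `junction`, else
#'    `repeat_length`;
#' 4. require the processed repeat to be an exact left-anchored prefix of
#'    the repeat (`fidelity_fail` otherwise).
#'
#' Only the leftmost seed occurrence is considered; a read failing fidelity
#' there is rejected rather than re-scanned at later occurrences.
#'
#' @param inserts Character vector of insert sequences.
#' @param repeat_seq The CRISPR direct repeat.
#' @param spacer_ends Character vector of native spacer-ending 5-mers.
#' @param identifiers Optional identifiers carried into the result.
#' @return Tibble with columns `identifier`, `insert`, `seed_offset`
#'   (0-based, `NA` if no seed), `upstream`, `processed_repeat`,
#'   `repeat_length` (length of the processed repeat), `route` (one of
#'   `repeat_length`, `junction`, `rejected`) and `reject_reason` (`NA` or
#'   one of `no_seed`, `too_short_no_junction`, `upstream_too_short`,
#'   `fidelity_fail`).
#' @export
qualify_reads <- function(inserts, repeat_seq, spacer_ends,
                          identifiers = NULL) {
  if (is.null(identifiers)) identifiers <- paste0("read", seq_along(inserts))
  if (length(inserts) == 0) {
    return(tibble::tibble(identifier = character(0), insert = character(0),
                          seed_offset = integer(0), upstream = character(0),
                          processed_repeat = character(0),
                          repeat_length = integer(0), route = character(0),
                          reject_reason = character(0)))
  }
  off <- find_repeat_start(inserts, repeat_seq)
  upstream <- ifelse(is.na(off), NA_character_, substr(inserts, 1L, off))
  processed <- ifelse(is.na(off), NA_character_,
                      substr(inserts, off + 1L, nchar(inserts)))
  plen <- ifelse(is.na(off), NA_integer_, nchar(processed))

  route <- rep("rejected", length(inserts))
  reason <- rep(NA_character_, length(inserts))
  reason[is.na(off)] <- "no_seed"

  short <- !is.na(off) & plen < MIN_REPEAT_BASES
  long_enough <- !is.na(off) & plen >= MIN_REPEAT_BASES
  junction_ok <- short & check_junction(ifelse(is.na(upstream), "", upstream),
                                        spacer_ends)
  reason[short & !junction_ok & nchar(upstream) < JUNCTION_SPACER_BASES] <-
    "upstream_too_short"
  reason[short & !junction_ok & nchar(upstream) >= JUNCTION_SPACER_BASES] <-
    "too_short_no_junction"

  candidate <- long_enough | junction_ok
  fid <- candidate & check_fidelity(ifelse(is.na(processed), "", processed),
                                    repeat_seq)
  reason[candidate & !fid] <- "fidelity_fail"
  route[fid & long_enough] <- "repeat_length"
  route[fid & junction_ok] <- "junction"

  tibble::tibble(identifier = identifiers, insert = inserts,
                 seed_offset = off, upstream = upstream,
                 processed_repeat = processed, repeat_length = plen,
                 route = route, reject_reason = reason)
}

#' Build the 25-mer index of a reference gene
#'
#' @param reference_seq Reference gene sequence (sense strand, >= 25 nt).
#' @return An object of class `reference_index` holding the set of all
#'   distinct 25-nt substrings.
#' @export
build_reference_index <- function(reference_seq) {
  n <- nchar(reference_seq)
  if (n < REFERENCE_KMER) {
    stop("reference gene must be at least ", REFERENCE_KMER, " nt (got ", n, ")",
         call. = FALSE)
  }
  starts <- seq_len(n - REFERENCE_KMER + 1L)
  kmers <- unique(substring(reference_seq, starts, starts + REFERENCE_KMER - 1L))
  structure(list(kmers = kmers, k = REFERENCE_KMER), class = "reference_index")
}

#' Test reads for reference-gene content
#'
#' A read counts as a reference read when any of its 25-nt windows occurs in
#' the reference gene (sense strand only: the library is strand-specific).
#' Reads shorter than 25 nt never count; each read contributes at most one.
#'
#' @param inserts Character vector of insert sequences.
#' @param index A `reference_index` from [build_reference_index()].
#' @return Logical vector.
#' @export
is_reference_read <- function(inserts, index) {
  stopifnot(inherits(index, "reference_index"))
  k <- index$k
  vapply(inserts, function(s) {
    n <- nchar(s)
    if (is.na(n) || n < k) return(FALSE)
    starts <- seq_len(n - k + 1L)
    any(substring(s, starts, starts + k - 1L) %in% index$kmers)
  }, logical(1), USE.NAMES = FALSE)
}

#' Build the normalized crRNA 3'-end profile
#'
#' Tallies qualified processed-repeat lengths (1..`nchar(repeat)`) and
#' normalizes each count to the reference-gene read count, scaled by
#' `y_scale`. The height at position `l` is the level of crRNA molecules
#' whose 3' end lies at repeat base `l`, relative to the reference gene.
#'
#' @param matches Tibble from [qualify_reads()].
#' @param n_reference Number of reference-gene reads in the same sample.
#' @param params Pipeline parameters ([parse_params()]).
#' @return An object of class `crrna_profile`: list with `counts` (integer
#'   vector indexed 1..`nchar(repeat)`), `heights`, `n_reference`,
#'   `n_qualified`, `repeat_seq`, `y_scale`.
#' @export
build_profile <- function(matches, n_reference, params) {
  if (n_reference == 0) {
    stop(paste("no reference-gene reads found: normalization is undefined.",
               "Choose a reference gene that is detectably expressed in this dataset."),
         call. = FALSE)
  }
  lr <- nchar(params$repeat_seq)
  qualified <- matches$route != "rejected"
  lens <- matches$repeat_length[qualified]
  stopifnot(all(lens >= 1L & lens <= lr))
  counts <- tabulate(lens, nbins = lr)
  heights <- counts / n_reference * params$y_scale
  structure(list(counts = counts, heights = heights,
                 n_reference = as.integer(n_reference),
                 n_qualified = sum(qualified),
                 repeat_seq = params$repeat_seq, y_scale = params$y_scale),
            class = "crrna_profile")
}

#' @export
print.crrna_profile <- function(x, ...) {
  cat("crRNA 3'-end profile over a", nchar(x$repeat_seq), "nt repeat\n")
  cat("  qualified crRNA reads:", x$n_qualified, "\n")
  cat("  reference-gene reads: ", x$n_reference, "\n")
  top <- order(x$counts, decreasing = TRUE)[1:min(3, length(x$counts))]
  top <- top[x$counts[top] > 0]
  if (length(top)) {
    cat("  top 3'-end positions: ",
        paste(sprintf("%d (%d reads)", top, x$counts[top]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Profile as a per-base table
#'
#' @param profile A `crrna_profile`.
#' @return Tibble with `position` (1-based repeat coordinate), `base`,
#'   `raw_count`, `normalized_height`.
#' @export
profile_table <- function(profile) {
  lr <- nchar(profile$repeat_seq)
  tibble::tibble(position = seq_len(lr),
                 base = strsplit(profile$repeat_seq, "")[[1]],
                 raw_count = profile$counts,
                 normalized_height = profile$heights)
}

#' Render a profile as a bar chart plus TSV table
#'
#' One bar per repeat position, X tick labels the repeat bases, bar height
#' the normalized crRNA level with a 3' end at that base. The companion TSV
#' holds the same numbers so downstream analysis never parses images.
#'
#' @param profile A `crrna_profile`.
#' @param out_prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.<device>`.
#' @param device Plot file format, `"png"` or `"pdf"`.
#' @return Named character vector with the written `table` and `plot` paths,
#'   invisibly.
#' @export
render_profile <- function(profile, out_prefix, device = c("png", "pdf")) {
  device <- match.arg(device)
  tab <- profile_table(profile)
  tsv_path <- paste0(out_prefix, ".tsv")
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  plot_path <- paste0(out_prefix, ".", device)
  g <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$position,
                                         y = .data$normalized_height)) +
    ggplot2::geom_col(fill = "grey25", width = 0.8) +
    ggplot2::scale_x_continuous(breaks = tab$position, labels = tab$base,
                                expand = ggplot2::expansion(add = 0.6)) +
    ggplot2::labs(x = "CRISPR repeat sequence (5' to 3')",
                  y = "crRNA 3' ends (normalized to reference gene)") +
    ggplot2::theme_classic(base_size = 11) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(family = "mono"))
  ggplot2::ggsave(plot_path, g, width = max(6, nchar(profile$repeat_seq) * 0.22),
                  height = 3.5, dpi = 150)
  invisible(c(table = tsv_path, plot = plot_path))
}

#' Select FASTA files by keyword
#'
#' Returns the FASTA files in a directory whose base name contains `keyword`
#' as a literal substring, lexicographically ordered. An empty keyword
#' selects every FASTA file.
#'
#' @param directory Directory to scan.
#' @param keyword Literal substring to look for in file names.
#' @return Character vector of full paths (possibly empty).
#' @export
select_files_by_keyword <- function(directory, keyword = "") {
  if (!dir.exists(directory)) {
    stop("no such directory: ", directory, call. = FALSE)
  }
  files <- list.files(directory, pattern = "\\.(fasta|fa)$", full.names = TRUE)
  files <- files[grepl(keyword, basename(files), fixed = TRUE)]
  sort(files)
}

#' Profile one FASTA file of collapsed inserts
#'
#' Runs qualification and reference counting on every sequence in the file
#' and builds the normalized profile. Each collapsed record contributes one
#' molecule regardless of its pre-collapse duplicate count (collapsing
#' defines the molecule count); `weight_by_count = TRUE` re-weights by the
#' `_x<count>` header field for diagnostics.
#'
#' @param fasta_path Path to a FASTA of UMI-stripped inserts.
#' @param params Pipeline parameters ([parse_params()]).
#' @param spacer_ends Spacer-ending 5-mers ([parse_spacer_ends()]).
#' @param weight_by_count Weight reads by their collapsed duplicate count.
#' @return A list with `profile` (`crrna_profile`), `matches` (the
#'   [qualify_reads()] tibble with an `is_reference` column) and `stats`
#'   (named counts by route and rejection reason).
#' @export
profile_fasta <- function(fasta_path, params, spacer_ends,
                          weight_by_count = FALSE) {
  seqs <- read_fasta(fasta_path)
  matches <- qualify_reads(seqs$sequence, params$repeat_seq, spacer_ends,
                           identifiers = seqs$identifier)
  ref_index <- build_reference_index(params$reference_seq)
  matches$is_reference <- is_reference_read(seqs$sequence, ref_index)
  weights <- rep(1L, nrow(matches))
  if (weight_by_count) {
    m <- regmatches(seqs$identifier,
                    regexpr("_x([0-9]+)_umi:", seqs$identifier))
    w <- suppressWarnings(as.integer(sub("_x([0-9]+)_umi:", "\\1", m)))
    has <- grepl("_x[0-9]+_umi:", seqs$identifier)
    weights[has] <- w[!is.na(w)]
  }
  if (weight_by_count) {
    expanded <- matches[rep(seq_len(nrow(matches)), weights), , drop = FALSE]
    n_ref <- sum(weights[matches$is_reference])
    profile <- build_profile(expanded, n_ref, params)
  } else {
    profile <- build_profile(matches, sum(matches$is_reference), params)
  }
  stats <- c(total = nrow(matches),
             seed_found = sum(!is.na(matches$seed_offset)),
             qualified = sum(matches$route != "rejected"),
             route_repeat_length = sum(matches$route == "repeat_length"),
             route_junction = sum(matches$route == "junction"),
             rejected_no_seed = sum(matches$reject_reason %in% "no_seed"),
             rejected_too_short_no_junction =
               sum(matches$reject_reason %in% "too_short_no_junction"),
             rejected_upstream_too_short =
               sum(matches$reject_reason %in% "upstream_too_short"),
             rejected_fidelity_fail =
               sum(matches$reject_reason %in% "fidelity_fail"),
             reference = sum(matches$is_reference),
             reference_and_qualified =
               sum(matches$is_reference & matches$route != "rejected"))
  list(profile = profile, matches = matches, stats = stats)
}
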