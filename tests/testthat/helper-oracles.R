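# Independent brute-force oracles and small fixture builders used across
# the suite. The oracles deliberately share no code with the package paths
# they check.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_reads <- function(n, len_range = c(20, 60)) {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  tibble::tibble(
    identifier = paste0("rr", seq_len(n)),
    sequence = vapply(lens, rand_dna, ""),
    quality = vapply(lens, function(l) rand_qual(l), "")
  )
}

rand_qual <- function(l) {
  paste(sample(strsplit("!#$%&0123456789ABCDEFGHI", "")[[1]], l, replace = TRUE),
        collapse = "")
}

# direct per-offset mismatch-count adapter search (substitutions only)
oracle_locate <- function(seq, adapter, max_error_rate = 0.1, min_overlap = 3) {
  s <- utf8ToInt(seq); a <- utf8ToInt(adapter)
  ls <- length(s); la <- length(a)
  p <- 0L
  while (p + min_overlap <= ls) {
    k <- min(la, ls - p)
    if (sum(s[(p + 1):(p + k)] != a[1:k]) <= floor(max_error_rate * k)) return(p)
    p <- p + 1L
  }
  NA_integer_
}

# base-by-base complement, independent of Biostrings
oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(comp[strsplit(seq, "")[[1]]])), collapse = "")
}

# naive double loop: is any 25-window of the read a substring of reference?
oracle_is_reference <- function(read, reference, k = 25) {
  n <- nchar(read)
  if (n < k) return(FALSE)
  for (i in 1:(n - k + 1)) {
    if (grepl(substr(read, i, i + k - 1), reference, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# a directory of empty FASTA files named like the protocol's worked example
worked_example_fasta_dir <- function() {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  for (s in paste0("sample", 5:8)) {
    writeLines(c(">r1", "ACGT"), file.path(d, paste0(s, ".fasta")))
  }
  d
}

# small all-defaults simulated run shared by several tests
small_sim <- function(seed = 11, ...) {
  cfg <- sim_config(seed = seed, n_crrna = 200, n_reference = 60,
                    n_background = 60, ...)
  simulate_run(cfg)
}
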