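ADAPTER <- CRRNA_ADAPTER

test_that("locate_adapter finds exact and degenerate matches", {
  withr::local_seed(430)
  insert_umi <- paste0(rand_dna(14), "AAAAAA")  # 20 nt
  expect_equal(locate_adapter(paste0(insert_umi, ADAPTER)), 20L)

  # two substitutions over the full 21-nt alignment are within floor(0.1*21)
  mut <- ADAPTER
  substr(mut, 3, 3) <- "C"; substr(mut, 15, 15) <- "A"
  expect_equal(oracle_hamming(mut, ADAPTER), 2)
  seq2 <- paste0(insert_umi, mut)
  expect_equal(locate_adapter(seq2), oracle_locate(seq2, ADAPTER))
  expect_equal(locate_adapter(seq2), 20L)

  # a 2-base terminal adapter prefix is below min_overlap
  expect_true(is.na(locate_adapter(paste0(rand_dna(20), "AG"))))
  # but a 3-base terminal prefix qualifies
  expect_equal(locate_adapter(paste0(strrep("C", 20), "AGA")), 20L)
  expect_error(locate_adapter("ACGT", adapter = ""), "non-empty")
})

test_that("locate_adapter agrees with the brute-force oracle on random reads", {
  withr::local_seed(431)
  n <- 1000
  seqs <- character(n)
  for (i in seq_len(n)) {
    len <- sample(5:60, 1)
    s <- rand_dna(len)
    if (i %% 3 == 0) {
      # plant a (possibly mutated, possibly truncated) adapter copy
      p <- sample(0:(len - 3), 1)
      frag <- substr(ADAPTER, 1, min(nchar(ADAPTER), len - p))
      if (runif(1) < 0.5 && nchar(frag) > 1) {
        at <- sample(nchar(frag), 1)
        substr(frag, at, at) <- sample(c("A", "C", "G", "T"), 1)
      }
      s <- paste0(substr(s, 1, p), frag,
                  substr(s, p + nchar(frag) + 1, len))
    }
    seqs[i] <- s
  }
  got <- locate_adapter(seqs)
  want <- vapply(seqs, oracle_locate, 0L, adapter = ADAPTER, USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("trim_reads keeps the pre-adapter prefix and discards the rest", {
  reads <- tibble::tibble(
    identifier = c("keep", "no_adapter", "too_short"),
    sequence = c(paste0("ACGTACGT", "AAAAAA", ADAPTER),   # offset 14
                 strrep("C", 40),
                 paste0("ACGTAC", ADAPTER)),              # offset 6 < 7
    quality = strrep("I", c(8 + 6 + nchar(ADAPTER), 40, 6 + nchar(ADAPTER))))
  res <- trim_reads(reads)
  expect_equal(res$trimmed$identifier, "keep")
  expect_equal(res$trimmed$insert_plus_umi, "ACGTACGTAAAAAA")
  expect_equal(res$trimmed$adapter_offset, 14L)
  expect_equal(nchar(res$trimmed$quality), 14L)
  expect_equal(unname(res$stats),
               c(3L, 2L, 1L, 1L))  # input, adapter_found, no_adapter, too_short
})

test_that("strip_umi splits the terminal hexamer", {
  out <- strip_umi("ACGTAAAAAA")
  expect_equal(out$insert, "ACGT")
  expect_equal(out$umi, "AAAAAA")
  expect_equal(strip_umi("TAAAAAA")$insert, "T")
  expect_error(strip_umi("AAAAAA"), "longer than 6")
})

test_that("collapse_reads groups exact insert+UMI strings in first-seen order", {
  s1 <- "ACGTACGTAAAAAA"; s2 <- "TTTTACGTCCCCCC"
  trimmed <- tibble::tibble(identifier = c("a", "b", "c"),
                            insert_plus_umi = c(s1, s1, s2),
                            quality = strrep("I", nchar(c(s1, s1, s2))))
  out <- collapse_reads(trimmed)
  expect_equal(out$insert, c("ACGTACGT", "TTTTACGT"))
  expect_equal(out$umi, c("AAAAAA", "CCCCCC"))
  expect_equal(out$count, c(2L, 1L))
  expect_equal(out$identifier, c("a", "c"))
  expect_equal(sum(out$count), nrow(trimmed))

  # identical insert under different UMIs stays two molecules
  two <- tibble::tibble(insert_plus_umi = c("ACGTAAAAAA", "ACGTCCCCCC"))
  expect_equal(nrow(collapse_reads(two)), 2L)

  # collapsing an already-collapsed stream is the identity on sequences
  again <- collapse_reads(tibble::tibble(
    insert_plus_umi = paste0(out$insert, out$umi)))
  expect_equal(paste0(again$insert, again$umi), paste0(out$insert, out$umi))
  expect_true(all(again$count == 1L))
})

test_that("UMI stripping shortens every record by exactly six bases", {
  withr::local_seed(432)
  x <- vapply(sample(7:40, 50, replace = TRUE), rand_dna, "")
  out <- strip_umi(x)
  expect_equal(nchar(out$insert), nchar(x) - 6L)
  expect_true(all(nchar(out$umi) == 6L))
})

test_that("trimming and collapsing recover simulator ground truth exactly", {
  run <- small_sim(seed = 33, substitution_rate = 0)
  tr <- trim_reads(run$reads)
  expect_equal(nrow(tr$trimmed), nrow(run$reads))
  gt <- run$ground_truth[match(tr$trimmed$identifier, run$ground_truth$read_id), ]
  expect_equal(tr$trimmed$insert_plus_umi, paste0(gt$insert, gt$umi))

  collapsed <- collapse_reads(tr$trimmed)
  expect_equal(sum(collapsed$count), nrow(run$reads))
  truth_counts <- table(paste0(run$ground_truth$insert, run$ground_truth$umi))
  expect_equal(collapsed$count,
               unname(as.integer(truth_counts[paste0(collapsed$insert,
                                                     collapsed$umi)])))
})

test_that("trim_collapse_file writes count/UMI headers and enforces read length", {
  d <- withr::local_tempdir()
  seq1 <- paste0("ACGTACGT", "AAAAAA", ADAPTER)
  reads <- tibble::tibble(identifier = c("a", "b"), sequence = c(seq1, seq1),
                          quality = strrep("I", nchar(c(seq1, seq1))))
  fq <- file.path(d, "s.fastq")
  write_fastq(reads, fq)
  out <- trim_collapse_file(fq, log_path = file.path(d, "log.txt"))
  written <- read_fastq(file.path(d, "s.trimmed.collapsed.fastq"))
  expect_equal(written$identifier, "a_x2_umi:AAAAAA")
  expect_equal(written$sequence, "ACGTACGT")
  expect_match(readLines(file.path(d, "log.txt")), "distinct_after_collapse=1")
  expect_error(trim_collapse_file(fq, max_read_length = 10L), "longer")
})
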