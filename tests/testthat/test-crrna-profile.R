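# Shared fixture: a 36-nt repeat starting GTTCA and spacer endings that do
# not occur in the constructed upstreams by accident.
REPEAT <- "GTTCACTGCCGTATAGGCAGCTAAGAAAGTCATCAC"
ENDS <- c("ACGTA", "TTGCA")
rp <- function(l) substr(REPEAT, 1, l)

test_that("find_repeat_start returns the leftmost exact seed match", {
  expect_equal(find_repeat_start(paste0("AAACGTA", rp(8)), REPEAT), 7L)
  expect_true(is.na(find_repeat_start("ACGTACGTACGT", REPEAT)))
  # two occurrences: leftmost wins
  expect_equal(find_repeat_start(paste0(rp(5), "AA", rp(5)), REPEAT), 0L)
  # N never matches the seed
  expect_true(is.na(find_repeat_start("GTTCN", REPEAT)))
  expect_true(is.na(find_repeat_start(sub("T", "N", "GTTCA"), REPEAT)))
})

test_that("check_junction needs five upstream bases ending in a spacer ending", {
  expect_true(check_junction("CCACGTA", ENDS))
  expect_false(check_junction("CCCCC", ENDS))
  expect_false(check_junction("CGTA", ENDS))    # only 4 upstream bases
  expect_true(check_junction("ACGTA", ENDS))
  expect_equal(check_junction(c("ACGTA", "TTTTT"), ENDS), c(TRUE, FALSE))
})

test_that("check_fidelity accepts exact left-anchored prefixes only", {
  expect_true(check_fidelity(rp(12), REPEAT))
  expect_true(check_fidelity(REPEAT, REPEAT))
  mism <- rp(12); substr(mism, 6, 6) <- "A"  # repeat base 6 is C
  expect_false(check_fidelity(mism, REPEAT))
  expect_false(check_fidelity(paste0(REPEAT, "A"), REPEAT))  # read-through
})

test_that("qualify_reads applies seed, length/junction, and fidelity in order", {
  m <- qualify_reads(
    c(paste0("CCCCC", rp(12)),          # >= 12 repeat bases
      paste0("ACGTA", rp(5)),           # junction rescue at l = 5
      paste0("CCCCC", rp(11)),          # short, upstream not a spacer ending
      paste0("ACGTA", rp(11)),          # short but junction rescues l = 11
      paste0("CGTA", rp(11)),           # short, only 4 upstream bases
      paste0("CCCCC", REPEAT, "AAAA"),  # read-through past the repeat
      strrep("T", 30)),                 # no seed anywhere
    REPEAT, ENDS)
  expect_equal(m$route, c("repeat_length", "junction", "rejected", "junction",
                          "rejected", "rejected", "rejected"))
  expect_equal(m$reject_reason,
               c(NA, NA, "too_short_no_junction", NA, "upstream_too_short",
                 "fidelity_fail", "no_seed"))
  expect_equal(m$repeat_length[1:4], c(12L, 5L, 11L, 11L))
  expect_equal(m$upstream[1], "CCCCC")
  expect_equal(m$processed_repeat[2], rp(5))
  # every qualified processed repeat is an exact prefix of the repeat
  q <- m[m$route != "rejected", ]
  expect_true(all(check_fidelity(q$processed_repeat, REPEAT)))
})

test_that("a fidelity failure at the leftmost seed is not re-scanned", {
  # seed occurs twice; the first copy is followed by off-repeat sequence,
  # the second would qualify, but only the leftmost anchors the read
  insert <- paste0("CCCCC", rp(5), "TTTTTTT", rp(14))
  m <- qualify_reads(insert, REPEAT, ENDS)
  expect_equal(m$seed_offset, 5L)
  expect_equal(m$route, "rejected")
  expect_equal(m$reject_reason, "fidelity_fail")
})

test_that("repeat-length qualification is monotone in processed length", {
  for (l in 12:nchar(REPEAT)) {
    m <- qualify_reads(paste0("CCCCC", rp(l)), REPEAT, ENDS)
    expect_equal(m$route, "repeat_length")
    expect_equal(m$repeat_length, l)
  }
})

test_that("reference index holds all distinct 25-mers", {
  expect_length(build_reference_index(strrep("ACGTG", 5))$kmers, 1L)
  idx30 <- build_reference_index(paste0(strrep("ACGTG", 5), "TTTTT"))
  expect_length(idx30$kmers, 6L)
  expect_length(build_reference_index(strrep("A", 30))$kmers, 1L)
  expect_error(build_reference_index(strrep("A", 24)), "25")
})

test_that("is_reference_read needs one exact 25-nt window", {
  withr::local_seed(441)
  reference <- rand_dna(80)
  idx <- build_reference_index(reference)
  expect_true(is_reference_read(substr(reference, 3, 27), idx))
  expect_false(is_reference_read(substr(reference, 3, 26), idx))  # 24 nt
  mut <- substr(reference, 3, 27)
  substr(mut, 13, 13) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 13, 13))[1]
  expect_false(is_reference_read(mut, idx))
})

test_that("is_reference_read agrees with the double-loop substring oracle", {
  withr::local_seed(442)
  reference <- rand_dna(120)
  idx <- build_reference_index(reference)
  reads <- character(300)
  for (i in seq_along(reads)) {
    if (i %% 2 == 0) {
      st <- sample(90, 1); ln <- sample(20:35, 1)
      r <- substr(reference, st, min(120, st + ln - 1))
      if (runif(1) < 0.3) substr(r, 5, 5) <- sample(c("A", "C", "G", "T"), 1)
      reads[i] <- paste0(rand_dna(sample(0:5, 1)), r)
    } else {
      reads[i] <- rand_dna(sample(15:45, 1))
    }
  }
  got <- is_reference_read(reads, idx)
  want <- vapply(reads, oracle_is_reference, TRUE, reference = reference,
                 USE.NAMES = FALSE)
  expect_equal(got, want)
})

test_that("build_profile normalizes counts to the reference gene", {
  params <- list(repeat_seq = REPEAT, reference_seq = strrep("ACGTG", 10),
                 y_scale = 1)
  matches <- qualify_reads(
    c(rep(paste0("CCCCC", rp(12)), 3), rep(paste0("CCCCC", rp(20)), 7)),
    REPEAT, ENDS)
  prof <- build_profile(matches, n_reference = 10, params)
  expect_equal(prof$counts[12], 3L)
  expect_equal(prof$counts[20], 7L)
  expect_equal(sum(prof$counts), prof$n_qualified)
  expect_equal(prof$heights[c(12, 20)], c(0.3, 0.7))
  params$y_scale <- 2
  prof2 <- build_profile(matches, n_reference = 10, params)
  expect_equal(prof2$heights, prof$heights * 2)
  prof3 <- build_profile(matches, n_reference = 5,
                         `[[<-`(params, "y_scale", 1))
  expect_equal(prof3$heights, prof$heights * 2)
  expect_error(build_profile(matches, n_reference = 0, params),
               "reference gene")
})

test_that("render_profile writes a per-base TSV and a plot file", {
  params <- list(repeat_seq = REPEAT, reference_seq = strrep("ACGTG", 10),
                 y_scale = 1)
  matches <- qualify_reads(paste0("CCCCC", rp(30)), REPEAT, ENDS)
  prof <- build_profile(matches, n_reference = 2, params)
  d <- withr::local_tempdir()
  paths <- render_profile(prof, file.path(d, "s8"), device = "pdf")
  tab <- utils::read.delim(paths[["table"]])
  expect_equal(nrow(tab), nchar(REPEAT))
  expect_equal(tab$base, strsplit(REPEAT, "")[[1]])
  expect_equal(tab$raw_count[30], 1L)
  expect_equal(tab$normalized_height[30], 0.5)
  expect_true(file.exists(paths[["plot"]]))

  # an all-zero profile still renders
  empty <- build_profile(qualify_reads(character(0), REPEAT, ENDS),
                         n_reference = 2, params)
  paths0 <- render_profile(empty, file.path(d, "empty"), device = "pdf")
  expect_equal(sum(utils::read.delim(paths0[["table"]])$raw_count), 0L)
})

test_that("select_files_by_keyword matches literal substrings of file names", {
  d <- worked_example_fasta_dir()
  expect_equal(basename(select_files_by_keyword(d, "8")), "sample8.fasta")
  expect_equal(basename(select_files_by_keyword(d, "mpl")),
               paste0("sample", 5:8, ".fasta"))
  expect_equal(select_files_by_keyword(d, "sem"), character(0))
  expect_error(select_files_by_keyword(file.path(d, "nope"), "x"),
               "no such directory")
})
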