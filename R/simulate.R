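# Synthetic multiplexed sequencing runs with the protocol's molecular read
# structure and a ground-truth table, so every pipeline stage is testable
# without external data.
#
# Each simulated molecule is insert + 6-nt random hexamer (UMI) + the
# constant 3' adapter + downstream PCR-primer region, read for a fixed
# number of cycles (so the adapter is usually truncated), with a matching
# index read. PCR duplicates replicate a molecule (same insert and UMI,
# independent sequencing errors).

# Synthetic defaults: a 36-nt type III-like direct repeat, six 35-nt spacers
# and an 80-nt reference gene, all free of the repeat's first five bases so
# the seed anchor is unambiguous by construction.
SIM_REPEAT <- "GTTCACTGCCGTATAGGCAGCTAAGAAAGTCATCAC"
SIM_SPACERS <- c(
  "CAAGTGACACGATATTTACGTAAGTAACCCCCTTA",
  "GCTTACCCCATCCCAAAATTTGGACAGGAACCTGA",
  "GGTGCACTTTGGAAGGACTCAAACGGACAGATGAG",
  "CGCCTTAGCCGGGCATCCCACTATATCGCTCCGTG",
  "TATATCGAGTCATTCGTTGGACTACGCATCTCCAT",
  "GCGGCAAGATAGCGCAAGGTGAGACTTGTGCGCGT"
)
SIM_REFERENCE <- paste0(
  "GCATGATTTGCTAGCTGCCCCTTGCAACTTTATCAGAATTCACGCGCTCC",
  "TGCCATTGAGAGTTCCCAGGCAGCCTACGT"
)
# Downstream of the adapter the read runs into the PCR-primer region; only
# the first 13 bases are contractual, the tail is padding for truncation.
SIM_FILLER <- paste0("GAACTCCAGTCACATCTCGTATGCCGTCTTCTGCTTG", strrep("A", 80))

# TruSeq LT barcodes AD001-AD008 as they appear in the indexing primers; the
# index read observes their reverse complement.
TRUSEQ_LT <- c(AD001 = "ATCACG", AD002 = "CGATGT", AD003 = "TTAGGC",
               AD004 = "TGACCA", AD005 = "ACAGTG", AD006 = "GCCAAT",
               AD007 = "CAGATC", AD008 = "ACTTGA")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Defines the study conditions a synthetic run emulates. Defaults model a
#' small multiplexed bacterial crRNA-biogenesis run: four samples (as in a
#' typical 8-index key where half the indexes are unused), an 80-cycle
#' single-end configuration, a dominant Cas6 cleavage position with minor
#' shoulders, a modest PCR duplicate load, and a low uniform substitution
#' error rate.
#'
#' @param seed Integer PRNG seed; fixed-seed runs are byte-identical.
#' @param read_length Sequencing cycles (default 80).
#' @param samples Tibble or data.frame with `sample_name` and
#'   `index_sequence` (the sequence observed in the index read).
#' @param repeat_seq CRISPR direct repeat.
#' @param spacers Character vector of spacer sequences (>= 30 nt each).
#' @param reference_seq Reference gene sequence.
#' @param end_distribution Named numeric vector: probability that a crRNA
#'   3' end falls at repeat position `l` (names are positions). Positions
#'   must lie in `[12, nchar(repeat_seq)]` so simulated crRNAs qualify via
#'   the repeat-length route.
#' @param n_crrna,n_reference,n_background Molecules per sample of each
#'   class.
#' @param pcr_duplication Named numeric vector: probability of each PCR
#'   multiplicity (names are multiplicities).
#' @param substitution_rate Per-base substitution probability in sample
#'   reads (index reads are simulated error-free).
#' @param y_scale Scale factor written to the params file.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       read_length = 80L,
                       samples = tibble::tibble(
                         sample_name = paste0("sample", 5:8),
                         index_sequence = reverse_complement(
                           unname(TRUSEQ_LT[5:8]))),
                       repeat_seq = SIM_REPEAT,
                       spacers = SIM_SPACERS,
                       reference_seq = SIM_REFERENCE,
                       end_distribution = c("24" = 0.05, "29" = 0.10,
                                            "30" = 0.70, "31" = 0.10,
                                            "36" = 0.05),
                       n_crrna = 2000L,
                       n_reference = 500L,
                       n_background = 500L,
                       pcr_duplication = c("1" = 0.55, "2" = 0.25,
                                           "3" = 0.12, "4" = 0.08),
                       substitution_rate = 0.002,
                       y_scale = 1) {
  cfg <- list(seed = as.integer(seed), read_length = as.integer(read_length),
              samples = tibble::as_tibble(samples), repeat_seq = repeat_seq,
              spacers = spacers, reference_seq = reference_seq,
              end_distribution = end_distribution,
              n_crrna = as.integer(n_crrna),
              n_reference = as.integer(n_reference),
              n_background = as.integer(n_background),
              pcr_duplication = pcr_duplication,
              substitution_rate = substitution_rate, y_scale = y_scale)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$read_length >= 1L,
            nrow(cfg$samples) >= 1L,
            all(c("sample_name", "index_sequence") %in% names(cfg$samples)),
            cfg$n_crrna >= 0L, cfg$n_reference >= 0L, cfg$n_background >= 0L,
            cfg$substitution_rate >= 0, cfg$substitution_rate < 1)
  if (abs(sum(cfg$end_distribution) - 1) > 1e-9) {
    stop("end_distribution probabilities must sum to 1", call. = FALSE)
  }
  if (abs(sum(cfg$pcr_duplication) - 1) > 1e-9) {
    stop("pcr_duplication probabilities must sum to 1", call. = FALSE)
  }
  ends <- as.integer(names(cfg$end_distribution))
  if (any(is.na(ends)) || any(ends < 12L) || any(ends > nchar(cfg$repeat_seq))) {
    stop("end_distribution positions must lie in [12, nchar(repeat_seq)]",
         call. = FALSE)
  }
  if (any(nchar(cfg$spacers) < 30L)) {
    stop("spacers must each be at least 30 nt", call. = FALSE)
  }
  if (anyDuplicated(cfg$samples$index_sequence)) {
    stop("sample index sequences must be distinct", call. = FALSE)
  }
  invisible(cfg)
}

apply_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Assemble one sequencing read from a molecule
#'
#' Concatenates insert, UMI, the constant 3' adapter and the downstream
#' PCR-primer region, truncates to the read length, and applies i.i.d.
#' substitution errors. Qualities are uniform `I` (qualities are carried
#' but never interpreted by the pipeline).
#'
#' @param insert Insert sequence (RNA sense strand, non-empty).
#' @param umi 6-nt unique molecular identifier.
#' @param read_length Sequencing cycles.
#' @param substitution_rate Per-base substitution probability.
#' @param identifier Read identifier.
#' @return A one-row tibble (`identifier`, `sequence`, `quality`).
#' @export
assemble_read <- function(insert, umi, read_length = 80L,
                          substitution_rate = 0, identifier = "read1") {
  if (!nzchar(insert)) stop("insert must be non-empty", call. = FALSE)
  if (nchar(umi) != 6L) stop("umi must be exactly 6 nt", call. = FALSE)
  full <- paste0(insert, umi, CRRNA_ADAPTER, SIM_FILLER)
  seq <- substr(full, 1L, read_length)
  seq <- apply_substitutions(seq, substitution_rate)
  tibble::tibble(identifier = identifier, sequence = seq,
                 quality = strrep("I", nchar(seq)))
}

sample_molecules <- function(cfg, sample_name) {
  mk <- function(class, n, inserts, ends) {
    if (n == 0) {
      return(tibble::tibble(sample_name = character(0), class = character(0),
                            insert = character(0), umi = character(0),
                            true_end_position = integer(0)))
    }
    tibble::tibble(sample_name = sample_name, class = class, insert = inserts,
                   umi = vapply(seq_len(n), function(i) random_dna(6L), ""),
                   true_end_position = ends)
  }
  # crRNA: spacer 3' tail (5-20 nt, so the junction route is exercised) +
  # repeat prefix of length l ~ end_distribution
  ends <- as.integer(names(cfg$end_distribution))
  l <- ends[sample.int(length(ends), cfg$n_crrna, replace = TRUE,
                       prob = cfg$end_distribution)]
  sp <- cfg$spacers[sample.int(length(cfg$spacers), cfg$n_crrna, replace = TRUE)]
  tail_len <- sample(5:20, max(cfg$n_crrna, 1L), replace = TRUE)[seq_len(cfg$n_crrna)]
  crrna_insert <- paste0(substr(sp, nchar(sp) - tail_len + 1L, nchar(sp)),
                         substring(cfg$repeat_seq, 1L, l))[seq_len(cfg$n_crrna)]
  crrna <- mk("crrna", cfg$n_crrna, crrna_insert, l)
  # reference: random 25-40 nt windows of the reference gene
  nref <- nchar(cfg$reference_seq)
  rlen_vals <- 25:min(40L, nref)
  rlen <- rlen_vals[sample.int(length(rlen_vals), max(cfg$n_reference, 1L),
                               replace = TRUE)][seq_len(cfg$n_reference)]
  rstart <- vapply(rlen, function(ln) sample(nref - ln + 1L, 1L), 0L)
  ref <- mk("reference", cfg$n_reference,
            substr(rep(cfg$reference_seq, cfg$n_reference), rstart,
                   rstart + rlen - 1L),
            rep(NA_integer_, cfg$n_reference))
  # background: random sequence, 20-40 nt
  blen <- sample(20:40, max(cfg$n_background, 1L),
                 replace = TRUE)[seq_len(cfg$n_background)]
  bg <- mk("background", cfg$n_background,
           vapply(blen, random_dna, ""), rep(NA_integer_, cfg$n_background))
  rbind(crrna, ref, bg)
}

#' Simulate a multiplexed sequencing run
#'
#' Generates the paired R1/I1 FASTQ streams of a run together with a
#' ground-truth table. Each molecule is replicated with a PCR multiplicity
#' drawn from `pcr_duplication` (duplicates share insert and UMI but receive
#' independent sequencing errors); reads from all samples are shuffled into
#' one run. Index reads carry one extra dark cycle (`A`) beyond the index,
#' as index reads often do, and are error-free.
#'
#' When `out_dir` is given, a complete runnable fixture set is written:
#' `Undetermined_S0_L001_R1_001.fastq`, `Undetermined_S0_L001_I1_001.fastq`,
#' `ground_truth.tsv`, `key.tsv`, `params.txt` and `spacer_ends.txt` (the
#' last 5 nt of each configured spacer, keeping simulator and junction
#' filter consistent by construction).
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory.
#' @return A list with tibbles `reads`, `index_reads`, `ground_truth`, and
#'   (when `out_dir` is given) `paths`.
#' @export
simulate_run <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, {
    molecules <- do.call(rbind, lapply(cfg$samples$sample_name,
                                       function(s) sample_molecules(cfg, s)))
    nmol <- nrow(molecules)
    mult_vals <- as.integer(names(cfg$pcr_duplication))
    mult <- mult_vals[sample.int(length(mult_vals), nmol, replace = TRUE,
                                 prob = cfg$pcr_duplication)]
    mol_of_read <- rep(seq_len(nmol), mult)
    nread <- length(mol_of_read)
    ord <- if (nread > 0) sample.int(nread) else integer(0)
    mol_of_read <- mol_of_read[ord]
    read_id <- sprintf("r%06d", seq_len(nread))
    first_read_of_mol <- read_id[match(seq_len(nmol), mol_of_read)]
    sequence <- character(nread)
    for (i in seq_len(nread)) {
      m <- mol_of_read[i]
      full <- paste0(molecules$insert[m], molecules$umi[m], CRRNA_ADAPTER,
                     SIM_FILLER)
      sequence[i] <- apply_substitutions(substr(full, 1L, cfg$read_length),
                                         cfg$substitution_rate)
    }
    reads <- tibble::tibble(identifier = read_id, sequence = sequence,
                            quality = strrep("I", nchar(sequence)))
    idx_seq <- paste0(cfg$samples$index_sequence[
      match(molecules$sample_name[mol_of_read], cfg$samples$sample_name)], "A")
    index_reads <- tibble::tibble(identifier = read_id, sequence = idx_seq,
                                  quality = strrep("I", nchar(idx_seq)))
    ground_truth <- tibble::tibble(
      read_id = read_id,
      sample_name = molecules$sample_name[mol_of_read],
      class = molecules$class[mol_of_read],
      insert = molecules$insert[mol_of_read],
      umi = molecules$umi[mol_of_read],
      true_end_position = molecules$true_end_position[mol_of_read],
      duplicate_of = ifelse(read_id == first_read_of_mol[mol_of_read],
                            NA_character_, first_read_of_mol[mol_of_read])
    )
  })
  out <- list(reads = reads, index_reads = index_reads,
              ground_truth = ground_truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      r1 = file.path(out_dir, "Undetermined_S0_L001_R1_001.fastq"),
      i1 = file.path(out_dir, "Undetermined_S0_L001_I1_001.fastq"),
      ground_truth = file.path(out_dir, "ground_truth.tsv"),
      key = file.path(out_dir, "key.tsv"),
      params = file.path(out_dir, "params.txt"),
      spacer_ends = file.path(out_dir, "spacer_ends.txt")
    )
    write_fastq(reads, paths[["r1"]])
    write_fastq(index_reads, paths[["i1"]])
    utils::write.table(ground_truth, paths[["ground_truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines(paste(cfg$samples$sample_name, cfg$samples$index_sequence,
                     sep = "\t"), paths[["key"]])
    writeLines(c(cfg$repeat_seq, cfg$reference_seq,
                 format(cfg$y_scale, scientific = FALSE)), paths[["params"]])
    writeLines(spacer_endings(cfg$spacers), paths[["spacer_ends"]])
    out$paths <- paths
  }
  out
}

#' Spacer endings implied by a spacer set
#'
#' @param spacers Character vector of spacer sequences.
#' @return Unique last-5-nt endings, one per distinct ending.
#' @export
spacer_endings <- function(spacers) {
  unique(substr(spacers, nchar(spacers) - 4L, nchar(spacers)))
}
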