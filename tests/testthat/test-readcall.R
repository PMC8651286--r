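# Read assignment, CpG calling, conversion QC and sample tallies.

# helper: the fully-converted, all-unmethylated read of an amplicon
unmeth_read <- function(amp) gsub("Y", "T", amp$converted)
# helper: fully-methylated pattern (CpGs kept as C)
meth_read <- function(amp) gsub("Y", "C", amp$converted)
# mutate n positions of a read away from the reference, avoiding given
# 0-based offsets (CpG dinucleotides, QC cytosines)
mutate_read <- function(seq, n, avoid0 = integer()) {
  chars <- strsplit(seq, "")[[1]]
  ok <- setdiff(which(chars %in% c("A", "G")), avoid0 + 1L)
  stopifnot(length(ok) >= n)
  flip <- ok[seq_len(n)]
  chars[flip] <- ifelse(chars[flip] == "A", "G", "A")
  paste(chars, collapse = "")
}

test_that("assign_read applies the 80% identity rule, both orientations, ties", {
  p <- synthetic_panel()
  amp <- p$amplicons$NEUT1
  r <- unmeth_read(amp)
  a <- assign_read(r, p)
  expect_equal(a$marker, "NEUT1")
  expect_equal(a$identity, 100)
  expect_equal(a$reason, "none")

  # reverse-complemented read assigns to the same marker
  arc <- assign_read(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(r))), p)
  expect_equal(arc$marker, "NEUT1")
  expect_equal(arc$orientation, "-")

  # a read below 80% identity to every reference is rejected
  L <- nchar(r)
  avoid <- c(amp$cpg_offsets, amp$cpg_offsets + 1L, amp$noncpg_c_offsets)
  n_bad <- ceiling(0.25 * L)
  weak <- mutate_read(r, n_bad, avoid)
  aw <- assign_read(weak, p)
  expect_true(is.na(aw$marker))
  expect_equal(aw$reason, "low_identity")
  expect_lt(aw$identity, 80)

  # equidistant read between two identical references -> ambiguous
  seqa <- "TTACGGATTCGATTAGGACGTT"
  twin <- amplicon_panel(list(
    amplicon_def("TW1", "x", "chr1", 0, nchar(seqa), seqa),
    amplicon_def("TW2", "y", "chr1", 100, 100 + nchar(seqa), seqa)))
  at <- assign_read(gsub("Y", "T", twin$amplicons$TW1$converted), twin)
  expect_true(is.na(at$marker))
  expect_equal(at$reason, "ambiguous_assignment")
})

test_that("call_cpgs maps CG/TG/other dinucleotides and flags absent CpGs", {
  # reference with 4 CpGs
  seq <- "TTACGAACGATTCGTACGTT"
  amp <- amplicon_def("T4", "t", "chr1", 0, nchar(seq), seq)
  expect_length(amp$cpg_offsets, 4)
  r <- unmeth_read(amp)
  expect_equal(call_cpgs(r, amp), rep("U", 4))
  # methylated at CpG 2 only
  chars <- strsplit(r, "")[[1]]
  chars[amp$cpg_offsets[2] + 1] <- "C"
  expect_equal(call_cpgs(paste(chars, collapse = ""), amp),
               c("U", "M", "U", "U"))
  # CA at CpG 1 -> ambiguous
  chars <- strsplit(r, "")[[1]]
  chars[amp$cpg_offsets[1] + 2] <- "A"
  expect_equal(call_cpgs(paste(chars, collapse = ""), amp)[1], "A")
  # truncated read missing the terminal CpG -> absent
  short <- substr(r, 1, amp$cpg_offsets[4])
  expect_equal(call_cpgs(short, amp)[4], "absent")
})

test_that("conversion_rate counts covered non-CpG cytosines read as T", {
  seq <- "TCACGTCACTCGTC"  # CpGs at 3 and 10; non-CpG Cs at 1,6,9,13 (0-based)
  amp <- amplicon_def("QC", "t", "chr1", 0, nchar(seq), seq)
  expect_length(amp$noncpg_c_offsets, 4)
  full <- unmeth_read(amp)
  expect_equal(conversion_rate(full, amp), 1.0)
  # leave one of the four unconverted (as C)
  chars <- strsplit(full, "")[[1]]
  chars[amp$noncpg_c_offsets[2] + 1] <- "C"
  expect_equal(conversion_rate(paste(chars, collapse = ""), amp), 0.75)
  # amplicon with no non-CpG C: undefined, and reads pass the filter
  seq2 <- "TAACGTTACGTTA"
  amp2 <- amplicon_def("NOC", "noc", "chr1", 0, nchar(seq2), seq2)
  expect_length(amp2$noncpg_c_offsets, 0)
  expect_true(is.na(conversion_rate(unmeth_read(amp2), amp2)))
  res <- tally_sample(data.frame(id = "r1", seq = unmeth_read(amp2)),
                      amplicon_panel(list(amp2)))
  expect_equal(res$counts$n_retained, 1L)
})

test_that("classify_molecule implements strict and allow-one-exception rules", {
  expect_true(classify_molecule(c("U", "U", "U", "U"), "strict"))
  expect_false(classify_molecule(c("U", "M", "U", "U"), "strict"))
  expect_true(classify_molecule(c("U", "M", "U", "U"), "allow_one_exception"))
  expect_false(classify_molecule(c("M", "M", "U", "U"), "allow_one_exception"))
  # exempt list restricts which CpG may deviate
  expect_true(classify_molecule(c("U", "M", "U"), "allow_one_exception",
                                exempt = 2L))
  expect_false(classify_molecule(c("M", "U", "U"), "allow_one_exception",
                                 exempt = 2L))
  # ambiguous calls never count as unmethylated
  expect_false(classify_molecule(c("U", "A", "U"), "allow_one_exception"))
  expect_error(classify_molecule(c("U", "absent"), "strict"), "absent")
})

test_that("tally_sample computes fractions, reasons and conserves reads", {
  p <- synthetic_panel()
  amp <- p$amplicons$MONO1
  reads <- data.frame(
    id = sprintf("r%03d", 1:100),
    seq = c(rep(unmeth_read(amp), 30), rep(meth_read(amp), 70)),
    qual = strrep("F", nchar(amp$ref_seq)), stringsAsFactors = FALSE)
  res <- tally_sample(reads, p)
  row <- res$counts[res$counts$marker == "MONO1", ]
  expect_equal(row$n_retained, 100L)
  expect_equal(row$n_fully_unmethylated, 30L)
  expect_equal(row$fraction, 0.30)
  expect_equal(row$mean_conversion, 1.0)

  # low-quality, truncated and junk reads land in the right buckets
  junk <- paste(rep("A", 120), collapse = "")
  trunc <- substr(unmeth_read(amp), 1, amp$cpg_offsets[length(amp$cpg_offsets)])
  reads2 <- data.frame(
    id = c("good", "lowq", "trunc", "junk"),
    seq = c(unmeth_read(amp), unmeth_read(amp), trunc, junk),
    qual = c(strrep("F", nchar(amp$ref_seq)),
             strrep("$", nchar(amp$ref_seq)),  # Phred 3
             strrep("F", nchar(trunc)), strrep("F", 120)),
    stringsAsFactors = FALSE)
  res2 <- tally_sample(reads2, p, per_read = TRUE)
  expect_equal(unname(res2$summary$reject_tallies[c("none", "low_quality",
                                                    "missing_cpgs",
                                                    "low_identity")]),
               c(1, 1, 1, 1))
  expect_equal(sum(res2$summary$reject_tallies), nrow(reads2))
  got <- res2$assessments
  expect_equal(got$reject_reason[match(c("good", "lowq", "trunc", "junk"),
                                       got$read_id)],
               c("none", "low_quality", "missing_cpgs", "low_identity"))
})

test_that("raising thresholds never increases retention (monotonicity)", {
  p <- synthetic_panel()
  mix <- c(neutrophil = 0.4, bcell = 0.3, HEK293 = 0.3)
  sim <- simulate_reads(p, mix, read_sim_config(depth = 120, seed = 3,
                                                sequencing_error = 0.02))
  n_ret <- function(cfg) sum(tally_sample(sim$reads, p, cfg)$counts$n_retained)
  base <- n_ret(readcall_config())
  expect_lte(n_ret(readcall_config(min_identity = 90)), base)
  expect_lte(n_ret(readcall_config(min_mean_quality = 36)), base)
  expect_lte(n_ret(readcall_config(min_conversion = 0.999)), base)
})

test_that("pure error-free cell type gives fraction 1 at own markers, 0 elsewhere", {
  p <- synthetic_panel()
  sim <- simulate_reads(p, c(tcell = 1),
                        read_sim_config(depth = 50, conversion_rate = 1,
                                        sequencing_error = 0, meth_fail = 0,
                                        seed = 2))
  res <- tally_sample(sim$reads, p)
  own <- res$counts$cell_type == "tcell"
  expect_true(all(res$counts$fraction[own] == 1))
  expect_true(all(res$counts$fraction[!own] == 0))
  expect_true(all(res$counts$n_retained == 50L))
})

test_that("pipeline classification equals the naive per-read oracle", {
  # two small amplicons plus noisy and junk reads
  toy <- amplicon_panel(list(
    tiny_amplicon("TOY1", "a", "TACGGATCGTTA"),
    tiny_amplicon("TOY2", "b", "TTGCAATCGAACGGTT")))
  set.seed(9)
  base1 <- gsub("Y", "T", toy$amplicons$TOY1$converted)
  base2 <- gsub("Y", "C", toy$amplicons$TOY2$converted)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(length(ch), k)
    ch[i] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  reads <- c(
    base1, base2,
    vapply(1:60, function(i) mut(base1, sample(0:3, 1)), character(1)),
    vapply(1:60, function(i) mut(base2, sample(0:3, 1)), character(1)),
    vapply(1:30, function(i) paste(sample(c("A", "C", "G", "T"), 12,
                                          replace = TRUE), collapse = ""),
           character(1)),
    substr(base1, 1, 10), substr(base2, 3, 16))
  df <- data.frame(id = sprintf("r%03d", seq_along(reads)), seq = reads,
                   qual = strrep("F", nchar(reads)), stringsAsFactors = FALSE)
  got <- tally_sample(df, toy, per_read = TRUE)$assessments
  for (i in seq_along(reads)) {
    want <- oracle_interpret(df$seq[i], df$qual[i], toy)
    expect_equal(got$reject_reason[i], want$reason, info = df$seq[i])
    if (want$reason %in% c("none", "missing_cpgs", "poor_conversion")) {
      expect_equal(got$marker[i], want$marker, info = df$seq[i])
    }
    expect_equal(got$fully_unmethylated[i], want$unmeth, info = df$seq[i])
  }
})
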