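# Fragment extraction from SAM alignments and the filter chain. The
# primer window is 101..119 on a 200-base test reference (see helpers).

test_that("a fully containing read yields exactly the window bases", {
  ref <- test_reference()
  p <- test_primer_515Y()
  sam <- write_test_sam(tempfile(fileext = ".sam"), "ref16S", 200L,
                        qname = "r1", flag = 0L, pos = 41L, cigar = "150M",
                        seq = substr(ref, 41, 190))
  fr <- extract_fragments(sam, p, sample_id = "s1", groups = "Bacteria")
  expect_equal(nrow(fr), 1)
  expect_identical(fr$bases, substr(ref, 101, 119))
  expect_identical(fr$group, "Bacteria")
  expect_equal(fr$mean_quality, 40)
  expect_identical(fr$flank_side, "both")
})

test_that("reads violating the spanning rule yield no fragment", {
  ref <- test_reference()
  p <- test_primer_515Y()
  sam <- tempfile(fileext = ".sam")
  # ends 3 bases into the window; covers the window but no 5-base flank;
  # covers with right flank only; unmapped; secondary
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:ref16S\tLN:200",
    sprintf("ends_early\t0\tref16S\t54\t60\t50M\t*\t0\t0\t%s\t%s",
            substr(ref, 54, 103), strrep("I", 50)),
    sprintf("no_flank\t0\tref16S\t99\t60\t23M\t*\t0\t0\t%s\t%s",
            substr(ref, 99, 121), strrep("I", 23)),
    sprintf("right_flank\t0\tref16S\t100\t60\t30M\t*\t0\t0\t%s\t%s",
            substr(ref, 100, 129), strrep("I", 30)),
    sprintf("unmapped\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
            substr(ref, 41, 90), strrep("I", 50)),
    sprintf("secondary\t256\tref16S\t41\t60\t100M\t*\t0\t0\t%s\t%s",
            substr(ref, 41, 140), strrep("I", 100)))
  writeLines(lines, sam)
  fr <- extract_fragments(sam, p, groups = "Bacteria")
  expect_identical(fr$read_id, "right_flank")
  expect_identical(fr$flank_side, "right")
  # the stricter both-sides rule rejects it
  fr2 <- extract_fragments(sam, p, groups = "Bacteria", both_sides = TRUE)
  expect_equal(nrow(fr2), 0)
})

test_that("reads with indels inside the window are skipped, outside kept", {
  ref <- test_reference()
  p <- test_primer_515Y()
  sam <- tempfile(fileext = ".sam")
  seq_del_in <- paste0(substr(ref, 81, 104), substr(ref, 106, 140))   # del at 105
  seq_ins_in <- paste0(substr(ref, 81, 110), "A", substr(ref, 111, 140))
  seq_del_out <- paste0(substr(ref, 81, 90), substr(ref, 92, 140))    # del at 91
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:ref16S\tLN:200",
    sprintf("del_in\t0\tref16S\t81\t60\t24M1D35M\t*\t0\t0\t%s\t%s",
            seq_del_in, strrep("I", nchar(seq_del_in))),
    sprintf("ins_in\t0\tref16S\t81\t60\t30M1I30M\t*\t0\t0\t%s\t%s",
            seq_ins_in, strrep("I", nchar(seq_ins_in))),
    sprintf("del_out\t0\tref16S\t81\t60\t10M1D49M\t*\t0\t0\t%s\t%s",
            seq_del_out, strrep("I", nchar(seq_del_out))))
  writeLines(lines, sam)
  fr <- extract_fragments(sam, p, groups = "Bacteria")
  expect_identical(fr$read_id, "del_out")
  expect_identical(fr$bases, substr(ref, 101, 119))
})

test_that("tiling reads match a brute-force count of qualifying starts", {
  ref <- test_reference()
  p <- test_primer_515Y()  # window 101..119, length 19
  rl <- 50L
  starts <- 1:(200 - rl + 1)
  sam <- write_test_sam(tempfile(fileext = ".sam"), "ref16S", 200L,
                        qname = sprintf("t%03d", starts), flag = 0L,
                        pos = starts, cigar = sprintf("%dM", rl),
                        seq = substring(ref, starts, starts + rl - 1L))
  for (both in c(FALSE, TRUE)) {
    fr <- extract_fragments(sam, p, groups = "Bacteria", both_sides = both)
    ends <- starts + rl - 1L
    left <- starts <= 101L - 5L
    right <- ends >= 119L + 5L
    qual <- starts <= 101L & ends >= 119L &
      (if (both) left & right else left | right)
    expect_identical(sort(fr$read_id), sort(sprintf("t%03d", starts[qual])))
    expect_true(all(fr$bases == substr(ref, 101, 119)))
  }
})

test_that("group labels come from the sidecar and are validated", {
  ref <- test_reference()
  p <- test_primer_515Y()
  sam <- write_test_sam(tempfile(fileext = ".sam"), "ref16S", 200L,
                        qname = c("r1", "r2"), flag = 0L, pos = c(41L, 45L),
                        cigar = "100M",
                        seq = substring(ref, c(41, 45), c(140, 144)))
  sidecar_path <- tempfile(fileext = ".tsv")
  writeLines(c("read_id\tgroup", "r1\tArchaea", "r2\tEukarya"), sidecar_path)
  sidecar <- read_group_sidecar(sidecar_path)
  fr <- extract_fragments(sam, p, groups = sidecar)
  expect_identical(fr$group[match(c("r1", "r2"), fr$read_id)],
                   c("Archaea", "Eukarya"))
  expect_error(extract_fragments(sam, p, groups = "Protista"),
               "unknown group")
})

test_that("extraction validates reference name and window coordinates", {
  ref <- test_reference()
  sam <- write_test_sam(tempfile(fileext = ".sam"), "ref16S", 200L,
                        qname = "r1", flag = 0L, pos = 41L, cigar = "150M",
                        seq = substr(ref, 41, 190))
  wrong_ref <- degenerate_primer("515Y", "GTGYCAGCMGCCGCGGTAA", "forward",
                                 101, reference = "Ec16S")
  expect_error(extract_fragments(sam, wrong_ref), "not found in alignment header")
  out_of_range <- degenerate_primer("p", strrep("A", 19), "forward",
                                    190, reference = "ref16S")
  expect_error(extract_fragments(sam, out_of_range), "exceeds reference length")
})

test_that("quality filter removes low-mean-quality fragments, boundary inclusive", {
  fr <- data.frame(read_id = c("a", "b", "c"), sample_id = "s",
                   group = "Bacteria", primer = "p",
                   bases = c("ACGT", "ACGT", "ACGT"),
                   mean_quality = c(40, 2, 30), flank_side = "both")
  out <- quality_filter(fr, min_mean_quality = 30)
  expect_identical(out$read_id, c("a", "c"))
  expect_equal(attr(out, "n_removed"), 1L)
  # FASTA path: no qualities, pass through with a notice
  fr$mean_quality <- NA_real_
  expect_message(out2 <- quality_filter(fr), "no quality information")
  expect_equal(nrow(out2), 3)
})

test_that("ambiguous fragments are dropped before scoring", {
  fr <- data.frame(read_id = c("a", "b"), sample_id = "s", group = "Bacteria",
                   primer = "p", bases = c("ACGT", "ACNT"),
                   mean_quality = 40, flank_side = "both")
  out <- drop_ambiguous_fragments(fr)
  expect_identical(out$read_id, "a")
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("exclusion filter drops >6 mismatches, keeps exactly 6", {
  p <- degenerate_primer("515Y", "GTGYCAGCMGCCGCGGTAA", "forward", 101,
                         reference = "ref16S")
  perfect <- expand_primer(p$sequence)[1]
  six <- perfect
  for (i in 1:6) substr(six, i, i) <- setdiff(c("A", "C", "G", "T"),
                                              iupac_set(substr(p$sequence, i, i)))[1]
  ten <- perfect
  for (i in 1:10) substr(ten, i, i) <- setdiff(c("A", "C", "G", "T"),
                                               iupac_set(substr(p$sequence, i, i)))[1]
  fr <- data.frame(read_id = c("perfect", "six", "ten"), sample_id = "s",
                   group = "Bacteria", primer = "515Y",
                   bases = c(perfect, six, ten), mean_quality = 40,
                   flank_side = "both")
  out <- exclusion_filter(fr, p)
  expect_setequal(out$read_id, c("perfect", "six"))
  expect_equal(attr(out, "n_removed"), 1L)
  expect_identical(out$n_mismatches[out$read_id == "six"], 6L)
})

test_that("evaluate_primer preserves read conservation across the chain", {
  spec <- demo_simulation_spec(21)
  sim <- simulate_reads(spec, out_dir = tempfile())
  row <- sim$files[1, ]
  ev <- evaluate_primer(row$sam, spec$primers[[1]], sample_id = row$sample_id,
                        groups = row$group)
  t <- ev$tally
  expect_equal(t[["extracted"]],
               t[["emitted"]] + t[["low_quality"]] + t[["ambiguous"]] +
                 t[["excluded"]])
  expect_equal(nrow(ev$fragments), t[["emitted"]])
})

test_that("pre-extracted FASTQ/FASTA input builds equivalent fragments", {
  p <- test_primer_515Y()
  oligos <- expand_primer(p$sequence)
  fa <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(sprintf(">v%d", seq_along(oligos)), oligos)), fa)
  fr <- fragments_from_sequences(fa, p, groups = "Bacteria")
  expect_equal(nrow(fr), 4)
  expect_true(all(is.na(fr$mean_quality)))
  expect_identical(score_fragments(fr, p)$n_mismatches, rep(0L, 4))
  fq <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(sprintf("@v%d", seq_along(oligos)), oligos, "+",
                             strrep("5", nchar(p$sequence)))), fq)
  frq <- fragments_from_sequences(fq, p, groups = "Bacteria")
  expect_equal(frq$mean_quality, rep(20, 4))
  expect_error(
    fragments_from_sequences(Biostrings::DNAStringSet("ACGT"), p),
    "primer length")
})
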