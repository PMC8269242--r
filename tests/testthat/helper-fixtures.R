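# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: mismatch counting is checked against a
# brute-force minimum Hamming distance over the full primer expansion, and
# SAM fixtures are written as literal text lines.

# minimum Hamming distance of `fragment` to any concrete expansion of the
# degenerate `primer` -- the defining property of the mismatch count
brute_force_mismatches <- function(primer, fragment) {
  oligos <- expand_primer(primer, cap = 100000L)
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  min(vapply(oligos, hamming, integer(1L), b = fragment))
}

# a random degenerate primer of given length with degeneracy <= cap
random_degenerate_primer <- function(len, cap = 256L) {
  codes <- names(primerscope:::.IUPAC_MASKS)
  repeat {
    s <- paste(sample(codes, len, replace = TRUE,
                      prob = c(rep(6, 4), rep(1, 11))), collapse = "")
    if (degeneracy_count(s) <= cap) return(s)
  }
}

random_fragment <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# write a minimal single-reference SAM file from parallel vectors
write_test_sam <- function(path, ref, ref_len, qname, flag, pos, cigar, seq,
                           qual = strrep("I", nchar(seq))) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", ref, ref_len),
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
            qname, flag, ref, pos, cigar, seq, qual))
  writeLines(lines, path)
  path
}

# a fixed 200-base reference with one expansion of 515Y planted at 101..119
test_reference <- function() {
  set.seed(42)
  ref <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  substr(ref, 101, 119) <- "GTGCCAGCAGCCGCGGTAA"
  ref
}

test_primer_515Y <- function() {
  degenerate_primer("515Y", "GTGYCAGCMGCCGCGGTAA", "forward",
                    ref_start = 101L, reference = "ref16S")
}
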