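# Extraction of primer-binding-region fragments from reads aligned to a
# group-specific SSU rRNA reference, plus the downstream filter chain.
# Pipeline order is fixed: extract -> quality filter -> drop non-ACGT ->
# exclusion filter; evaluate_primer() runs the chain and keeps a read
# conservation tally.

.empty_fragments <- function() {
  data.frame(
    read_id = character(0), sample_id = character(0), group = character(0),
    primer = character(0), bases = character(0), mean_quality = numeric(0),
    flank_side = character(0), stringsAsFactors = FALSE)
}

.as_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                   indexDestination = FALSE)
}

#' Extract primer-binding-region fragments from aligned reads
#'
#' For every primary aligned read whose alignment spans the primer window,
#' returns the read bases aligned to reference columns
#' `ref_start..ref_end`, in reference orientation, together with the mean
#' Phred quality over the window. Unmapped, secondary and supplementary
#' records are skipped, as are reads with an insertion or deletion inside
#' the primer window (length-changing variants cannot be scored by
#' positional mismatch counting).
#'
#' The spanning rule follows the convention that a qualifying read overlaps
#' the primer-binding region plus a flank: the alignment must cover the full
#' window and, by default, at least `flank` reference bases on at least one
#' side (`both_sides = TRUE` requires the flank on both sides). The side(s)
#' satisfying the flank are recorded per fragment.
#'
#' @param alignments path to a SAM (or BAM) file of reads aligned to a
#'   single reference sequence.
#' @param primer a [degenerate_primer()]; its `reference` must match the
#'   alignment reference and its window must lie within the reference.
#' @param sample_id sample identifier attached to every fragment.
#' @param groups either a single group name (one of [SSU_GROUPS]) applied to
#'   all reads, or a data.frame with columns `read_id`, `group` (the sidecar
#'   convention). Reads without a label get `NA`.
#' @param flank required flank width in reference bases (default 5).
#' @param both_sides require the flank on both sides of the window instead
#'   of at least one.
#' @return data.frame with columns `read_id`, `sample_id`, `group`,
#'   `primer`, `bases`, `mean_quality`, `flank_side`.
#' @export
extract_fragments <- function(alignments, primer, sample_id = "sample1",
                              groups = NA_character_, flank = 5L,
                              both_sides = FALSE) {
  stopifnot(inherits(primer, "degenerate_primer"))
  flank <- as.integer(flank)
  bam <- .as_bam(alignments)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!primer$reference %in% names(hdr)) {
    stop(sprintf("reference '%s' not found in alignment header (has: %s)",
                 primer$reference, paste(names(hdr), collapse = ", ")))
  }
  ref_len <- hdr[[primer$reference]]
  rs <- primer$ref_start
  re <- primer$ref_end
  if (re > ref_len) {
    stop(sprintf("primer window %d..%d exceeds reference length %d",
                 rs, re, ref_len))
  }

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  gal <- gal[as.character(GenomicAlignments::seqnames(gal)) == primer$reference]
  if (length(gal) == 0L) return(.empty_fragments())

  astart <- GenomicAlignments::start(gal)
  aend <- GenomicAlignments::end(gal)
  left_ok <- astart <= rs - flank
  right_ok <- aend >= re + flank
  spans <- astart <= rs & aend >= re &
    (if (both_sides) left_ok & right_ok else left_ok | right_ok)
  gal <- gal[spans]
  if (length(gal) == 0L) return(.empty_fragments())
  left_ok <- left_ok[spans]
  right_ok <- right_ok[spans]
  astart <- astart[spans]

  cig <- GenomicAlignments::cigar(gal)
  ins <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = astart, ops = "I")
  del <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = astart, ops = "D")
  # insertion between reference columns p and p+1 is reported as a
  # zero-width range starting at p+1; it disturbs the window iff strictly
  # inside it
  ins_in <- vapply(seq_along(gal), function(i) {
    s <- IRanges::start(ins[[i]])
    any(s > rs & s <= re)
  }, logical(1L))
  del_in <- vapply(seq_along(gal), function(i) {
    r <- del[[i]]
    any(IRanges::start(r) <= re & IRanges::end(r) >= rs)
  }, logical(1L))
  keep <- !(ins_in | del_in)
  gal <- gal[keep]
  if (length(gal) == 0L) return(.empty_fragments())
  left_ok <- left_ok[keep]
  right_ok <- right_ok[keep]
  astart <- astart[keep]

  # project read bases and qualities into reference space, then slice the
  # primer window; indels inside the window are gone by construction
  seq_ref <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(gal)$seq, GenomicAlignments::cigar(gal),
    from = "query", to = "reference")
  offs <- rs - astart + 1L
  bases <- as.character(Biostrings::subseq(seq_ref, start = offs,
                                           width = re - rs + 1L))

  qual <- S4Vectors::mcols(gal)$qual
  mean_q <- rep(NA_real_, length(gal))
  if (!is.null(qual)) {
    # reads stored without base qualities ("*" in SAM) are left NA
    has_q <- Biostrings::width(qual) == Biostrings::width(S4Vectors::mcols(gal)$seq)
    if (any(has_q)) {
      qual_ref <- GenomicAlignments::sequenceLayer(
        methods::as(qual, "BStringSet")[has_q],
        GenomicAlignments::cigar(gal)[has_q],
        from = "query", to = "reference")
      qwin <- as.character(Biostrings::subseq(qual_ref, start = offs[has_q],
                                              width = re - rs + 1L))
      mean_q[has_q] <- vapply(qwin, function(q) mean(utf8ToInt(q) - 33L),
                              numeric(1L), USE.NAMES = FALSE)
    }
  }

  side <- ifelse(left_ok & right_ok, "both", ifelse(left_ok, "left", "right"))
  out <- data.frame(
    read_id = S4Vectors::mcols(gal)$qname,
    sample_id = sample_id,
    group = NA_character_,
    primer = primer$name,
    bases = bases,
    mean_quality = mean_q,
    flank_side = side,
    stringsAsFactors = FALSE)
  .label_groups(out, groups)
}

.label_groups <- function(fragments, groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("read_id", "group") %in% names(groups)))
    idx <- match(fragments$read_id, groups$read_id)
    fragments$group <- groups$group[idx]
  } else {
    stopifnot(length(groups) == 1L)
    fragments$group <- as.character(groups)
  }
  known <- is.na(fragments$group) | fragments$group %in% SSU_GROUPS
  if (!all(known)) {
    stop("unknown group label(s): ",
         paste(unique(fragments$group[!known]), collapse = ", "))
  }
  fragments
}

#' Build fragments from pre-extracted primer-region sequences
#'
#' Alternative input path for workflows that have already cut out the
#' primer-binding regions: a FASTA/FASTQ file (or `DNAStringSet` /
#' `QualityScaledDNAStringSet`) of sequences exactly covering the window,
#' in reference orientation, with group labels supplied via the sidecar
#' convention.
#'
#' @param sequences file path or `XStringSet`; FASTA input yields
#'   `mean_quality = NA`.
#' @param primer a [degenerate_primer()] (used for the name and length check).
#' @param sample_id sample identifier.
#' @param groups as in [extract_fragments()].
#' @param format `"fasta"` or `"fastq"`; guessed from the extension when
#'   `sequences` is a path.
#' @return fragment data.frame as from [extract_fragments()].
#' @export
fragments_from_sequences <- function(sequences, primer, sample_id = "sample1",
                                     groups = NA_character_, format = NULL) {
  stopifnot(inherits(primer, "degenerate_primer"))
  if (is.character(sequences)) {
    if (is.null(format)) {
      format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", sequences,
                          ignore.case = TRUE)) "fastq" else "fasta"
    }
    sequences <- if (format == "fastq") {
      # suppress a benign note about dropped metadata columns on conversion
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(sequences))
    } else {
      Biostrings::readDNAStringSet(sequences, format = "fasta")
    }
  }
  plen <- nchar(primer$sequence)
  if (length(sequences) && any(Biostrings::width(sequences) != plen)) {
    stop(sprintf("pre-extracted sequences must all have the primer length (%d)",
                 plen))
  }
  mean_q <- rep(NA_real_, length(sequences))
  if (methods::is(sequences, "QualityScaledXStringSet")) {
    qv <- methods::as(Biostrings::quality(sequences), "IntegerList")
    mean_q <- vapply(qv, mean, numeric(1L))
  }
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(sequences))
  ids <- sub("\\s.*$", "", ids)
  out <- data.frame(
    read_id = ids, sample_id = sample_id, group = NA_character_,
    primer = primer$name, bases = as.character(sequences),
    mean_quality = mean_q, flank_side = NA_character_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  .label_groups(out, groups)
}

#' Read a read-to-group sidecar TSV
#'
#' Two tab-separated columns, `read_id` and `group`, with or without a
#' header line. Group labels must be drawn from [SSU_GROUPS].
#'
#' @param path path to the TSV.
#' @return data.frame with columns `read_id`, `group`.
#' @export
read_group_sidecar <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^read_id\t", first)
  df <- if (has_header) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = "character", comment.char = "#",
                      quote = "")
  } else {
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("read_id", "group"),
                      colClasses = "character", comment.char = "#",
                      quote = "")
  }
  names(df)[1:2] <- c("read_id", "group")
  bad <- setdiff(unique(df$group), SSU_GROUPS)
  if (length(bad)) stop("unknown group label(s) in sidecar: ",
                        paste(bad, collapse = ", "))
  df
}

#' Remove fragments whose mean region quality falls below a threshold
#'
#' Fragments without quality information (FASTA input) pass through
#' unchanged with a notice.
#'
#' @param fragments fragment data.frame.
#' @param min_mean_quality Phred threshold (default 30).
#' @return filtered fragment data.frame; the number of removed fragments is
#'   attached as `attr(, "n_removed")`.
#' @export
quality_filter <- function(fragments, min_mean_quality = 30) {
  if (nrow(fragments) == 0L) {
    attr(fragments, "n_removed") <- 0L
    return(fragments)
  }
  if (all(is.na(fragments$mean_quality))) {
    message("fragments carry no quality information; quality filter is a no-op")
    attr(fragments, "n_removed") <- 0L
    return(fragments)
  }
  keep <- !is.na(fragments$mean_quality) &
    fragments$mean_quality >= min_mean_quality
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove fragments containing non-ACGT characters
#'
#' Reads with ambiguity codes (including N) in the primer window are
#' excluded before mismatch counting rather than counted as matches or
#' mismatches, so uninformative bases inflate neither tally.
#'
#' @param fragments fragment data.frame.
#' @return filtered fragment data.frame with `attr(, "n_removed")`.
#' @export
drop_ambiguous_fragments <- function(fragments) {
  keep <- !grepl("[^ACGT]", fragments$bases)
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Score fragments against a primer
#'
#' Adds an `n_mismatches` column: the number of positions at which the
#' fragment base is outside the primer's IUPAC set, with reverse primers
#' compared via their reverse complement (fragments are kept in reference
#' orientation).
#'
#' @param fragments fragment data.frame (non-ACGT fragments already removed).
#' @param primer a [degenerate_primer()].
#' @return the fragment data.frame with an `n_mismatches` column.
#' @export
score_fragments <- function(fragments, primer) {
  fragments$n_mismatches <- if (nrow(fragments)) {
    count_mismatches(binding_site_sequence(primer), fragments$bases)
  } else integer(0)
  fragments
}

#' Exclude fragments too diverged to be genuine primer-region sequences
#'
#' Aligned reads falling in the primer region with no match to the primer
#' at a generous mismatch threshold (default 6) are treated as
#' misalignments or distantly related sequences and removed; the boundary
#' is inclusive (exactly `max_mm` mismatches is retained).
#'
#' @param fragments fragment data.frame.
#' @param primer a [degenerate_primer()].
#' @param max_mm maximum mismatches to retain (default 6).
#' @return filtered, scored fragment data.frame with `attr(, "n_removed")`.
#' @export
exclusion_filter <- function(fragments, primer, max_mm = 6L) {
  if (is.null(fragments$n_mismatches)) {
    fragments <- score_fragments(fragments, primer)
  }
  keep <- fragments$n_mismatches <= max_mm
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Run the full extraction and filtering chain for one primer
#'
#' extract -> quality filter -> drop non-ACGT -> exclusion filter, with a
#' read-conservation tally: the number of extracted fragments equals the
#' number emitted plus the per-filter removals.
#'
#' @param alignments SAM/BAM path (see [extract_fragments()]), or an
#'   already-extracted fragment data.frame.
#' @param primer a [degenerate_primer()].
#' @param sample_id,groups,flank,both_sides passed to [extract_fragments()].
#' @param min_mean_quality Phred threshold for [quality_filter()].
#' @param max_mm threshold for [exclusion_filter()].
#' @return list with `fragments` (scored, filtered data.frame) and `tally`
#'   (named integer vector: extracted, low_quality, ambiguous, excluded,
#'   emitted).
#' @export
evaluate_primer <- function(alignments, primer, sample_id = "sample1",
                            groups = NA_character_, flank = 5L,
                            both_sides = FALSE, min_mean_quality = 30,
                            max_mm = 6L) {
  frags <- if (is.data.frame(alignments)) alignments else {
    extract_fragments(alignments, primer, sample_id = sample_id,
                      groups = groups, flank = flank,
                      both_sides = both_sides)
  }
  n0 <- nrow(frags)
  fq <- quality_filter(frags, min_mean_quality)
  n_q <- attr(fq, "n_removed")
  fa <- drop_ambiguous_fragments(fq)
  n_a <- attr(fa, "n_removed")
  fs <- score_fragments(fa, primer)
  fe <- exclusion_filter(fs, primer, max_mm = max_mm)
  n_e <- attr(fe, "n_removed")
  tally <- c(extracted = n0, low_quality = n_q, ambiguous = n_a,
             excluded = n_e, emitted = nrow(fe))
  stopifnot(tally[["extracted"]] ==
              tally[["emitted"]] + n_q + n_a + n_e)
  list(fragments = fe, tally = tally)
}
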