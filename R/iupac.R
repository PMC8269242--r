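# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8). Holding codes
# as masks makes set membership a bitwise AND, which lets mismatch counting
# vectorise over whole fragment collections.
.IUPAC_MASKS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.BASES <- c("A", "C", "G", "T")

# minimal IUPAC letter for every non-empty base subset, indexed by mask
.MASK_TO_CODE <- local({
  out <- character(15L)
  out[.IUPAC_MASKS] <- names(.IUPAC_MASKS)
  out
})

# utf8 code point -> mask (0 marks an invalid character), for fast lookup
.MASK_LOOKUP <- local({
  out <- integer(127L)
  out[utf8ToInt(paste(names(.IUPAC_MASKS), collapse = ""))] <- .IUPAC_MASKS
  out
})

.mask_size <- function(mask) {
  # popcount over the 4 base bits
  ((mask %/% 1L) %% 2L) + ((mask %/% 2L) %% 2L) +
    ((mask %/% 4L) %% 2L) + ((mask %/% 8L) %% 2L)
}

#' Normalise a nucleotide sequence to the uppercase IUPAC DNA alphabet
#'
#' Uppercases, converts U to T, and rejects any character outside the 15-letter
#' IUPAC nucleotide alphabet, reporting the first offending position.
#'
#' @param seq character vector of sequences.
#' @param what label used in error messages (e.g. `"primer"`).
#' @return character vector of normalised sequences.
#' @export
normalize_iupac <- function(seq, what = "sequence") {
  if (!is.character(seq) || anyNA(seq)) {
    stop(what, " must be a character vector without NA")
  }
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  for (i in seq_along(s)) {
    if (!nzchar(s[[i]])) stop(what, " must be non-empty")
    codes <- utf8ToInt(s[[i]])
    bad <- codes > 127L | .MASK_LOOKUP[pmin(codes, 127L)] == 0L
    if (any(bad)) {
      p <- which(bad)[1L]
      stop(sprintf("invalid IUPAC character '%s' at position %d in %s",
                   substr(s[[i]], p, p), p, what))
    }
  }
  s
}

.seq_masks <- function(seq) .MASK_LOOKUP[utf8ToInt(seq)]

#' Nucleotide set denoted by a single IUPAC code
#'
#' @param code single IUPAC character (case-insensitive; U allowed for T).
#' @return character vector, a subset of `c("A","C","G","T")`.
#' @examples
#' iupac_set("Y")  # C, T
#' iupac_set("N")  # A, C, G, T
#' @export
iupac_set <- function(code) {
  s <- normalize_iupac(code, what = "IUPAC code")
  if (length(s) != 1L || nchar(s) != 1L) {
    stop("iupac_set() expects a single character")
  }
  m <- .seq_masks(s)
  .BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) != 0L]
}

.primer_sequence <- function(x, what = "primer") {
  if (inherits(x, "degenerate_primer")) x$sequence else normalize_iupac(x, what)
}

#' Number of nondegenerate oligonucleotides encoded by a degenerate primer
#'
#' The product over positions of the IUPAC set sizes; equal to the size of
#' [expand_primer()]'s output. This is the number of distinct oligos that
#' must be synthesised for a fully degenerate primer.
#'
#' @param x a [degenerate_primer()] or an IUPAC sequence string.
#' @return a positive integer (double if the product exceeds `.Machine$integer.max`).
#' @examples
#' degeneracy_count("GTGYCAGCMGCCGCGGTAA")   # 4  (515Y)
#' degeneracy_count("CCGYCAATTYMTTTRAGTTT")  # 16 (926R)
#' @export
degeneracy_count <- function(x) {
  s <- .primer_sequence(x)
  prod(.mask_size(.seq_masks(s)))
}

#' Expand a degenerate primer into its set of concrete oligonucleotides
#'
#' Enumerates all and only the nondegenerate (A/C/G/T) sequences compatible
#' with the primer, in lexicographic order.
#'
#' @param x a [degenerate_primer()] or an IUPAC sequence string.
#' @param cap refuse expansion if the degeneracy exceeds this (guards against
#'   runaway enumeration of near-random sequences); raise it explicitly for
#'   very highly degenerate primers.
#' @return character vector of distinct A/C/G/T sequences, sorted.
#' @examples
#' expand_primer("NA")   # AA, CA, GA, TA
#' @export
expand_primer <- function(x, cap = 4096L) {
  s <- .primer_sequence(x)
  n <- degeneracy_count(s)
  if (n > cap) {
    stop(sprintf("degeneracy %d exceeds expansion cap %d; raise `cap` to force",
                 n, cap))
  }
  sets <- lapply(strsplit(s, "")[[1L]], iupac_set)
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  oligos <- do.call(paste0, rev(grid))
  sort(unique(oligos))
}

#' Count mismatches between a degenerate primer and concrete fragments
#'
#' A position matches when the fragment base is a member of the primer's
#' IUPAC set at that position; the mismatch count is the number of
#' non-matching positions. Zero mismatches is a "perfect match": the
#' fragment is identical to at least one oligo in the primer's expansion.
#'
#' Fragments must be nondegenerate (A/C/G/T only); reads containing
#' ambiguity codes are excluded upstream rather than scored (see
#' [drop_ambiguous_fragments()]).
#'
#' @param primer a [degenerate_primer()] or IUPAC sequence string, already
#'   oriented like the fragments (use [binding_site_sequence()] for
#'   reverse primers scored against reference-orientation fragments).
#' @param fragments character vector of A/C/G/T sequences, each the same
#'   length as the primer.
#' @return integer vector of mismatch counts, one per fragment.
#' @examples
#' count_mismatches("GTGYCAGCMGCCGCGGTAA", "GTGCCAGCAGCCGCGGTAA")  # 0
#' count_mismatches("ACGT", c("ACGT", "ACGA", "TTTT"))
#' @export
count_mismatches <- function(primer, fragments) {
  pseq <- .primer_sequence(primer)
  n <- nchar(pseq)
  if (length(fragments) == 0L) return(integer(0))
  frag <- chartr("u", "U", toupper(fragments))
  frag <- chartr("U", "T", frag)
  lens <- nchar(frag)
  if (any(lens != n)) {
    i <- which(lens != n)[1L]
    stop(sprintf("fragment length %d does not match primer length %d (fragment %d)",
                 lens[i], n, i))
  }
  codes <- utf8ToInt(paste(frag, collapse = ""))
  if (any(codes > 127L)) stop("fragment contains a non-ASCII character")
  fm <- .MASK_LOOKUP[codes]
  if (any(!fm %in% c(1L, 2L, 4L, 8L))) {
    bad <- which(!fm %in% c(1L, 2L, 4L, 8L))[1L]
    stop(sprintf("fragment %d contains non-ACGT character '%s' at position %d",
                 (bad - 1L) %/% n + 1L, intToUtf8(codes[bad]), (bad - 1L) %% n + 1L))
  }
  pm <- .seq_masks(pseq)
  hits <- matrix(bitwAnd(fm, pm) == 0L, nrow = n)  # pm recycles per column
  as.integer(colSums(hits))
}

.COMPLEMENT_FROM <- "ACGTRYSWKMBDHVN"
.COMPLEMENT_TO   <- "TGCAYRSWMKVHDBN"

#' Reverse complement of an IUPAC sequence
#'
#' Complements every position with ambiguity codes mapped to their
#' complements (R/Y, K/M, B/V, D/H swap; S, W and N are self-complementary),
#' then reverses. Involutive: applying it twice returns the input.
#'
#' @param seq character vector of IUPAC sequences.
#' @return character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  s <- normalize_iupac(seq)
  comp <- chartr(.COMPLEMENT_FROM, .COMPLEMENT_TO, s)
  vapply(comp, function(x) {
    intToUtf8(rev(utf8ToInt(x)))
  }, character(1L), USE.NAMES = FALSE)
}

#' Minimal IUPAC consensus covering a set of equal-length oligos
#'
#' For each position, the smallest IUPAC code whose set contains every base
#' observed at that position across the input sequences. The result is the
#' most compact single degenerate sequence whose expansion is a superset of
#' the input; the expansion is usually strictly larger (the "redundant
#' oligonucleotides" a fully degenerate redesign would synthesise).
#'
#' @param oligos character vector of equal-length IUPAC sequences.
#' @return a single IUPAC sequence string.
#' @examples
#' degenerate_union(c("ACG", "ATC"))  # "AYS", degeneracy 4 vs 2 oligos
#' @export
degenerate_union <- function(oligos) {
  s <- normalize_iupac(oligos, what = "oligo")
  n <- unique(nchar(s))
  if (length(n) != 1L) stop("all oligos must have equal length")
  m <- matrix(.MASK_LOOKUP[utf8ToInt(paste(s, collapse = ""))], nrow = n)
  union_mask <- apply(m, 1L, function(row) Reduce(bitwOr, row))
  paste(.MASK_TO_CODE[union_mask], collapse = "")
}
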