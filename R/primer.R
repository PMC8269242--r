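#' Construct a degenerate PCR primer
#'
#' A primer is a named IUPAC sequence written 5'-to-3' as it anneals, with an
#' orientation and 1-based inclusive coordinates on a reference SSU rRNA gene
#' (conventionally the E. coli K-12 MG1655 16S rRNA, or a group-specific
#' reference named in the config).
#'
#' For a reverse primer the annealing sequence is the reverse complement of
#' the reference (template) strand over `ref_start..ref_end`; use
#' [binding_site_sequence()] to obtain the reference-orientation sequence
#' that fragments extracted from alignments are compared against.
#'
#' @param name short identifier, e.g. `"515Y"`.
#' @param sequence IUPAC sequence, 5'-to-3' as the primer anneals.
#' @param orientation `"forward"` or `"reverse"`.
#' @param ref_start,ref_end 1-based inclusive coordinates of the binding site
#'   on the reference; the window length must equal the primer length.
#' @param reference name of the reference sequence the coordinates refer to.
#' @param targets which of [SSU_GROUPS] the primer is expected to bind;
#'   used for the taxonomic-overlap correction in [pair_coverage()].
#' @return an object of class `degenerate_primer`.
#' @examples
#' p515Y <- degenerate_primer("515Y", "GTGYCAGCMGCCGCGGTAA", "forward", 515)
#' degeneracy_count(p515Y)
#' @export
degenerate_primer <- function(name, sequence,
                              orientation = c("forward", "reverse"),
                              ref_start, ref_end = NULL,
                              reference = "Ec16S",
                              targets = SSU_GROUPS) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  orientation <- match.arg(orientation)
  sequence <- normalize_iupac(sequence, what = sprintf("primer %s", name))
  ref_start <- as.integer(ref_start)
  if (is.null(ref_end)) ref_end <- ref_start + nchar(sequence) - 1L
  ref_end <- as.integer(ref_end)
  if (ref_start < 1L || ref_end < ref_start) {
    stop(sprintf("primer %s: invalid coordinates %d..%d", name, ref_start, ref_end))
  }
  if (ref_end - ref_start + 1L != nchar(sequence)) {
    stop(sprintf(
      "primer %s: window %d..%d has length %d but the sequence has length %d",
      name, ref_start, ref_end, ref_end - ref_start + 1L, nchar(sequence)))
  }
  targets <- match.arg(targets, SSU_GROUPS, several.ok = TRUE)
  structure(
    list(name = name, sequence = sequence, orientation = orientation,
         ref_start = ref_start, ref_end = ref_end,
         reference = reference, targets = targets),
    class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s)\n", x$name, x$orientation))
  cat(sprintf("  5'-%s-3'  (%d nt, degeneracy %d)\n",
              x$sequence, nchar(x$sequence), degeneracy_count(x)))
  cat(sprintf("  %s:%d-%d  targets: %s\n", x$reference, x$ref_start,
              x$ref_end, paste(x$targets, collapse = ", ")))
  invisible(x)
}

#' Reference-orientation sequence of a primer's binding site
#'
#' Fragments are extracted from alignments in reference orientation, so a
#' forward primer is compared as written while a reverse primer is compared
#' as its reverse complement. One extraction pass thus serves both primers
#' of a pair.
#'
#' @param primer a [degenerate_primer()].
#' @return IUPAC sequence string in reference orientation.
#' @export
binding_site_sequence <- function(primer) {
  stopifnot(inherits(primer, "degenerate_primer"))
  if (primer$orientation == "forward") primer$sequence
  else reverse_complement(primer$sequence)
}

#' Read primer definitions from a YAML config file
#'
#' The config holds a top-level `primers:` list; each entry has `name`,
#' `sequence` (5'-to-3' as the primer anneals), `orientation`, `ref_start`
#' and optionally `ref_end` (1-based inclusive), `reference`, and `targets`
#' (subset of [SSU_GROUPS]; defaults to all four for universal primers).
#' A top-level `pairs:` list of `{fwd, rev}` entries is returned alongside.
#'
#' @param path path to the YAML file.
#' @return list with elements `primers` (named list of [degenerate_primer()])
#'   and `pairs` (data.frame with columns `fwd`, `rev`; zero rows if absent).
#' @export
read_primer_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$primers) || length(cfg$primers) == 0L) {
    stop("config has no `primers` entries: ", path)
  }
  primers <- lapply(cfg$primers, function(p) {
    for (field in c("name", "sequence", "orientation", "ref_start")) {
      if (is.null(p[[field]])) {
        stop(sprintf("primer entry missing required field `%s` in %s", field, path))
      }
    }
    degenerate_primer(
      name = p$name, sequence = p$sequence, orientation = p$orientation,
      ref_start = p$ref_start, ref_end = p$ref_end,
      reference = if (is.null(p$reference)) "Ec16S" else p$reference,
      targets = if (is.null(p$targets)) SSU_GROUPS else unlist(p$targets))
  })
  names(primers) <- vapply(primers, `[[`, character(1L), "name")
  if (anyDuplicated(names(primers))) {
    stop("duplicate primer names in config: ",
         paste(unique(names(primers)[duplicated(names(primers))]), collapse = ", "))
  }
  pairs <- if (is.null(cfg$pairs)) {
    data.frame(fwd = character(0), rev = character(0))
  } else {
    data.frame(
      fwd = vapply(cfg$pairs, `[[`, character(1L), "fwd"),
      rev = vapply(cfg$pairs, `[[`, character(1L), "rev"))
  }
  for (nm in c(pairs$fwd, pairs$rev)) {
    if (!nm %in% names(primers)) stop("pair references unknown primer: ", nm)
  }
  list(primers = primers, pairs = pairs)
}
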