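# Observed primer-site variants and minimal-mixture design. A degenerate
# primer is shorthand for a mixture of concrete oligos; rather than widening
# degeneracies (which multiplies the number of synthesised oligos and
# dilutes perfect matches), a minimal mixture lists exactly the variants
# actually observed in the environment above an abundance threshold.

#' Tabulate observed primer-site variants
#'
#' Counts the distinct primer-region sequences among filtered fragments,
#' per dataset (sample) and overall. Variants are reported in the primer's
#' own 5'-to-3' orientation (fragments from reverse primers are
#' reverse-complemented), so each row is directly a candidate synthesis
#' oligo.
#'
#' The overall relative abundance across datasets is by default the
#' unweighted mean of per-dataset relative abundances, giving each
#' environment equal weight regardless of sequencing depth;
#' `weighting = "pooled"` weights by read counts instead.
#'
#' @param fragments filtered fragment data.frame (see [evaluate_primer()]).
#' @param primer a [degenerate_primer()].
#' @param weighting `"mean"` (default) or `"pooled"`.
#' @param min_count variants whose count is below this in every dataset are
#'   flagged `possible_error` (the long tail of rare variants that may
#'   derive from sequencing error); they stay in the table but are excluded
#'   from mixture design by default.
#' @return object of class `variant_table`: list with `primer` (the
#'   [degenerate_primer()]), `table` (data.frame: `variant`,
#'   `n_mismatches`, `matched`, `count_total`, `overall_abundance`,
#'   `possible_error`, sorted by overall abundance descending with ties
#'   broken lexicographically), `counts` and `abundance` (variant x dataset
#'   matrices aligned with `table` rows), and `weighting`.
#' @export
tabulate_variants <- function(fragments, primer,
                              weighting = c("mean", "pooled"),
                              min_count = 2L) {
  stopifnot(inherits(primer, "degenerate_primer"))
  weighting <- match.arg(weighting)
  if (nrow(fragments) == 0L) stop("no fragments to tabulate")
  variant <- fragments$bases
  if (primer$orientation == "reverse") variant <- reverse_complement(variant)
  counts <- table(variant = variant, dataset = fragments$sample_id)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  abund <- sweep(counts, 2L, colSums(counts), "/")
  overall <- if (weighting == "mean") rowMeans(abund)
             else rowSums(counts) / sum(counts)
  mm <- count_mismatches(primer$sequence, rownames(counts))
  tab <- data.frame(
    variant = rownames(counts),
    n_mismatches = mm,
    matched = mm == 0L,
    count_total = rowSums(counts),
    overall_abundance = overall,
    possible_error = apply(counts, 1L, max) < min_count,
    stringsAsFactors = FALSE)
  ord <- order(-tab$overall_abundance, tab$variant)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(
    list(primer = primer, table = tab,
         counts = counts[ord, , drop = FALSE],
         abundance = abund[ord, , drop = FALSE],
         weighting = weighting),
    class = "variant_table")
}

#' @export
print.variant_table <- function(x, n = 10L, ...) {
  cat(sprintf("<variant_table> %s: %d variants across %d dataset(s)\n",
              x$primer$name, nrow(x$table), ncol(x$counts)))
  cat(sprintf("  matched overall abundance: %.4f\n",
              sum(x$table$overall_abundance[x$table$matched])))
  print(utils::head(x$table, n))
  invisible(x)
}

#' Design a minimal explicit oligonucleotide mixture
#'
#' Starting from a nondegenerate seed oligo, adds every observed variant
#' whose overall relative abundance across datasets exceeds a threshold,
#' plus any curated additions (e.g. variants for taxa known to be missed
#' that enter via a `must_include` file rather than database lookups). The
#' result is an explicit mixture tailored to the environmental sequences
#' actually present, rather than a fully degenerate consensus most of
#' whose expansions never occur in nature.
#'
#' @param table a [tabulate_variants()] result.
#' @param seed nondegenerate seed oligo; defaults to the highest-abundance
#'   variant perfectly matched by the primer (or the overall
#'   highest-abundance variant if none is matched).
#' @param abundance_threshold include variants with overall relative
#'   abundance strictly greater than this (default 0.02, i.e. >2%).
#' @param must_include character vector (or FASTA path) of curated oligos
#'   to force into the mixture.
#' @param exclude_errors drop `possible_error`-flagged variants from the
#'   abundance rule (default TRUE); curated additions are never dropped.
#' @return object of class `mixture_design`: list with `primer_name`,
#'   `seed`, `oligos` (data.frame: `oligo`, `justification`),
#'   `achieved_coverage` (named vector per dataset plus `"overall"`,
#'   recomputed from the variant table), `n_oligos`, `degenerate_union`
#'   and `union_degeneracy`, plus the observed variant table for
#'   redundancy accounting.
#' @export
design_mixture <- function(table, seed = NULL, abundance_threshold = 0.02,
                           must_include = NULL, exclude_errors = TRUE) {
  stopifnot(inherits(table, "variant_table"))
  if (abundance_threshold <= 0 || abundance_threshold > 1) {
    stop("abundance_threshold must be in (0, 1]")
  }
  tab <- table$table
  plen <- nchar(table$primer$sequence)
  if (is.null(seed)) {
    cand <- if (any(tab$matched)) tab$variant[tab$matched] else tab$variant
    seed <- cand[[1L]]
  }
  seed <- normalize_iupac(seed, what = "seed oligo")
  if (grepl("[^ACGT]", seed)) stop("seed oligo must be nondegenerate (A/C/G/T)")
  if (nchar(seed) != plen) {
    stop(sprintf("seed length %d differs from primer length %d",
                 nchar(seed), plen))
  }
  if (is.character(must_include) && length(must_include) == 1L &&
      file.exists(must_include)) {
    must_include <- as.character(Biostrings::readDNAStringSet(must_include))
  }
  if (length(must_include)) {
    must_include <- normalize_iupac(must_include, what = "curated oligo")
    if (any(nchar(must_include) != plen)) {
      stop("curated oligos must all have the primer length")
    }
    if (any(grepl("[^ACGT]", must_include))) {
      stop("curated oligos must be nondegenerate (A/C/G/T)")
    }
  }
  eligible <- tab$overall_abundance > abundance_threshold
  if (exclude_errors) eligible <- eligible & !tab$possible_error
  by_abundance <- tab$variant[eligible]

  oligo <- unique(c(seed, by_abundance, must_include))
  justification <- character(length(oligo))
  justification[match(unique(must_include), oligo)] <- "curated"
  justification[oligo %in% by_abundance & justification == ""] <-
    sprintf("observed abundance > %g", abundance_threshold)
  justification[oligo == seed][1L] <-
    if (seed %in% by_abundance) "seed (observed)" else "seed"
  justification[justification == ""] <- "curated"

  in_mix <- tab$variant %in% oligo
  per_ds <- colSums(table$abundance[in_mix, , drop = FALSE])
  achieved <- c(per_ds, overall = sum(tab$overall_abundance[in_mix]))
  union_seq <- degenerate_union(oligo)
  structure(
    list(primer_name = table$primer$name, seed = seed,
         oligos = data.frame(oligo = oligo, justification = justification,
                             stringsAsFactors = FALSE),
         achieved_coverage = achieved,
         n_oligos = length(oligo),
         degenerate_union = union_seq,
         union_degeneracy = degeneracy_count(union_seq),
         abundance_threshold = abundance_threshold,
         observed = tab$variant),
    class = "mixture_design")
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design> %s-min: %d oligos (union %s, degeneracy %d)\n",
              x$primer_name, x$n_oligos, x$degenerate_union,
              x$union_degeneracy))
  cat(sprintf("  overall achieved coverage: %.4f\n",
              x$achieved_coverage[["overall"]]))
  print(x$oligos)
  invisible(x)
}

#' Compare an explicit mixture with its fully degenerate equivalent
#'
#' Achieving the mixture's coverage through added degeneracies alone would
#' require synthesising every expansion of the minimal degenerate union of
#' the mixture -- usually far more oligos, most never observed in the data
#' (redundant oligonucleotides that dilute the perfectly matching ones).
#'
#' @param design a [design_mixture()] result.
#' @return data.frame (one row): `n_oligos`, `union_degeneracy`, `ratio`
#'   (union degeneracy / mixture size) and `n_redundant` (union expansions
#'   never observed among the tabulated variants).
#' @export
compare_mixture_vs_degenerate <- function(design) {
  stopifnot(inherits(design, "mixture_design"))
  expansions <- expand_primer(design$degenerate_union,
                              cap = max(4096L, design$union_degeneracy))
  data.frame(
    primer_name = design$primer_name,
    n_oligos = design$n_oligos,
    union_degeneracy = design$union_degeneracy,
    ratio = design$union_degeneracy / design$n_oligos,
    n_redundant = sum(!expansions %in% design$observed),
    stringsAsFactors = FALSE)
}

.mismatch_matrix <- function(pseq, variants) {
  n <- nchar(pseq)
  pm <- .seq_masks(pseq)
  fm <- .MASK_LOOKUP[utf8ToInt(paste(variants, collapse = ""))]
  matrix(bitwAnd(fm, pm) == 0L, nrow = n)  # n x length(variants), TRUE = mismatch
}

#' Rank single-position degeneracy widenings of a primer
#'
#' For each primer position, finds the minimal IUPAC widening that would
#' newly match the variants whose only mismatch lies at that position, and
#' ranks positions by the overall relative abundance so gained. This is
#' how a dominant one-mismatch taxon is rescued by a single added
#' degeneracy.
#'
#' @param table a [tabulate_variants()] result.
#' @param primer the [degenerate_primer()] to improve (defaults to the
#'   table's primer).
#' @param max_added maximum number of suggestions returned (each an
#'   independent single-code edit to the original primer).
#' @return data.frame ranked by `abundance_gain` descending: `position`
#'   (1-based in the primer's 5'-to-3' sequence), `old_code`, `new_code`,
#'   `abundance_gain`, `new_sequence`, `new_degeneracy`. Zero rows if every
#'   variant is already matched or no single edit helps.
#' @export
suggest_degeneracies <- function(table, primer = NULL, max_added = 3L) {
  stopifnot(inherits(table, "variant_table"))
  if (is.null(primer)) primer <- table$primer
  pseq <- primer$sequence
  tab <- table$table
  mm <- count_mismatches(pseq, tab$variant)
  single <- which(mm == 1L)
  empty <- data.frame(position = integer(0), old_code = character(0),
                      new_code = character(0), abundance_gain = numeric(0),
                      new_sequence = character(0), new_degeneracy = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(single) == 0L) return(empty)
  mmat <- .mismatch_matrix(pseq, tab$variant[single])
  pos <- apply(mmat, 2L, which)  # the single mismatching position per variant
  pm <- .seq_masks(pseq)
  rows <- lapply(sort(unique(pos)), function(p) {
    idx <- single[pos == p]
    gain <- sum(tab$overall_abundance[idx])
    obs_masks <- .MASK_LOOKUP[utf8ToInt(paste(substr(tab$variant[idx], p, p),
                                              collapse = ""))]
    new_mask <- Reduce(bitwOr, c(pm[p], obs_masks))
    new_code <- .MASK_TO_CODE[new_mask]
    new_seq <- pseq
    substr(new_seq, p, p) <- new_code
    data.frame(position = p,
               old_code = substr(pseq, p, p),
               new_code = new_code,
               abundance_gain = gain,
               new_sequence = new_seq,
               new_degeneracy = degeneracy_count(new_seq),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$abundance_gain, out$position), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, max_added)
}
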