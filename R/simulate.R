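# Deterministic synthetic-data generator. Produces every input the other
# stages consume -- group-specific SSU references, sheared reads with
# qualities as FASTQ + SAM, group sidecars, paired abundance tables -- with
# full ground truth recorded, so planted parameters can be recovered and
# checked end to end without any external data.

#' Build a variant pool for a primer's binding site
#'
#' A pool is the set of window sequences (reference orientation) a
#' simulated read draws from when it spans the primer window, with planted
#' frequencies. The first entry is a perfect match (one expansion of the
#' binding site); the remaining entries carry `1..k` guaranteed mismatches
#' introduced at deterministic positions outside the primer's IUPAC sets.
#'
#' @param primer a [degenerate_primer()].
#' @param match_freq planted frequency of the perfectly matching variant.
#' @param mismatch_freqs frequencies of the mismatched variants; together
#'   with `match_freq` they must sum to 1. The i-th mismatched variant
#'   carries i mismatches.
#' @param seed integer seed making the mutated variants reproducible.
#' @return data.frame with columns `sequence`, `freq`, `n_mismatches`.
#' @export
variant_pool <- function(primer, match_freq = 0.75,
                         mismatch_freqs = c(0.15, 0.07, 0.03), seed = 1L) {
  stopifnot(inherits(primer, "degenerate_primer"))
  freqs <- c(match_freq, mismatch_freqs)
  if (abs(sum(freqs) - 1) > 1e-9) stop("pool frequencies must sum to 1")
  site <- binding_site_sequence(primer)
  match_var <- expand_primer(site)[1L]
  n <- nchar(site)
  masks <- .seq_masks(site)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  mutable <- which(masks != 15L)  # an N position cannot mismatch
  if (length(mutable) < length(mismatch_freqs)) {
    stop("primer has too few non-N positions to plant mismatched variants")
  }
  variants <- vapply(seq_along(mismatch_freqs), function(k) {
    v <- match_var
    pos <- mutable[sample.int(length(mutable), k)]
    for (p in pos) {
      outside <- .BASES[bitwAnd(c(1L, 2L, 4L, 8L), masks[p]) == 0L]
      substr(v, p, p) <- sample(outside, 1L)
    }
    v
  }, character(1L))
  data.frame(sequence = c(match_var, variants), freq = freqs,
             n_mismatches = c(0L, seq_along(mismatch_freqs)),
             stringsAsFactors = FALSE)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Specify a read simulation
#'
#' Collects everything [simulate_reference()] and [simulate_reads()] need.
#' Defaults emulate a shotgun survey at desk scale: 150-base reads (the
#' short-read regime in which primer regions are observed unlinked),
#' 2000 reads per sample and group, a 1600-base SSU-like reference, and a
#' two-level quality model (passing reads at Q40, a planted fraction of
#' failing reads at Q2) that makes quality-filter outcomes exactly
#' predictable.
#'
#' @param primers list of [degenerate_primer()]s sharing one reference
#'   name; windows must not overlap.
#' @param pools named list: for each group (subset of [SSU_GROUPS]), a
#'   named list of [variant_pool()] data.frames, one per primer name.
#' @param seed RNG seed; every generator output is a pure function of the
#'   spec including this seed.
#' @param reference_length reference length in bases.
#' @param read_length read length in bases; must exceed the longest primer
#'   window by at least 10.
#' @param n_reads reads per sample per group.
#' @param sample_ids character vector of sample identifiers.
#' @param quality_fail_rate planted fraction of reads written with Q2
#'   bases (removed by the default Phred-30 mean-quality filter).
#' @param q_pass,q_fail Phred scores of the two read classes.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(primers, pools, seed = 1L,
                            reference_length = 1600L, read_length = 150L,
                            n_reads = 2000L,
                            sample_ids = c("sample1", "sample2", "sample3"),
                            quality_fail_rate = 0.1, q_pass = 40L,
                            q_fail = 2L) {
  stopifnot(length(primers) >= 1L, length(pools) >= 1L)
  if (is.null(names(pools)) || !all(names(pools) %in% SSU_GROUPS)) {
    stop("pools must be named by group (one of: ",
         paste(SSU_GROUPS, collapse = ", "), ")")
  }
  pnames <- vapply(primers, `[[`, character(1L), "name")
  names(primers) <- pnames
  refs <- unique(vapply(primers, `[[`, character(1L), "reference"))
  if (length(refs) != 1L) stop("all primers must share one reference name")
  for (p in primers) {
    if (p$ref_end + 5L > reference_length) {
      stop(sprintf("window of %s exceeds the reference (need length >= %d)",
                   p$name, p$ref_end + 5L))
    }
    if (read_length <= nchar(p$sequence) + 10L) {
      stop("read_length must exceed the primer length by more than 10")
    }
  }
  for (g in names(pools)) {
    for (pn in names(pools[[g]])) {
      if (!pn %in% pnames) stop("pool for unknown primer: ", pn)
      pool <- pools[[g]][[pn]]
      stopifnot(is.data.frame(pool), all(c("sequence", "freq") %in% names(pool)))
      if (abs(sum(pool$freq) - 1) > 1e-9) {
        stop(sprintf("pool %s/%s frequencies must sum to 1", g, pn))
      }
      if (any(nchar(pool$sequence) != nchar(primers[[pn]]$sequence))) {
        stop(sprintf("pool %s/%s has sequences of the wrong length", g, pn))
      }
    }
  }
  structure(
    list(primers = primers, pools = pools, seed = as.integer(seed),
         reference_name = refs, reference_length = as.integer(reference_length),
         read_length = as.integer(read_length), n_reads = as.integer(n_reads),
         sample_ids = sample_ids, quality_fail_rate = quality_fail_rate,
         q_pass = as.integer(q_pass), q_fail = as.integer(q_fail)),
    class = "simulation_spec")
}

#' Simulate group-specific reference sequences
#'
#' One random A/C/G/T reference per group, deterministic in the spec seed,
#' with each primer's pool consensus (the pool's first, perfectly matching
#' variant) embedded at the primer's window coordinates.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir if non-NULL, write one FASTA per group (named
#'   `<group>.fasta`, record id = the shared reference name).
#' @return named list (per group) of reference sequence strings; file
#'   paths attached as `attr(, "paths")` when written.
#' @export
simulate_reference <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  refs <- lapply(names(spec$pools), function(g) {
    ref <- paste(sample(.BASES, spec$reference_length, replace = TRUE),
                 collapse = "")
    for (p in spec$primers) {
      pool <- spec$pools[[g]][[p$name]]
      if (is.null(pool)) next
      substr(ref, p$ref_start, p$ref_end) <- pool$sequence[[1L]]
    }
    ref
  })
  names(refs) <- names(spec$pools)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(refs), function(g) {
      path <- file.path(out_dir, paste0(g, ".fasta"))
      dna <- Biostrings::DNAStringSet(refs[[g]])
      names(dna) <- spec$reference_name
      Biostrings::writeXStringSet(dna, path)
      path
    }, character(1L))
    attr(refs, "paths") <- paths
  }
  refs
}

.write_sam <- function(path, reference_name, reference_length, qname, pos,
                       seq, qual) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", reference_name, reference_length))
  records <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                     qname, reference_name, pos, nchar(seq), seq, qual)
  writeLines(c(header, records), path)
}

#' Simulate sheared reads over the references
#'
#' Uniform random read start positions per sample and group; every read
#' fully covering a primer window draws its window sequence from that
#' group's variant pool at the planted frequencies. Reads are written as
#' FASTQ (Phred+33) and as headered single-reference SAM per sample and
#' group, with a read-to-group sidecar and a ground-truth table recording,
#' per read and primer, the drawn variant and whether the read qualifies
#' for extraction under the +/-5-base flank spanning rule.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory (created if needed).
#' @param flank flank width used for the ground-truth qualifying flag.
#' @param both_sides ground-truth spanning rule variant (see
#'   [extract_fragments()]).
#' @return list with `files` (data.frame: `sample_id`, `group`, `sam`,
#'   `fastq`), `truth` (one row per read x primer), `sidecar`
#'   (`read_id`, `group`) and `references`.
#' @export
simulate_reads <- function(spec, out_dir = tempfile("sim"), flank = 5L,
                           both_sides = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- simulate_reference(spec, out_dir = file.path(out_dir, "refs"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed + 1L)
  rl <- spec$read_length
  L <- spec$reference_length
  q_pass_str <- strrep(intToUtf8(spec$q_pass + 33L), rl)
  q_fail_str <- strrep(intToUtf8(spec$q_fail + 33L), rl)

  files <- list()
  truth <- list()
  for (s in spec$sample_ids) {
    for (g in names(spec$pools)) {
      n <- spec$n_reads
      if (n > 0L) {
        starts <- sample.int(L - rl + 1L, n, replace = TRUE)
        ends <- starts + rl - 1L
        fails <- stats::runif(n) < spec$quality_fail_rate
        ids <- sprintf("%s:%s:%06d", s, g, seq_len(n))
        seqs <- substring(refs[[g]], starts, ends)
        rows <- list()
        for (p in spec$primers) {
          pool <- spec$pools[[g]][[p$name]]
          rs <- p$ref_start
          re <- p$ref_end
          covers <- starts <= rs & ends >= re
          variant <- rep(NA_character_, n)
          if (!is.null(pool) && any(covers)) {
            draw <- sample.int(nrow(pool), sum(covers), replace = TRUE,
                               prob = pool$freq)
            variant[covers] <- pool$sequence[draw]
            idx <- which(covers)
            off <- rs - starts[idx] + 1L
            for (j in seq_along(idx)) {
              substr(seqs[idx[j]], off[j], off[j] + (re - rs)) <-
                variant[idx[j]]
            }
          }
          left_ok <- starts <= rs - flank
          right_ok <- ends >= re + flank
          qualifies <- covers &
            (if (both_sides) left_ok & right_ok else left_ok | right_ok)
          rows[[p$name]] <- data.frame(
            read_id = ids, sample_id = s, group = g, primer = p$name,
            start = starts, end = ends, variant = variant,
            qualifies = qualifies, passes_quality = !fails,
            stringsAsFactors = FALSE)
        }
        truth[[paste(s, g)]] <- do.call(rbind, rows)
        quals <- ifelse(fails, q_fail_str, q_pass_str)
        fastq <- file.path(out_dir, sprintf("%s_%s.fastq", s, g))
        writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), fastq)
        sam <- file.path(out_dir, sprintf("%s_%s.sam", s, g))
        .write_sam(sam, spec$reference_name, L, ids, starts, seqs, quals)
      } else {
        fastq <- file.path(out_dir, sprintf("%s_%s.fastq", s, g))
        sam <- file.path(out_dir, sprintf("%s_%s.sam", s, g))
        writeLines(character(0), fastq)
        .write_sam(sam, spec$reference_name, L, character(0), integer(0),
                   character(0), character(0))
      }
      files[[paste(s, g)]] <- data.frame(
        sample_id = s, group = g, sam = sam, fastq = fastq,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(read_id = character(0), sample_id = character(0),
               group = character(0), primer = character(0),
               start = integer(0), end = integer(0),
               variant = character(0), qualifies = logical(0),
               passes_quality = logical(0))
  rownames(truth) <- NULL
  sidecar <- unique(truth[, c("read_id", "group")])
  rownames(sidecar) <- NULL
  files <- do.call(rbind, files)
  rownames(files) <- NULL
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sidecar, file.path(out_dir, "sidecar.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(files = files, truth = truth, sidecar = sidecar, references = refs,
       out_dir = out_dir)
}

#' Simulate paired amplicon/metagenome abundance tables
#'
#' The metagenome table is drawn from a Dirichlet-like positive
#' composition (independent gamma variates, column-normalised); the
#' amplicon table equals it up to multiplicative lognormal noise applied
#' per taxon and sample. `sigma = 0` gives exact equality, so downstream
#' regression returns R-squared 1 in the noise-free limit. Taxa are
#' assigned round-robin to a smaller set of groups, standing in for the
#' clustering of ASVs up to the resolution identifiable from short reads.
#'
#' @param n_taxa number of taxa (rows).
#' @param n_samples number of samples (columns).
#' @param n_groups number of broader groups taxa collapse into.
#' @param sigma standard deviation of the lognormal noise (natural log
#'   scale).
#' @param seed RNG seed.
#' @param concentration gamma shape parameter of the composition draw.
#' @return list with `amplicon` and `metagenome` (taxon x sample relative
#'   abundance matrices), `mapping` (data.frame `taxon`, `group`) and
#'   `sigma`.
#' @export
simulate_paired_tables <- function(n_taxa = 12L, n_samples = 6L,
                                   n_groups = 5L, sigma = 0, seed = 1L,
                                   concentration = 1) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  taxa <- sprintf("taxon%02d", seq_len(n_taxa))
  samples <- sprintf("sample%02d", seq_len(n_samples))
  met <- matrix(stats::rgamma(n_taxa * n_samples, shape = concentration),
                nrow = n_taxa, dimnames = list(taxa, samples))
  noise <- if (sigma > 0) {
    exp(matrix(stats::rnorm(n_taxa * n_samples, sd = sigma), nrow = n_taxa))
  } else 1
  amp <- met * noise
  mapping <- data.frame(
    taxon = taxa,
    group = sprintf("group%02d", rep_len(seq_len(n_groups), n_taxa)),
    stringsAsFactors = FALSE)
  list(amplicon = normalize_abundance(amp),
       metagenome = normalize_abundance(met),
       mapping = mapping, sigma = sigma)
}

#' Demo simulation specification
#'
#' A small bundled scenario used by the command-line `simulate` subcommand
#' and the worked examples: the 515Y (forward) / 926R (reverse) universal
#' primer pair at their conventional 16S coordinates, all four organismal
#' categories with group-specific planted match frequencies, three
#' samples, 2000 reads per sample and group.
#'
#' @param seed RNG seed.
#' @return a [simulation_spec()].
#' @export
demo_simulation_spec <- function(seed = 1L) {
  p515Y <- degenerate_primer("515Y", "GTGYCAGCMGCCGCGGTAA", "forward", 515L)
  p926R <- degenerate_primer("926R", "CCGYCAATTYMTTTRAGTTT", "reverse", 907L)
  match_freqs <- c(Archaea = 0.95, Bacteria = 0.9,
                   Cyanobacteria_plastid = 0.85, Eukarya = 0.7)
  pools <- lapply(seq_along(match_freqs), function(i) {
    f <- match_freqs[[i]]
    rest <- 1 - f
    list(
      "515Y" = variant_pool(p515Y, f, rest * c(0.6, 0.3, 0.1), seed = seed + i),
      "926R" = variant_pool(p926R, f, rest * c(0.6, 0.3, 0.1),
                            seed = seed + 10L + i))
  })
  names(pools) <- names(match_freqs)
  simulation_spec(primers = list(p515Y, p926R), pools = pools, seed = seed)
}
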