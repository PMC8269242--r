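# Coverage statistics: per sample x group x primer match fractions at
# 0/1/2-mismatch thresholds, primer-pair combination with taxonomic-overlap
# correction, and the worst-case lower bound on pair coverage.

#' Per-sample, per-group primer coverage at 0/1/2-mismatch thresholds
#'
#' Coverage at k mismatches is the fraction of scored fragments with at
#' most k mismatches to the primer; 0-mismatch coverage (the fraction of
#' perfect matches) is the headline statistic, since even a single
#' primer-template mismatch can strongly bias PCR. Groups with no
#' fragments are reported with `NA` coverage, never 0/0.
#'
#' @param fragments scored fragment data.frame (see [score_fragments()];
#'   [evaluate_primer()] output is already scored).
#' @param primer a [degenerate_primer()]; used to score if `n_mismatches`
#'   is absent, and for the primer name.
#' @param thresholds mismatch thresholds to tabulate (default 0, 1, 2).
#' @param all_groups if TRUE, emit a row for every sample x [SSU_GROUPS]
#'   combination; groups without fragments get `n_total = 0` and `NA`
#'   coverage (absence of evidence is not zero coverage).
#' @return data.frame with one row per sample x group: `n_total`,
#'   `n_match_0mm`, `n_match_1mm`, `n_match_2mm` (cumulative counts) and
#'   `coverage_0mm`, `coverage_1mm`, `coverage_2mm`.
#' @export
coverage <- function(fragments, primer, thresholds = c(0L, 1L, 2L),
                     all_groups = FALSE) {
  stopifnot(inherits(primer, "degenerate_primer"))
  if (is.null(fragments$n_mismatches)) {
    fragments <- score_fragments(fragments, primer)
  }
  thresholds <- sort(as.integer(thresholds))
  if (nrow(fragments) == 0L) {
    out <- data.frame(sample_id = character(0), group = character(0),
                      primer_name = character(0), n_total = integer(0))
    for (k in thresholds) out[[sprintf("n_match_%dmm", k)]] <- integer(0)
    for (k in thresholds) out[[sprintf("coverage_%dmm", k)]] <- numeric(0)
    return(out)
  }
  key <- interaction(fragments$sample_id, fragments$group, drop = TRUE,
                     lex.order = TRUE, sep = "\r")
  splits <- split(fragments$n_mismatches, key)
  parts <- strsplit(names(splits), "\r", fixed = TRUE)
  out <- data.frame(
    sample_id = vapply(parts, `[[`, character(1L), 1L),
    group = vapply(parts, `[[`, character(1L), 2L),
    primer_name = primer$name,
    n_total = vapply(splits, length, integer(1L)),
    stringsAsFactors = FALSE)
  for (k in thresholds) {
    out[[sprintf("n_match_%dmm", k)]] <-
      vapply(splits, function(mm) sum(mm <= k), integer(1L))
  }
  for (k in thresholds) {
    out[[sprintf("coverage_%dmm", k)]] <-
      ifelse(out$n_total > 0L, out[[sprintf("n_match_%dmm", k)]] / out$n_total,
             NA_real_)
  }
  if (all_groups) {
    full <- expand.grid(sample_id = unique(fragments$sample_id),
                        group = SSU_GROUPS, stringsAsFactors = FALSE)
    out <- merge(full, out, by = c("sample_id", "group"), all.x = TRUE)
    out$primer_name <- primer$name
    out$n_total[is.na(out$n_total)] <- 0L
    for (k in thresholds) {
      cnt <- sprintf("n_match_%dmm", k)
      out[[cnt]][is.na(out[[cnt]]) & out$n_total == 0L] <- 0L
    }
    out <- out[order(out$sample_id, out$group), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Worst-case combined coverage of a primer pair
#'
#' Lower bound on the fraction of templates perfectly matched by both
#' primers of a pair, assuming the sets of organisms missed by the forward
#' and reverse primers are disjoint:
#' `max(0, 1 - ((1 - coverage_fwd) + (1 - coverage_rev)))`.
#'
#' @param coverage_fwd,coverage_rev perfect-match (0-mismatch) coverage
#'   fractions; vectorised.
#' @return worst-case pair coverage in \[0, 1\].
#' @examples
#' worst_case_pair(0.98, 0.97)  # 0.95
#' worst_case_pair(0.4, 0.4)    # 0 (clamped)
#' @export
worst_case_pair <- function(coverage_fwd, coverage_rev) {
  stopifnot(is.numeric(coverage_fwd), is.numeric(coverage_rev))
  pmax(0, 1 - ((1 - coverage_fwd) + (1 - coverage_rev)))
}

#' Combined coverage of a forward/reverse primer pair
#'
#' Joins per-sample, per-group coverage records of the two primers and
#' reports pair coverage only over groups targeted by BOTH primers -- the
#' taxonomic-overlap correction (e.g. a 16S-only reverse primer
#' contributes no Eukarya rows, because nuclear 18S rRNA cannot be
#' amplified by the pair regardless of the forward primer's match).
#'
#' Because the two primer regions are observed on different short reads
#' and cannot be linked per template molecule, the default combination
#' rule is the independence product `coverage_fwd * coverage_rev`; `min`
#' and the [worst_case_pair()] lower bound are computed alongside and the
#' chosen rule is recorded in the output.
#'
#' @param cov_fwd,cov_rev coverage data.frames from [coverage()] for the
#'   forward and reverse primer.
#' @param fwd,rev the corresponding [degenerate_primer()] objects (their
#'   `targets` define the overlap correction).
#' @param rule combination rule for the `pair_coverage` column:
#'   `"product"` (default), `"min"` or `"worst_case"`.
#' @return data.frame with one row per sample x targeted group:
#'   `coverage_fwd`, `coverage_rev`, `product`, `min`, `worst_case`,
#'   `pair_coverage`, `rule`, `overlap_corrected`.
#' @export
pair_coverage <- function(cov_fwd, cov_rev, fwd, rev,
                          rule = c("product", "min", "worst_case")) {
  rule <- match.arg(rule)
  stopifnot(inherits(fwd, "degenerate_primer"),
            inherits(rev, "degenerate_primer"))
  shared <- intersect(fwd$targets, rev$targets)
  if (length(shared) == 0L) {
    warning(sprintf("primers %s and %s target disjoint group sets",
                    fwd$name, rev$name))
  }
  f <- cov_fwd[cov_fwd$group %in% shared,
               c("sample_id", "group", "coverage_0mm")]
  r <- cov_rev[cov_rev$group %in% shared,
               c("sample_id", "group", "coverage_0mm")]
  names(f)[3L] <- "coverage_fwd"
  names(r)[3L] <- "coverage_rev"
  m <- merge(f, r, by = c("sample_id", "group"))
  if (nrow(m)) m <- m[order(m$sample_id, m$group), , drop = FALSE]
  m$fwd_primer <- fwd$name
  m$rev_primer <- rev$name
  m$product <- m$coverage_fwd * m$coverage_rev
  m$min <- pmin(m$coverage_fwd, m$coverage_rev)
  m$worst_case <- worst_case_pair(m$coverage_fwd, m$coverage_rev)
  m$pair_coverage <- m[[rule]]
  m$rule <- rule
  m$overlap_corrected <- !setequal(shared, SSU_GROUPS) ||
    !setequal(fwd$targets, rev$targets)
  rownames(m) <- NULL
  m[, c("sample_id", "group", "fwd_primer", "rev_primer", "coverage_fwd",
        "coverage_rev", "product", "min", "worst_case", "pair_coverage",
        "rule", "overlap_corrected")]
}

#' Summarise coverage across samples
#'
#' Median, quartiles and range of each coverage column per primer x group
#' across samples; the median is the headline figure reported for a primer
#' in an environment.
#'
#' @param records coverage data.frame from [coverage()] (or
#'   [pair_coverage()] with `value_cols = "pair_coverage"`).
#' @param value_cols coverage columns to summarise.
#' @return data.frame with one row per primer x group x statistic column:
#'   `median`, `q25`, `q75`, `min`, `max`, `n_samples`.
#' @export
summarize_across_samples <- function(records,
                                     value_cols = grep("^coverage_",
                                                       names(records),
                                                       value = TRUE)) {
  stopifnot(nrow(records) >= 1L)
  pcol <- if ("primer_name" %in% names(records)) "primer_name" else "fwd_primer"
  key <- interaction(records[[pcol]], records$group, drop = TRUE,
                     lex.order = TRUE, sep = "\r")
  res <- lapply(value_cols, function(cl) {
    splits <- split(records[[cl]], key)
    parts <- strsplit(names(splits), "\r", fixed = TRUE)
    data.frame(
      primer_name = vapply(parts, `[[`, character(1L), 1L),
      group = vapply(parts, `[[`, character(1L), 2L),
      statistic = cl,
      n_samples = vapply(splits, function(x) sum(!is.na(x)), integer(1L)),
      median = vapply(splits, function(x) stats::median(x, na.rm = TRUE), numeric(1L)),
      q25 = vapply(splits, function(x) unname(stats::quantile(x, 0.25, na.rm = TRUE)), numeric(1L)),
      q75 = vapply(splits, function(x) unname(stats::quantile(x, 0.75, na.rm = TRUE)), numeric(1L)),
      min = vapply(splits, function(x) suppressWarnings(min(x, na.rm = TRUE)), numeric(1L)),
      max = vapply(splits, function(x) suppressWarnings(max(x, na.rm = TRUE)), numeric(1L)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Box-and-whisker display of coverage distributions
#'
#' One box per primer x group over the per-sample perfect-match coverage,
#' mirroring the usual way primer-coverage distributions are compared
#' across taxonomic categories.
#'
#' @param records coverage data.frame from [coverage()] (possibly rbind-ed
#'   over primers).
#' @param value column to plot (default `"coverage_0mm"`).
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot statistics.
#' @export
plot_coverage <- function(records, value = "coverage_0mm", ...) {
  pcol <- if ("primer_name" %in% names(records)) "primer_name" else "fwd_primer"
  fml <- stats::as.formula(paste(value, "~", pcol, "+ group"))
  invisible(graphics::boxplot(fml, data = records, las = 2,
                              ylab = "perfect-match coverage", ...))
}
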