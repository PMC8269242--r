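# Amplicon vs metagenome community-composition concordance: aggregate two
# taxon-by-sample abundance tables to a common taxonomic resolution,
# normalise to relative abundances, and regress per sample. Short
# metagenomic reads can sometimes be attributed only to a broad group, so
# ASVs are clustered up to that shared resolution before comparing.

.as_abundance_matrix <- function(x, what = "abundance table") {
  if (is.data.frame(x)) {
    first_chr <- is.character(x[[1L]]) || is.factor(x[[1L]])
    if (first_chr) {
      m <- as.matrix(x[, -1L, drop = FALSE])
      rownames(m) <- as.character(x[[1L]])
      x <- m
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix or data.frame (taxa x samples)")
  }
  if (is.null(rownames(x))) stop(what, " must have taxon rownames")
  if (any(x < 0)) stop(what, " contains negative entries")
  x
}

#' Normalise a taxon-by-sample table to relative abundances
#'
#' Divides each sample column by its sum so columns sum to 1; idempotent.
#' All-zero columns are left at zero with a warning.
#'
#' @param x numeric matrix or data.frame, taxa in rows, samples in columns
#'   (a first character column is treated as taxon names).
#' @return numeric matrix of relative abundances.
#' @export
normalize_abundance <- function(x) {
  m <- .as_abundance_matrix(x)
  cs <- colSums(m)
  if (any(cs == 0)) warning("all-zero sample column(s) left unnormalised")
  cs[cs == 0] <- 1
  sweep(m, 2L, cs, "/")
}

#' Read a taxon-by-sample abundance table from TSV
#'
#' First column holds taxon identifiers, remaining columns one sample
#' each; `#`-prefixed lines are comments.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with taxon rownames.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  .as_abundance_matrix(df, what = path)
}

#' Aggregate two abundance tables to a shared set of groups
#'
#' Sums abundances over a taxon-to-group mapping in both tables; groups
#' observed in only one source get explicit zero rows in the other, so a
#' taxon seen by one method but not the other counts against concordance
#' rather than being dropped.
#'
#' @param amplicon,metagenome taxon-by-sample matrices or data.frames.
#' @param mapping data.frame with columns `taxon`, `group`; every taxon in
#'   either table must map to exactly one group.
#' @return list with `amplicon` and `metagenome` group-by-sample matrices
#'   with identical row and column order.
#' @export
aggregate_to_common_groups <- function(amplicon, metagenome, mapping) {
  stopifnot(is.data.frame(mapping), all(c("taxon", "group") %in% names(mapping)))
  if (anyDuplicated(mapping$taxon)) {
    stop("taxa mapped to more than one group: ",
         paste(unique(mapping$taxon[duplicated(mapping$taxon)]), collapse = ", "))
  }
  amp <- .as_abundance_matrix(amplicon, "amplicon table")
  met <- .as_abundance_matrix(metagenome, "metagenome table")
  unmapped <- setdiff(c(rownames(amp), rownames(met)), mapping$taxon)
  if (length(unmapped)) {
    stop("unmapped taxa: ", paste(unmapped, collapse = ", "))
  }
  roll <- function(m) {
    g <- mapping$group[match(rownames(m), mapping$taxon)]
    rowsum(m, group = g)
  }
  a <- roll(amp)
  b <- roll(met)
  groups <- sort(union(rownames(a), rownames(b)))
  pad <- function(m) {
    out <- matrix(0, nrow = length(groups), ncol = ncol(m),
                  dimnames = list(groups, colnames(m)))
    out[rownames(m), ] <- m
    out
  }
  list(amplicon = pad(a), metagenome = pad(b))
}

#' Per-sample linear regression of amplicon on metagenome composition
#'
#' Ordinary least squares of amplicon relative abundance on metagenome
#' relative abundance across groups, per sample; the coefficient of
#' determination R-squared is the concordance statistic. Both tables are
#' renormalised to relative abundances first, so the fit is invariant to
#' common positive scaling of either table's raw counts. Groups absent
#' from both sources in a sample are dropped from that sample's fit.
#'
#' @param paired list with `amplicon` and `metagenome` group-by-sample
#'   matrices (see [aggregate_to_common_groups()]), with matching columns.
#' @param log10 regress on log10 abundances (zeros dropped) instead of the
#'   untransformed relative abundances; off by default.
#' @return data.frame with one row per sample: `sample_id`, `n_groups`,
#'   `r_squared`, `slope`, `intercept`, `reason` (`NA` for a reported fit;
#'   otherwise why the fit is null, e.g. fewer than 3 groups or degenerate
#'   variance).
#' @export
regress_concordance <- function(paired, log10 = FALSE) {
  amp <- normalize_abundance(paired$amplicon)
  met <- normalize_abundance(paired$metagenome)
  stopifnot(identical(dim(amp), dim(met)),
            identical(rownames(amp), rownames(met)))
  if (!identical(colnames(amp), colnames(met))) {
    stop("amplicon and metagenome tables have different sample columns")
  }
  rows <- lapply(colnames(amp), function(s) {
    y <- amp[, s]
    x <- met[, s]
    keep <- x > 0 | y > 0
    if (log10) keep <- x > 0 & y > 0
    x <- x[keep]
    y <- y[keep]
    if (log10) {
      x <- log10(x)
      y <- log10(y)
    }
    null_row <- function(reason) {
      data.frame(sample_id = s, n_groups = sum(keep),
                 r_squared = NA_real_, slope = NA_real_,
                 intercept = NA_real_, reason = reason,
                 stringsAsFactors = FALSE)
    }
    if (sum(keep) < 3L) return(null_row("fewer than 3 groups"))
    if (stats::var(x) == 0) return(null_row("degenerate variance in metagenome"))
    if (stats::var(y) == 0) return(null_row("degenerate variance in amplicon"))
    fit <- stats::lm(y ~ x)
    # coefficient of determination of the simple OLS fit; identical to
    # summary(fit)$r.squared but silent in the exact-fit limit
    r2 <- stats::cor(x, y)^2
    data.frame(sample_id = s, n_groups = sum(keep), r_squared = r2,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full concordance analysis from raw tables
#'
#' Convenience wrapper: [aggregate_to_common_groups()] then
#' [regress_concordance()].
#'
#' @inheritParams aggregate_to_common_groups
#' @inheritParams regress_concordance
#' @return per-sample concordance data.frame (see [regress_concordance()]).
#' @export
concordance <- function(amplicon, metagenome, mapping, log10 = FALSE) {
  regress_concordance(
    aggregate_to_common_groups(amplicon, metagenome, mapping),
    log10 = log10)
}

#' Stratify concordance results by depth
#'
#' Reports, per depth stratum, the fraction of samples whose R-squared
#' falls below a threshold -- concordance typically degrades below the
#' euphotic zone, so the default split is 150 m and the default threshold
#' 0.95.
#'
#' @param results concordance data.frame (see [regress_concordance()]).
#' @param metadata data.frame with columns `sample_id`, `depth_m`.
#' @param depth_split stratum boundary in metres (default 150).
#' @param r2_threshold R-squared threshold (default 0.95).
#' @return data.frame with one row per stratum: `stratum`, `n_samples`,
#'   `n_below`, `fraction_below`.
#' @export
depth_summary <- function(results, metadata, depth_split = 150,
                          r2_threshold = 0.95) {
  stopifnot(all(c("sample_id", "depth_m") %in% names(metadata)))
  m <- merge(results, metadata[, c("sample_id", "depth_m")], by = "sample_id")
  missing <- setdiff(results$sample_id, metadata$sample_id)
  if (length(missing)) {
    stop("samples without depth metadata: ", paste(missing, collapse = ", "))
  }
  m <- m[!is.na(m$r_squared), , drop = FALSE]
  m$stratum <- ifelse(m$depth_m > depth_split,
                      sprintf(">%g m", depth_split),
                      sprintf("<=%g m", depth_split))
  splits <- split(m$r_squared, m$stratum)
  out <- data.frame(
    stratum = names(splits),
    n_samples = vapply(splits, length, integer(1L)),
    n_below = vapply(splits, function(x) sum(x < r2_threshold), integer(1L)),
    stringsAsFactors = FALSE)
  out$fraction_below <- ifelse(out$n_samples > 0, out$n_below / out$n_samples, NA_real_)
  rownames(out) <- NULL
  out
}

#' Depth profile of concordance
#'
#' Scatter of per-sample R-squared against depth, depth increasing
#' downwards as in oceanographic profiles.
#'
#' @param results concordance data.frame.
#' @param metadata data.frame with `sample_id`, `depth_m`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_concordance_profile <- function(results, metadata, ...) {
  m <- merge(results, metadata[, c("sample_id", "depth_m")], by = "sample_id")
  graphics::plot(m$r_squared, m$depth_m, ylim = rev(range(m$depth_m)),
                 xlab = expression(R^2), ylab = "depth (m)", ...)
}
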