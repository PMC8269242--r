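# Machine-readable reporting and the end-to-end demo pipeline behind the
# command-line interface. The canonical output dialect is TSV (tab, UTF-8)
# with '#'-prefixed header lines recording the tool version and the
# parameters that produced the file, so every report is self-describing
# and byte-identical across reruns with the same seed.

.ps_version <- function() {
  as.character(utils::packageVersion("primerscope"))
}

#' Write a data.frame as a self-describing TSV report
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named character/numeric vector recorded as `# key=value`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path, params = c()) {
  header <- c(sprintf("# primerscope %s", .ps_version()),
              if (length(params)) {
                sprintf("# %s=%s", names(params), as.character(params))
              })
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract, filter and score fragments for a set of alignment files
#'
#' Runs [evaluate_primer()] over a file manifest (one SAM per sample and
#' group, as produced by [simulate_reads()] or an upstream alignment
#' step) and pools the scored fragments and conservation tallies.
#'
#' @param files data.frame with columns `sample_id`, `group`, `sam`.
#' @param primer a [degenerate_primer()].
#' @param ... passed to [evaluate_primer()] (thresholds, spanning rule).
#' @return list with `fragments` (pooled scored data.frame) and `tally`.
#' @export
evaluate_files <- function(files, primer, ...) {
  stopifnot(all(c("sample_id", "group", "sam") %in% names(files)))
  parts <- lapply(seq_len(nrow(files)), function(i) {
    evaluate_primer(files$sam[i], primer, sample_id = files$sample_id[i],
                    groups = files$group[i], ...)
  })
  frags <- do.call(rbind, lapply(parts, `[[`, "fragments"))
  rownames(frags) <- NULL
  tally <- Reduce(`+`, lapply(parts, `[[`, "tally"))
  list(fragments = frags, tally = tally)
}

#' Run the bundled demo pipeline end to end
#'
#' simulate -> extract -> evaluate -> pairs -> variants -> design on the
#' demo scenario ([demo_simulation_spec()]), writing every stage's TSV/JSON
#' report under `out_dir`. Identical seed and spec give byte-identical
#' outputs; this is both the smoke test and the worked example.
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed for the simulation.
#' @param spec optionally, a custom [simulation_spec()]; it must contain
#'   the primers named by `pair`.
#' @param pair character vector of length 2: forward and reverse primer
#'   names for the pair stage.
#' @param rule pair combination rule (see [pair_coverage()]).
#' @return named list of output file paths, invisibly; the computed
#'   objects are attached as `attr(, "results")`.
#' @export
run_demo_pipeline <- function(out_dir, seed = 1L, spec = NULL,
                              pair = c("515Y", "926R"), rule = "product") {
  if (is.null(spec)) spec <- demo_simulation_spec(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_reads(spec, out_dir = file.path(out_dir, "sim"))
  outputs <- list()
  results <- list(spec = spec, sim = sim)
  covs <- list()
  for (p in spec$primers) {
    ev <- evaluate_files(sim$files, p)
    cov <- coverage(ev$fragments, p)
    covs[[p$name]] <- cov
    path <- file.path(out_dir, sprintf("coverage_%s.tsv", p$name))
    write_report_tsv(cov, path, c(seed = spec$seed, primer = p$name,
                                  sequence = p$sequence,
                                  thresholds = "0,1,2", exclusion_mm = 6,
                                  min_mean_quality = 30,
                                  coordinates = "1-based inclusive"))
    outputs[[sprintf("coverage_%s", p$name)]] <- path

    vt <- tabulate_variants(ev$fragments, p)
    vpath <- file.path(out_dir, sprintf("variants_%s.tsv", p$name))
    write_report_tsv(vt$table, vpath,
                     c(seed = spec$seed, primer = p$name,
                       weighting = vt$weighting,
                       orientation = "primer 5'->3'"))
    outputs[[sprintf("variants_%s", p$name)]] <- vpath

    des <- design_mixture(vt)
    dpath <- file.path(out_dir, sprintf("design_%s_oligos.tsv", p$name))
    write_report_tsv(des$oligos, dpath,
                     c(seed = spec$seed, primer = p$name,
                       abundance_threshold = des$abundance_threshold,
                       seed_oligo = des$seed))
    jpath <- file.path(out_dir, sprintf("design_%s.json", p$name))
    jsonlite::write_json(
      list(primer = p$name, n_oligos = des$n_oligos,
           degenerate_union = des$degenerate_union,
           union_degeneracy = des$union_degeneracy,
           achieved_coverage = as.list(des$achieved_coverage),
           comparison = compare_mixture_vs_degenerate(des)),
      jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs[[sprintf("design_%s", p$name)]] <- c(dpath, jpath)
    results[[sprintf("evaluate_%s", p$name)]] <- ev
    results[[sprintf("variants_%s", p$name)]] <- vt
    results[[sprintf("design_%s", p$name)]] <- des
  }
  fwd <- spec$primers[[pair[1L]]]
  rev <- spec$primers[[pair[2L]]]
  pc <- pair_coverage(covs[[fwd$name]], covs[[rev$name]], fwd, rev,
                      rule = rule)
  ppath <- file.path(out_dir, "pair_coverage.tsv")
  write_report_tsv(pc, ppath, c(seed = spec$seed, rule = rule,
                                fwd = fwd$name, rev = rev$name))
  outputs$pair_coverage <- ppath
  results$pair_coverage <- pc

  summ <- summarize_across_samples(do.call(rbind, unname(covs)))
  spath <- file.path(out_dir, "coverage_summary.tsv")
  write_report_tsv(summ, spath, c(seed = spec$seed))
  outputs$coverage_summary <- spath
  results$summary <- summ

  attr(outputs, "results") <- results
  invisible(outputs)
}
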