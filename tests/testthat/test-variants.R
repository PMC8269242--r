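frag_df <- function(bases, sample_id = "s1", group = "Bacteria",
                    primer = "p") {
  data.frame(read_id = sprintf("%s_r%d", sample_id, seq_along(bases)),
             sample_id = sample_id, group = group, primer = primer,
             bases = bases, mean_quality = 40, flank_side = "both")
}

test_that("tabulate_variants counts distinct sequences with exact abundances", {
  p <- degenerate_primer("p", "ACGY", "forward", 1)
  fr <- frag_df(rep(c("ACGC", "ACGA", "TCGA"), c(70, 20, 10)))
  vt <- tabulate_variants(fr, p)
  expect_equal(vt$table$variant, c("ACGC", "ACGA", "TCGA"))
  expect_equal(vt$table$overall_abundance, c(0.7, 0.2, 0.1))
  expect_identical(vt$table$matched, c(TRUE, FALSE, FALSE))
  expect_identical(vt$table$n_mismatches, c(0L, 1L, 2L))
  # single variant collapses to one row of abundance 1
  vt1 <- tabulate_variants(frag_df(rep("ACGT", 5)), p)
  expect_equal(nrow(vt1$table), 1)
  expect_equal(vt1$table$overall_abundance, 1)
})

test_that("overall abundance weights datasets equally by default", {
  p <- degenerate_primer("p", "AC", "forward", 1)
  fr <- rbind(frag_df(rep(c("AC", "AG"), c(90, 10)), sample_id = "d1"),
              frag_df(rep(c("AC", "AG"), c(5, 5)), sample_id = "d2"))
  vt <- tabulate_variants(fr, p)
  expect_equal(vt$table$overall_abundance[vt$table$variant == "AG"],
               mean(c(0.1, 0.5)))
  vtp <- tabulate_variants(fr, p, weighting = "pooled")
  expect_equal(vtp$table$overall_abundance[vtp$table$variant == "AG"],
               15 / 110)
  # per-dataset abundances always sum to 1
  expect_equal(unname(colSums(vt$abundance)), c(1, 1))
})

test_that("variants from a reverse primer are reported in primer orientation", {
  p <- degenerate_primer("r", "ACGTY", "reverse", 1)
  # fragment equal to the reference-strand binding site RACGT
  fr <- frag_df("AACGT", primer = "r")
  vt <- tabulate_variants(fr, p)
  expect_identical(vt$table$variant, "ACGTT")
  expect_true(vt$table$matched)
})

test_that("design_mixture applies the strict abundance threshold", {
  p <- degenerate_primer("p", "NNNN", "forward", 1)
  abunds <- c(0.50, 0.25, 0.15, 0.05, 0.03, 0.02)
  vars <- c("AAAA", "CAAA", "GAAA", "TAAA", "ACAA", "AGAA")
  fr <- frag_df(rep(vars, round(abunds * 100)))
  vt <- tabulate_variants(fr, p, min_count = 1L)
  des <- design_mixture(vt, seed = "AAAA", abundance_threshold = 0.02)
  # exactly the five variants > 2% (the 0.02 one is excluded), seed included
  expect_setequal(des$oligos$oligo, vars[1:5])
  expect_equal(des$achieved_coverage[["overall"]], 1 - 0.02)
  expect_equal(des$n_oligos, 5)
})

test_that("threshold limits reproduce the degenerate extremes", {
  p <- degenerate_primer("p", "NNN", "forward", 1)
  fr <- frag_df(c(rep("AAA", 6), rep("CCC", 3), "GGG"))
  vt <- tabulate_variants(fr, p, min_count = 1L)
  all_in <- design_mixture(vt, seed = "AAA", abundance_threshold = 1e-9)
  expect_setequal(all_in$oligos$oligo, c("AAA", "CCC", "GGG"))
  expect_equal(all_in$achieved_coverage[["overall"]], 1)
  seed_only <- design_mixture(vt, seed = "TTT", abundance_threshold = 1)
  expect_identical(seed_only$oligos$oligo, "TTT")
  expect_equal(seed_only$achieved_coverage[["overall"]], 0)
})

test_that("coverage is non-decreasing in mixture size (conservation)", {
  p <- degenerate_primer("p", "NNNN", "forward", 1)
  set.seed(31)
  fr <- frag_df(sample(c("AAAA", "CAAA", "GAAA", "TAAA", "TTTT"), 400,
                       replace = TRUE, prob = c(0.4, 0.3, 0.15, 0.1, 0.05)))
  vt <- tabulate_variants(fr, p, min_count = 1L)
  thresholds <- c(0.5, 0.2, 0.12, 0.07, 0.01)
  covs <- vapply(thresholds, function(thr) {
    d <- design_mixture(vt, seed = vt$table$variant[1],
                        abundance_threshold = thr)
    # achieved coverage equals 1 minus the abundance of excluded variants
    excluded <- setdiff(vt$table$variant, d$oligos$oligo)
    expect_equal(
      d$achieved_coverage[["overall"]],
      1 - sum(vt$table$overall_abundance[vt$table$variant %in% excluded]))
    d$achieved_coverage[["overall"]]
  }, numeric(1))
  expect_true(all(diff(covs) >= -1e-12))
})

test_that("the degenerate union of a design covers all its oligos", {
  p <- degenerate_primer("p", "NNNN", "forward", 1)
  set.seed(17)
  for (i in 1:10) {
    fr <- frag_df(replicate(50, random_fragment(4)))
    vt <- tabulate_variants(fr, p, min_count = 1L)
    des <- design_mixture(vt, seed = vt$table$variant[1],
                          abundance_threshold = 0.05)
    expanded <- expand_primer(des$degenerate_union, cap = 1e6)
    expect_true(all(des$oligos$oligo %in% expanded))
    expect_true(des$n_oligos <= des$union_degeneracy)
  }
})

test_that("mixture vs degenerate comparison counts redundant expansions", {
  p <- degenerate_primer("p", "NNN", "forward", 1)
  fr <- frag_df(c(rep("ACG", 6), rep("ATC", 4)))
  vt <- tabulate_variants(fr, p, min_count = 1L)
  des <- design_mixture(vt, seed = "ACG", abundance_threshold = 0.1)
  expect_identical(des$degenerate_union, "AYS")
  cmp <- compare_mixture_vs_degenerate(des)
  expect_equal(cmp$n_oligos, 2)
  expect_equal(cmp$union_degeneracy, 4)
  # union expands to ACC, ACG, ATC, ATG; ACC and ATG never observed
  expect_equal(cmp$n_redundant, 2)
  expect_equal(cmp$ratio, 2)
})

test_that("a planted high-ratio scenario is reported faithfully", {
  p <- degenerate_primer("p", "NNNNN", "forward", 1)
  # two oligos differing at four 2-way positions: union degeneracy 16 vs 2
  fr <- frag_df(rep(c("AAAAA", "CCCCA"), c(60, 40)))
  vt <- tabulate_variants(fr, p, min_count = 1L)
  des <- design_mixture(vt, seed = "AAAAA", abundance_threshold = 0.1)
  cmp <- compare_mixture_vs_degenerate(des)
  expect_equal(cmp$union_degeneracy, 16)
  expect_true(cmp$ratio >= 8)
})

test_that("suggest_degeneracies finds the single-position rescue", {
  # a primer-orientation variant mismatching 785R only at position 7
  p785 <- degenerate_primer("785R", "GACTACHVGGGTATCTAATCC", "reverse", 785)
  matched <- sub("H", "A", sub("V", "A", p785$sequence, fixed = TRUE),
                 fixed = TRUE)
  sar11 <- matched
  substr(sar11, 7, 7) <- "G"   # G is outside H = {A,C,T}
  # fragments arrive in reference orientation for a reverse primer
  fr <- frag_df(reverse_complement(rep(c(matched, sar11), c(60, 40))),
                primer = "785R")
  vt <- tabulate_variants(fr, p785)
  sug <- suggest_degeneracies(vt)
  expect_equal(sug$position[1], 7)
  expect_identical(sug$old_code[1], "H")
  expect_identical(sug$new_code[1], "N")
  expect_identical(sug$new_sequence[1], "GACTACNVGGGTATCTAATCC")
  expect_equal(sug$new_degeneracy[1], 12)
  expect_equal(sug$abundance_gain[1], 0.4)
})

test_that("suggestions are ranked by abundance gained and are exact", {
  p <- degenerate_primer("p", "AAAA", "forward", 1)
  fr <- frag_df(rep(c("AAAA", "ACAA", "AAAG"), c(60, 30, 10)))
  vt <- tabulate_variants(fr, p, min_count = 1L)
  sug <- suggest_degeneracies(vt)
  expect_equal(sug$position, c(2, 4))
  expect_equal(sug$abundance_gain, c(0.3, 0.1))
  expect_identical(sug$new_code, c("M", "R"))
  # applying the top edit increases matched abundance by exactly the gain
  before <- sum(vt$table$overall_abundance[vt$table$matched])
  mm_after <- count_mismatches(sug$new_sequence[1], vt$table$variant)
  after <- sum(vt$table$overall_abundance[mm_after == 0])
  expect_equal(after - before, sug$abundance_gain[1])
  # fully matched table yields no suggestions
  vt2 <- tabulate_variants(frag_df(rep("AAAA", 10)), p, min_count = 1L)
  expect_equal(nrow(suggest_degeneracies(vt2)), 0)
})

test_that("possible sequencing errors are flagged and excluded from design", {
  p <- degenerate_primer("p", "NNN", "forward", 1)
  fr <- rbind(frag_df(c(rep("AAA", 98), "CCC", "GGG"), sample_id = "d1"))
  vt <- tabulate_variants(fr, p, min_count = 2L)
  expect_identical(vt$table$possible_error[vt$table$variant == "CCC"], TRUE)
  expect_identical(vt$table$possible_error[vt$table$variant == "AAA"], FALSE)
  des <- design_mixture(vt, seed = "AAA", abundance_threshold = 0.005)
  expect_false("CCC" %in% des$oligos$oligo)
  # but curated additions always enter
  des2 <- design_mixture(vt, seed = "AAA", abundance_threshold = 0.005,
                         must_include = "CCC")
  expect_true("CCC" %in% des2$oligos$oligo)
  expect_identical(des2$oligos$justification[des2$oligos$oligo == "CCC"],
                   "curated")
})
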