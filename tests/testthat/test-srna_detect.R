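mk_tx <- function(start, end, strand = "+") {
  data.frame(replicon_id = "chr", strand = strand, start = start, end = end,
             max_coverage = 50, libs = "l", stringsAsFactors = FALSE)
}
mk_sites <- function(pos, strand = "+", type = "TSS") {
  data.frame(replicon_id = "chr", strand = strand, position = pos,
             site_type = type, classes = NA_character_, step_height = 10,
             step_factor = 5, enrichment = 5, condition = "c1",
             stringsAsFactors = FALSE)
}
no_sites <- mk_sites(1L)[0, ]

test_that("the built-in fold score counts optimal non-crossing pairs", {
  expect_equal(builtin_fold_score("GGGGAAACCCC"), -4 / 11)
  expect_equal(builtin_fold_score("AAAAAAA"), 0)
  for (seed in 1:50) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "U"), sample(8:20, 1), TRUE),
               collapse = "")
    score <- builtin_fold_score(s)
    expect_gte(score, -0.5)
    expect_lte(score, 0)
  }
})

test_that("the fold score equals exhaustive pairing enumeration", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(6:14, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    expect_equal(builtin_fold_score(s), -oracle_max_pairs(s) / n,
                 info = paste("seed", seed, s))
  }
})

test_that("intergenic transcripts become TSS-anchored sRNA candidates", {
  genes <- make_genes(2000L, 2600L, "+")
  tx <- mk_tx(300L, 379L)  # 80 nt, far from any gene
  tss <- mk_sites(300L)
  cand <- detect_srna_intergenic(tx, genes, tss, no_sites, list())
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$origin, "intergenic")
  expect_equal(cand$tss_position, 300L)
  expect_equal(cand$end_anchor, "transcript_edge")
  expect_equal(c(cand$start, cand$end), c(300L, 379L))

  # overlapping an opposite-strand gene makes it antisense
  anti <- detect_srna_intergenic(mk_tx(2100L, 2200L, "-"), genes,
                                 mk_sites(2200L, "-"), no_sites, list())
  expect_equal(anti$origin, "antisense")

  # overlapping a same-strand gene: not an sRNA candidate at all
  same <- detect_srna_intergenic(mk_tx(2100L, 2200L), genes, tss,
                                 no_sites, list())
  expect_equal(nrow(same), 0L)
})

test_that("overlong candidates are refined to a drop point or PS", {
  genes <- make_genes(5000L, 5400L, "+")
  # 900 nt transcript: coverage plateau 50 for 200 nt then 20 (a sharp
  # relative drop) for the rest
  v <- numeric(1200)
  v[101:1000] <- c(rep(50, 200), rep(20, 700))
  tx <- mk_tx(101L, 1000L)
  tss <- mk_sites(101L)
  cand <- detect_srna_intergenic(tx, genes, tss, no_sites,
                                 list(make_track(v)))
  expect_equal(cand$end_anchor, "drop_point")
  expect_equal(c(cand$start, cand$end), c(101L, 301L))

  # a processing site 5' of the drop point wins
  ps <- mk_sites(260L, type = "PS")
  cand2 <- detect_srna_intergenic(tx, genes, tss, ps, list(make_track(v)))
  expect_equal(cand2$end_anchor, "processing_site")
  expect_equal(cand2$end, 260L)
})

test_that("candidates without a TSS are rejected with a reason", {
  genes <- make_genes(2000L, 2600L, "+")
  gm <- genome("chr", paste(rep("ACGT", 1000), collapse = ""))
  tx <- mk_tx(300L, 379L)
  cand <- detect_srna_intergenic(tx, genes, no_sites, no_sites, list())
  expect_true(is.na(cand$tss_position))
  filtered <- apply_srna_filters(cand, gm)
  expect_false(filtered$passed_filters)
  expect_match(filtered$reject_reasons, "no TSS")
  # the TSS requirement can be deactivated
  relaxed <- apply_srna_filters(cand, gm, require_anchor = FALSE)
  expect_false(grepl("no TSS", relaxed$reject_reasons))
})

test_that("quality filters enforce length and structure", {
  hairpin <- paste0(paste(rep("G", 20), collapse = ""),
                    "AAAA",
                    paste(rep("C", 20), collapse = ""),
                    paste(rep("AC", 18), collapse = ""))  # 80 nt, stable
  polya <- paste(rep("A", 80), collapse = "")
  gm <- genome("chr", paste0(hairpin, polya, paste(rep("A", 40), collapse = "")))
  base <- data.frame(replicon_id = "chr", strand = "+",
                     start = c(1L, 81L, 1L), end = c(80L, 160L, 25L),
                     origin = "intergenic",
                     tss_position = c(1L, 81L, 1L), ps_position = NA_integer_,
                     end_anchor = "transcript_edge", fold_score = NA_real_,
                     passed_filters = NA, reject_reasons = "",
                     stringsAsFactors = FALSE)
  out <- apply_srna_filters(base, gm)
  expect_true(out$passed_filters[1])            # stable 80-mer
  expect_lte(out$fold_score[1], -0.05)
  expect_false(out$passed_filters[2])           # poly-A cannot pair
  expect_match(out$reject_reasons[2], "unstable fold")
  expect_equal(out$fold_score[2], 0)
  expect_false(out$passed_filters[3])           # 25 nt < 30
  expect_match(out$reject_reasons[3], "length<30")

  long <- base[1, ]
  long$end <- 600L
  expect_match(apply_srna_filters(long, genome("chr", paste(rep("A", 700),
                                                            collapse = "")))
               $reject_reasons, "length>500")
})

test_that("known sRNA overlap bypasses the filters", {
  gm <- genome("chr", paste(rep("A", 200), collapse = ""))
  cand <- data.frame(replicon_id = "chr", strand = "+", start = 10L,
                     end = 100L, origin = "intergenic",
                     tss_position = NA_integer_, ps_position = NA_integer_,
                     end_anchor = "transcript_edge", fold_score = NA_real_,
                     passed_filters = NA, reject_reasons = "",
                     stringsAsFactors = FALSE)
  known <- feature_table("chr", "sRNA", 50L, 90L, "+",
                         attributes = list(c(ID = "known1")))
  out <- apply_srna_filters(cand, gm, known = known)
  expect_true(out$passed_filters)
})

test_that("UTR-derived candidates respect their anchor rules", {
  genes <- make_genes(c(500L, 1000L), c(900L, 1400L), c("+", "+"))
  tx <- mk_tx(400L, 1500L)
  # 5'UTR: TSS at 410, PS at 470 inside the 5'UTR
  tss <- mk_sites(410L)
  ps <- mk_sites(470L, type = "PS")
  cand <- detect_srna_utr(tx, genes, tss, ps, list())
  five <- cand[cand$origin == "five_utr", ]
  expect_equal(nrow(five), 1L)
  expect_equal(c(five$start, five$end), c(410L, 470L))
  expect_equal(five$end_anchor, "processing_site")

  # interCDS needs a PS start; without one there is no candidate
  cand2 <- detect_srna_utr(tx, genes, tss, mk_sites(470L, type = "PS"),
                           list())
  expect_equal(sum(cand2$origin == "inter_cds"), 0L)
  ps_mid <- mk_sites(c(470L, 930L, 960L), type = "PS")
  cand3 <- detect_srna_utr(tx, genes, tss, ps_mid, list())
  inter <- cand3[cand3$origin == "inter_cds", ]
  expect_equal(nrow(inter), 1L)
  expect_equal(c(inter$start, inter$end), c(930L, 960L))

  # 3'UTR: starting at a PS, running to the transcript end
  ps3 <- mk_sites(1420L, type = "PS")
  cand4 <- detect_srna_utr(tx, genes, tss, ps3, list())
  three <- cand4[cand4$origin == "three_utr", ]
  expect_equal(nrow(three), 1L)
  expect_equal(c(three$start, three$end), c(1420L, 1500L))
  expect_equal(three$end_anchor, "transcript_edge")
})

test_that("planted sRNAs are recovered through the full chain", {
  truth <- shared_sim$truth
  tx <- merge_with_genes(call_transcripts(shared_sim$cov, treatments = NULL),
                         truth$genes)
  tss <- call_sites(shared_sim$tex_plus, shared_sim$tex_minus, param_set(),
                    "TSS")
  ps <- call_sites(shared_sim$tex_plus, shared_sim$tex_minus, param_set(),
                   "PS")
  cand <- detect_srna_intergenic(tx, truth$genes, tss, ps, shared_sim$cov)
  cand <- apply_srna_filters(cand, truth$genome)
  passed <- cand[cand$passed_filters, ]
  recovered <- vapply(seq_len(nrow(truth$srnas)), function(i) {
    any(passed$strand == truth$srnas$strand[i] &
          passed$start <= truth$srnas$start[i] + 3L &
          passed$end >= truth$srnas$end[i] - 3L)
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
  # every passed candidate satisfies every active filter
  lens <- passed$end - passed$start + 1L
  expect_true(all(lens >= 30L & lens <= 500L))
  expect_true(all(!is.na(passed$tss_position) | passed$origin %in%
                    c("three_utr", "inter_cds")))
  expect_true(all(passed$fold_score <= -0.05))
})
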