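mk_tss <- function(pos, strand = "+", step = 10, classes = NA_character_) {
  data.frame(replicon_id = "chr", strand = strand, position = pos,
             site_type = "TSS", classes = classes, step_height = step,
             step_factor = 5, enrichment = 5, condition = "c1",
             stringsAsFactors = FALSE)
}
mk_transcripts <- function(start, end, strand = "+") {
  data.frame(replicon_id = "chr", strand = strand, start = start, end = end,
             max_coverage = 50, libs = "l", stringsAsFactors = FALSE)
}
no_terminators <- data.frame(replicon_id = character(), strand = character(),
                             start = integer(), end = integer(),
                             method = character(), drop_ratio = numeric(),
                             confirmed = logical(), stringsAsFactors = FALSE)

test_that("5' and 3' UTRs are derived from their anchors", {
  genes <- make_genes(150L, 400L, "+")
  tss <- classify_tss(mk_tss(100L), genes)
  tx <- mk_transcripts(100L, 430L)
  utrs <- derive_utrs(tss, tx, no_terminators, genes)
  five <- utrs[utrs$utr_type == "five_prime", ]
  expect_equal(c(five$start, five$end, five$length), c(100L, 149L, 50L))
  expect_equal(five$anchor, "TSS")
  three <- utrs[utrs$utr_type == "three_prime", ]
  expect_equal(c(three$start, three$end), c(401L, 430L))
  expect_equal(three$anchor, "transcript_edge")

  # no TSS in the transcript: no 5' UTR
  utrs2 <- derive_utrs(classify_tss(mk_tss(5000L), genes), tx,
                       no_terminators, genes)
  expect_equal(sum(utrs2$utr_type == "five_prime"), 0L)
})

test_that("a confirmed terminator bounds the 3' UTR", {
  genes <- make_genes(150L, 400L, "+")
  tss <- classify_tss(mk_tss(100L), genes)
  tx <- mk_transcripts(100L, 480L)
  term <- data.frame(replicon_id = "chr", strand = "+", start = 410L,
                     end = 445L, method = "convergent_heuristic",
                     drop_ratio = 0.2, confirmed = TRUE,
                     stringsAsFactors = FALSE)
  utrs <- derive_utrs(tss, tx, term, genes)
  three <- utrs[utrs$utr_type == "three_prime", ]
  expect_equal(c(three$start, three$end), c(401L, 445L))
  expect_equal(three$anchor, "terminator")
  # an unconfirmed terminator is ignored
  term$confirmed <- FALSE
  three2 <- derive_utrs(tss, tx, term, genes)
  three2 <- three2[three2$utr_type == "three_prime", ]
  expect_equal(three2$end, 480L)
})

test_that("minus-strand UTRs mirror the plus-strand geometry", {
  genes <- make_genes(500L, 900L, "-")
  tss <- classify_tss(mk_tss(950L, strand = "-"), genes)
  tx <- mk_transcripts(460L, 950L, strand = "-")
  utrs <- derive_utrs(tss, tx, no_terminators, genes)
  five <- utrs[utrs$utr_type == "five_prime", ]
  expect_equal(c(five$start, five$end), c(901L, 950L))
  three <- utrs[utrs$utr_type == "three_prime", ]
  expect_equal(c(three$start, three$end), c(460L, 499L))
})

test_that("every UTR abuts its gene exactly", {
  truth <- shared_sim$truth
  tss <- classify_tss(call_sites(shared_sim$tex_plus, shared_sim$tex_minus,
                                 param_set(), "TSS"), truth$genes)
  tx <- merge_with_genes(call_transcripts(shared_sim$cov, treatments = NULL),
                         truth$genes)
  utrs <- derive_utrs(tss, tx, no_terminators, truth$genes)
  expect_gt(nrow(utrs), 0L)
  genes <- truth$genes
  for (i in seq_len(nrow(utrs))) {
    g <- genes[match(utrs$gene_id[i], genes$feature_id), ]
    if (utrs$utr_type[i] == "five_prime") {
      if (utrs$strand[i] == "+") expect_equal(utrs$end[i] + 1L, g$start)
      else expect_equal(utrs$start[i] - 1L, g$end)
    } else {
      if (utrs$strand[i] == "+") expect_equal(utrs$start[i] - 1L, g$end)
      else expect_equal(utrs$end[i] + 1L, g$start)
    }
    expect_gte(utrs$length[i], 1L)
  }
})

test_that("UTR length histogram conserves counts", {
  utrs <- data.frame(utr_type = "five_prime", replicon_id = "chr",
                     strand = "+", start = c(1L, 1L, 1L),
                     end = c(50L, 55L, 120L), gene_id = "g", anchor = "TSS",
                     length = c(50L, 55L, 120L), stringsAsFactors = FALSE)
  h <- utr_length_histogram(utrs, 100L)
  expect_equal(h$count, c(2L, 1L))
  expect_equal(h$bin_start, c(0L, 100L))
  expect_equal(sum(h$count), nrow(utrs))
  expect_equal(nrow(utr_length_histogram(utrs[0, ], 100L)), 0L)
  same <- utr_length_histogram(utrs[c(1, 1, 1), ], 100L)
  expect_equal(nrow(same), 1L)
})

test_that("operons split into sub-operons at internal non-genic TSSs", {
  genes <- make_genes(c(200L, 700L), c(600L, 1100L), c("+", "+"))
  tx <- mk_transcripts(150L, 1150L)
  tss <- classify_tss(mk_tss(c(150L, 650L)), genes)
  ops <- detect_operons(tx, genes, tss)
  expect_equal(nrow(ops), 1L)
  expect_false(ops$monocistronic)
  expect_equal(ops$gene_ids[[1]], c("g01", "g02"))
  sub <- ops$suboperons[[1]]
  expect_equal(nrow(sub), 2L)
  expect_equal(sub$tss_position, c(150L, 650L))
  expect_equal(sub$start, c(150L, 650L))
  expect_equal(sub$end, c(649L, 1150L))

  # single gene, one TSS: monocistronic, one sub-operon
  mono <- detect_operons(mk_transcripts(150L, 650L), genes[1, ],
                         classify_tss(mk_tss(150L), genes[1, ]))
  expect_true(mono$monocistronic)
  expect_equal(nrow(mono$suboperons[[1]]), 1L)

  # transcript with no gene: no operon
  empty <- detect_operons(mk_transcripts(5000L, 5400L), genes,
                          classify_tss(mk_tss(5000L), genes))
  expect_equal(nrow(empty), 0L)
})

test_that("sub-operon intervals are ordered and contained", {
  truth <- shared_sim$truth
  tss <- classify_tss(call_sites(shared_sim$tex_plus, shared_sim$tex_minus,
                                 param_set(), "TSS"), truth$genes)
  tx <- merge_with_genes(call_transcripts(shared_sim$cov, treatments = NULL),
                         truth$genes)
  ops <- detect_operons(tx, truth$genes, tss)
  for (i in seq_len(nrow(ops))) {
    sub <- ops$suboperons[[i]]
    expect_true(all(sub$start >= ops$start[i] & sub$end <= ops$end[i]))
    if (nrow(sub) > 1L) {
      sub <- sub[order(sub$start), ]
      expect_true(all(sub$start[-1L] > sub$end[-nrow(sub)]))
    }
  }
})

test_that("operon totals conserve", {
  genes <- make_genes(c(200L, 700L, 2000L), c(600L, 1100L, 2400L),
                      c("+", "+", "-"))
  tx <- rbind(mk_transcripts(150L, 1150L), mk_transcripts(1950L, 2450L, "-"))
  tss <- classify_tss(mk_tss(150L), genes)
  ops <- detect_operons(tx, genes, tss)
  s <- operon_summary(ops)
  expect_equal(s$total, s$monocistronic + s$polycistronic)
  expect_equal(s$total, 2L)
  expect_equal(s$polycistronic, 1L)
  empty <- operon_summary(detect_operons(tx[0, ], genes, tss))
  expect_equal(unlist(empty), c(total = 0L, monocistronic = 0L,
                                polycistronic = 0L))
})
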