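test_that("ORF scanning respects start/stop and length bounds", {
  # ATG + 10 sense codons + TAA = 36 nt
  body <- paste(rep("GCT", 10), collapse = "")
  orf36 <- paste0("ATG", body, "TAA")
  hits <- find_orfs(paste0("CC", orf36, "CC"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 3L)
  expect_equal(hits$length, 36L)
  expect_equal(hits$frame, 2L)
  expect_equal(hits$start_codon, "ATG")

  expect_equal(nrow(find_orfs("ATGTAA")), 0L)       # 6 nt < 30
  # noncanonical starts only when requested
  gtg <- paste0("GTG", body, "TAA")
  expect_equal(nrow(find_orfs(gtg)), 0L)
  expect_equal(nrow(find_orfs(gtg, start_codons = c("ATG", "GTG"))), 1L)
})

test_that("ORF scanning equals the brute-force triple-loop scan", {
  for (seed in 1:200) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    got <- find_orfs(s)
    want <- oracle_orfs(s)
    expect_equal(got$offset, want$offset, info = paste("seed", seed))
    expect_equal(got$length, want$length, info = paste("seed", seed))
    expect_equal(got$frame, want$frame, info = paste("seed", seed))
  }
})

test_that("RBS matching tolerates the configured mismatches", {
  expect_equal(find_rbs("TTAGGAGGTT"), 3L)
  expect_equal(find_rbs("TTAGGTGGTT", max_mismatch = 1L), 3L)
  expect_equal(find_rbs("TTTTTTTTTT"), integer(0))
  expect_equal(find_rbs("TTAGGTGGTT", max_mismatch = 0L), integer(0))
})

test_that("RBS matching equals the brute-force window scan", {
  for (seed in 1:200) {
    set.seed(seed)
    s <- paste(sample(c("A", "G", "T", "C"), 60, TRUE,
                      prob = c(0.35, 0.35, 0.15, 0.15)), collapse = "")
    mm <- sample(0:2, 1)
    expect_equal(find_rbs(s, max_mismatch = mm),
                 oracle_rbs(s, max_mismatch = mm),
                 info = paste("seed", seed))
  }
})

sorf_region <- function() {
  # pad(4) TSS..RBS gap, AGGAGG, 8 nt spacer, 45 nt ORF, pad
  body <- paste(rep(c("GCT", "GAA", "CGT"), length.out = 13), collapse = "")
  paste0("CTCT", "AGGAGG", "CTCTCTCT", "ATG", body, "TAA",
         "CTCTCTCTCT")
}

test_that("sORFs require an RBS in the accepted window downstream of a TSS", {
  region <- sorf_region()
  gm <- genome("chr", paste0(paste(rep("C", 100), collapse = ""), region,
                             paste(rep("C", 100), collapse = "")))
  tx <- data.frame(replicon_id = "chr", strand = "+", start = 101L,
                   end = 100L + nchar(region), max_coverage = 50,
                   libs = "l", stringsAsFactors = FALSE)
  genes <- make_genes(2000L, 2400L, "+")
  tss <- data.frame(replicon_id = "chr", strand = "+", position = 101L,
                    site_type = "TSS", classes = NA_character_,
                    step_height = 10, step_factor = 5, enrichment = 5,
                    condition = "c1", stringsAsFactors = FALSE)
  hits <- detect_sorfs(tx, genes, tss, NULL, gm)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 101L + 18L)       # ATG at region offset 19
  expect_equal(hits$end - hits$start + 1L, 45L)
  expect_equal(hits$start_codon, "ATG")
  expect_equal(hits$rbs_position, 101L + 4L) # RBS at region offset 5
  expect_equal(hits$tss_position, 101L)
  gap <- hits$start - (hits$rbs_position + 6L) # bases after the RBS 3' edge
  expect_gte(gap - 1L, 3L)
  expect_lte(gap - 1L, 15L)

  # without any TSS there is no sORF
  expect_equal(nrow(detect_sorfs(tx, genes, tss[0, ], NULL, gm)), 0L)
})

test_that("an RBS too far upstream is rejected", {
  body <- paste(rep("GCT", 13), collapse = "")
  region <- paste0("CT", "AGGAGG",
                   paste(rep("CT", 10), collapse = ""),  # 20 nt gap
                   "ATG", body, "TAA", "CTCT")
  gm <- genome("chr", paste0(paste(rep("C", 50), collapse = ""), region))
  tx <- data.frame(replicon_id = "chr", strand = "+", start = 51L,
                   end = 50L + nchar(region), max_coverage = 50, libs = "l",
                   stringsAsFactors = FALSE)
  tss <- data.frame(replicon_id = "chr", strand = "+", position = 51L,
                    site_type = "TSS", classes = NA_character_,
                    step_height = 10, step_factor = 5, enrichment = 5,
                    condition = "c1", stringsAsFactors = FALSE)
  expect_equal(nrow(detect_sorfs(tx, make_genes(2000L, 2400L, "+"), tss,
                                 NULL, gm)), 0L)
})

test_that("transcripts containing annotated CDS are not scanned", {
  region <- sorf_region()
  gm <- genome("chr", paste0(paste(rep("C", 100), collapse = ""), region,
                             paste(rep("C", 100), collapse = "")))
  tx <- data.frame(replicon_id = "chr", strand = "+", start = 101L,
                   end = 100L + nchar(region), max_coverage = 50,
                   libs = "l", stringsAsFactors = FALSE)
  genes <- make_genes(110L, 150L, "+")  # a CDS inside the transcript
  tss <- data.frame(replicon_id = "chr", strand = "+", position = 101L,
                    site_type = "TSS", classes = NA_character_,
                    step_height = 10, step_factor = 5, enrichment = 5,
                    condition = "c1", stringsAsFactors = FALSE)
  expect_equal(nrow(detect_sorfs(tx, genes, tss, NULL, gm)), 0L)
})

test_that("minus-strand detection mirrors the reverse complement", {
  region <- sorf_region()
  n_pad <- 80L
  plus_seq <- paste0(paste(rep("C", n_pad), collapse = ""), region,
                     paste(rep("C", n_pad), collapse = ""))
  L <- nchar(plus_seq)
  minus_seq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(plus_seq)))
  genes <- make_genes(3000L, 3400L, "+")
  tx_plus <- data.frame(replicon_id = "chr", strand = "+",
                        start = n_pad + 1L, end = n_pad + nchar(region),
                        max_coverage = 50, libs = "l",
                        stringsAsFactors = FALSE)
  tss_plus <- data.frame(replicon_id = "chr", strand = "+",
                         position = n_pad + 1L, site_type = "TSS",
                         classes = NA_character_, step_height = 10,
                         step_factor = 5, enrichment = 5, condition = "c1",
                         stringsAsFactors = FALSE)
  plus_hits <- detect_sorfs(tx_plus, genes, tss_plus, NULL,
                            genome("chr", plus_seq))
  tx_minus <- tx_plus
  tx_minus$strand <- "-"
  tx_minus$start <- L - (n_pad + nchar(region)) + 1L
  tx_minus$end <- L - n_pad
  tss_minus <- tss_plus
  tss_minus$strand <- "-"
  tss_minus$position <- L - n_pad
  minus_hits <- detect_sorfs(tx_minus, genes, tss_minus, NULL,
                             genome("chr", minus_seq))
  expect_equal(nrow(minus_hits), nrow(plus_hits))
  expect_equal(L - minus_hits$end + 1L, plus_hits$start)
  expect_equal(L - minus_hits$start + 1L, plus_hits$end)
  expect_equal(minus_hits$start_codon, plus_hits$start_codon)
})
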