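# Shared in-code fixtures.

frag_lib <- seq_library("frag_c1_r1", "fragmented", "c1", 1L)
texp_lib <- seq_library("texp_c1_r1", "TEX_plus", "c1", 1L)
texm_lib <- seq_library("texm_c1_r1", "TEX_minus", "c1", 1L)

make_track <- function(values, strand = "+", lib = frag_lib,
                       replicon = "chr") {
  coverage_track(replicon, strand, lib, values)
}

make_genes <- function(start, end, strand, replicon = "chr",
                       type = "gene") {
  n <- length(start)
  feature_table(replicon, type, start, end, strand,
                attributes = lapply(seq_len(n),
                                    function(i) c(ID = sprintf("g%02d", i))))
}

# a random feature table for round-trip properties
random_features <- function(n, seed) {
  set.seed(seed)
  start <- sort(sample.int(5000L, n))
  len <- sample.int(300L, n)
  feature_table(
    replicon_id = "chr", feature_type = sample(c("gene", "CDS"), n, TRUE),
    start = start, end = start + len, strand = sample(c("+", "-"), n, TRUE),
    score = ifelse(runif(n) < 0.5, NA_real_, round(runif(n, 0, 99), 2)),
    attributes = lapply(seq_len(n), function(i) {
      a <- c(ID = sprintf("f%03d", i))
      if (i %% 3L == 0L) a <- c(a, Parent = sprintf("f%03d", max(1L, i - 1L)),
                                note = "x")
      a
    })
  )
}

# a small annotated simulation shared by several test files
shared_sim <- local({
  sim <- simulate_genome(10000L, 8L, seed = 101L)
  truth <- plant_features(sim, seed = 101L)
  tracks <- simulate_coverage(truth, depth = 50, noise_sd = 0, seed = 101L)
  treat <- vapply(tracks, function(t) t$library$treatment, character(1))
  list(truth = truth, tracks = tracks, treat = treat,
       tex_plus = tracks[treat == "TEX_plus"],
       tex_minus = tracks[treat == "TEX_minus"],
       cov = tracks[treat != "TEX_plus"])
})
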