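test_that("site statistics follow their definitions", {
  tp <- make_track(c(1, 1, 50), lib = texp_lib)
  tm <- make_track(c(1, 1, 5), lib = texm_lib)
  s <- site_statistics(tp, tm, 3L)
  expect_equal(s$step_height, 49)
  expect_equal(s$step_factor, 50)
  expect_equal(s$enrichment, 10)

  flat <- site_statistics(make_track(c(5, 5, 5), lib = texp_lib),
                          make_track(c(5, 5, 5), lib = texm_lib), 2L)
  expect_equal(flat$step_height, 0)
  expect_equal(flat$step_factor, 1)

  zero_minus <- site_statistics(make_track(c(1, 8), lib = texp_lib),
                                make_track(c(1, 0), lib = texm_lib), 2L)
  expect_equal(zero_minus$enrichment, 8)  # pseudo-count denominator

  expect_error(site_statistics(tp, tm, 1L), "upstream")
  minus_tp <- make_track(c(50, 1, 1), strand = "-", lib = texp_lib)
  minus_tm <- make_track(c(5, 1, 1), strand = "-", lib = texm_lib)
  sm <- site_statistics(minus_tp, minus_tm, 1L)  # upstream neighbor is pos 2
  expect_equal(sm$step_height, 49)
  expect_error(site_statistics(minus_tp, minus_tm, 3L), "upstream")
})

test_that("a sharp TEX+ step with flat TEX- yields one TSS", {
  v <- c(rep(1, 10), rep(40, 10), rep(1, 10))
  tp <- list(make_track(v, lib = texp_lib))
  tm <- list(make_track(rep(2, 30), lib = texm_lib))
  tss <- call_sites(tp, tm, param_set(), "TSS")
  expect_equal(nrow(tss), 1L)
  expect_equal(tss$position, 11L)
  expect_equal(tss$site_type, "TSS")
  expect_equal(tss$condition, "c1")
})

test_that("enrichment and step branches are evaluated independently", {
  v <- c(rep(1, 5), rep(40, 5))
  tp <- list(make_track(v, lib = texp_lib))
  tm_same <- list(make_track(v, lib = texm_lib))
  # identical tracks: enrichment = 1 everywhere; a params set that requires
  # enrichment >= 2 for both branches calls nothing
  p_enr <- param_set(height = 100, height_reduction = 99, factor = 100,
                     factor_reduction = 99, enrichment_factor = 2)
  expect_equal(nrow(call_sites(tp, tm_same, p_enr, "TSS")), 0L)
  # while the plain height/factor branch alone still fires (enrichment 1
  # passes the >= 1 guard)
  p_step <- param_set(height = 10, factor = 5, enrichment_factor = 2)
  hit <- call_sites(tp, tm_same, p_step, "TSS")
  expect_equal(hit$position, 6L)
  # and the relaxed branch fires when enrichment is present even though the
  # full height/factor thresholds fail
  tm_flat <- list(make_track(rep(2, 10), lib = texm_lib))
  p_relax <- param_set(height = 100, height_reduction = 100 - 30,
                       factor = 100, factor_reduction = 100 - 30,
                       enrichment_factor = 2)
  hit2 <- call_sites(tp, tm_flat, p_relax, "TSS")
  expect_equal(hit2$position, 6L)
})

test_that("PS mode detects the reverse enrichment pattern", {
  step <- c(rep(1, 10), rep(40, 10))
  flat <- rep(2, 20)
  ps <- call_sites(list(make_track(flat, lib = texp_lib)),
                   list(make_track(step, lib = texm_lib)),
                   param_set(), "PS")
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$position, 11L)
  expect_equal(ps$site_type, "PS")
  # the same data in TSS mode yields nothing (enrichment < 1 at the step)
  expect_equal(nrow(call_sites(list(make_track(flat, lib = texp_lib)),
                               list(make_track(step, lib = texm_lib)),
                               param_set(), "TSS")), 0L)
})

test_that("site calling matches the brute-force threshold oracle", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- 120L
    plus <- pmax(round(rnorm(n, 3, 4), 1), 0)
    minus <- pmax(round(rnorm(n, 3, 4), 1), 0)
    strand <- sample(c("+", "-"), 1)
    params <- param_set(height = runif(1, 0, 3),
                        height_reduction = 0,
                        factor = runif(1, 0, 4), factor_reduction = 0,
                        enrichment_factor = runif(1, 1, 4),
                        processing_site_factor = runif(1, 1, 4),
                        base_height = runif(1, 0, 2))
    mode <- sample(c("TSS", "PS"), 1)
    got <- call_sites(list(make_track(plus, strand, texp_lib)),
                      list(make_track(minus, strand, texm_lib)),
                      params, mode, cluster_width = 0L)
    want <- oracle_site_positions(plus, minus, strand, params, mode)
    expect_equal(got$position, sort(want), info = paste("seed", seed, mode))
  }
})

test_that("raising thresholds never increases the number of calls", {
  set.seed(42)
  plus <- pmax(round(rnorm(200, 3, 5), 1), 0)
  minus <- pmax(round(rnorm(200, 3, 5), 1), 0)
  tp <- list(make_track(plus, lib = texp_lib))
  tm <- list(make_track(minus, lib = texm_lib))
  base <- param_set(height = 0.5, height_reduction = 0, factor = 1,
                    factor_reduction = 0, enrichment_factor = 1.5,
                    base_height = 0)
  # raw (uncluster-merged) calls: merging nearby calls can split or fuse
  # clusters, so the monotone set relation holds at the position level
  n0 <- call_sites(tp, tm, base, "TSS", cluster_width = 0L)$position
  for (param in c("height", "factor", "enrichment_factor", "base_height")) {
    for (mult in c(1.5, 3, 6)) {
      vals <- as.list(unclass(base))
      vals[[param]] <- vals[[param]] * mult
      n1 <- call_sites(tp, tm, do.call(param_set, vals), "TSS",
                       cluster_width = 0L)$position
      expect_true(all(n1 %in% n0), label = paste(param, "x", mult))
    }
  }
})

test_that("clustered calls keep the highest step within the merge width", {
  # two calls 2 nt apart: merged, the larger step wins
  v <- c(1, 1, 30, 1, 60, rep(60, 5))
  tp <- list(make_track(v, lib = texp_lib))
  tm <- list(make_track(rep(2, 10), lib = texm_lib))
  p <- param_set(height = 5, factor = 2, enrichment_factor = 2)
  tss <- call_sites(tp, tm, p, "TSS", cluster_width = 3L)
  expect_equal(nrow(tss), 1L)
  expect_equal(tss$position, 5L)  # step of 59 beats step of 29
  wide <- call_sites(tp, tm, p, "TSS", cluster_width = 0L)
  expect_equal(wide$position, c(3L, 5L))
})

test_that("TSS classification assigns the documented classes", {
  sites <- data.frame(replicon_id = "chr", strand = "+",
                      position = c(450L, 380L), site_type = "TSS",
                      classes = NA_character_,
                      step_height = c(20, 5), step_factor = 10,
                      enrichment = 5, condition = "c1",
                      stringsAsFactors = FALSE)
  gene <- make_genes(500L, 900L, "+")
  out <- classify_tss(sites, gene)
  expect_equal(out$classes[1], "primary")    # higher step
  expect_equal(out$classes[2], "secondary")

  anti <- data.frame(replicon_id = "chr", strand = "-", position = 600L,
                     site_type = "TSS", classes = NA_character_,
                     step_height = 9, step_factor = 9, enrichment = 9,
                     condition = "c1", stringsAsFactors = FALSE)
  expect_equal(classify_tss(anti, gene)$classes, "antisense")

  internal <- data.frame(replicon_id = "chr", strand = "+", position = 700L,
                         site_type = "TSS", classes = NA_character_,
                         step_height = 9, step_factor = 9, enrichment = 9,
                         condition = "c1", stringsAsFactors = FALSE)
  expect_equal(classify_tss(internal, gene)$classes, "internal")

  orphan <- data.frame(replicon_id = "chr", strand = "+", position = 5000L,
                       site_type = "TSS", classes = NA_character_,
                       step_height = 9, step_factor = 9, enrichment = 9,
                       condition = "c1", stringsAsFactors = FALSE)
  expect_equal(classify_tss(orphan, gene)$classes, "orphan")
})

test_that("every classified TSS carries at least one class", {
  tss <- call_sites(shared_sim$tex_plus, shared_sim$tex_minus, param_set(),
                    "TSS")
  out <- classify_tss(tss, shared_sim$truth$genes)
  expect_true(all(nzchar(out$classes)))
  # a TSS can carry several classes w.r.t. different genes; the class sets
  # partition consistently (orphan excludes everything else)
  multi <- strsplit(out$classes, ",")
  expect_true(all(vapply(multi, function(cl) {
    !("orphan" %in% cl && length(cl) > 1L)
  }, logical(1))))
})

test_that("evaluation matches calls to curated positions greedily", {
  cur <- curated_set(data.frame(replicon_id = "chr", strand = "+",
                                position = 100L), 1L, 1000L)
  mk_calls <- function(pos) {
    data.frame(replicon_id = "chr", strand = "+", position = pos,
               site_type = "TSS", classes = NA_character_, step_height = 1,
               step_factor = 1, enrichment = 1, condition = "c1",
               stringsAsFactors = FALSE)
  }
  hit <- evaluate_sites(mk_calls(101L), cur, match_tolerance = 2L)
  expect_equal(hit$TP, 1L)
  expect_equal(hit$FP, 0L)
  expect_equal(hit$TPR, 1)

  miss <- evaluate_sites(mk_calls(150L), cur, match_tolerance = 2L)
  expect_equal(miss$TP, 0L)
  expect_equal(miss$FP, 1L)
  # calls outside the curated region are not evaluated
  outside <- evaluate_sites(mk_calls(5000L), cur, match_tolerance = 2L)
  expect_equal(outside$FP, 0L)
})

test_that("the false-positive rate uses region length minus positives", {
  set.seed(1)
  cur_pos <- sort(sample.int(10000L, 100L))
  cur <- curated_set(data.frame(replicon_id = "chr", strand = "+",
                                position = cur_pos), 1L, 10000L)
  # 33 calls far away from every curated position
  far <- setdiff(seq(3L, 10000L, by = 7L), as.vector(outer(cur_pos, -3:3, "+")))
  calls <- data.frame(replicon_id = "chr", strand = "+",
                      position = far[1:33], site_type = "TSS",
                      classes = NA_character_, step_height = 1,
                      step_factor = 1, enrichment = 1, condition = "c1",
                      stringsAsFactors = FALSE)
  st <- evaluate_sites(calls, cur, match_tolerance = 2L)
  expect_equal(st$FP, 33L)
  expect_equal(st$FPR, 33 / 9900)
})
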