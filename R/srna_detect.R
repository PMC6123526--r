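# Small noncoding RNA detection: candidates of five origins (intergenic,
# antisense, 5'UTR-, 3'UTR-, interCDS-derived) anchored on TSSs, processing
# sites, and coverage drop points, followed by quality filters (length
# range, TSS requirement, secondary-structure stability).

#' Default sRNA detection parameters
#'
#' @param tss_tolerance Maximum distance (nt) between a candidate 5' end
#'   and a TSS.
#' @param min_len,max_len Accepted candidate length range (nt).
#' @param fold_cutoff Maximum per-nucleotide fold score for a stable
#'   structure (more negative = more stable).
#' @param drop_ratio Decrease ratio for 3'-end refinement by
#'   [find_drop_point()].
#' @return Named list of parameters.
#' @export
srna_params <- function(tss_tolerance = 3L, min_len = 30L, max_len = 500L,
                        fold_cutoff = -0.05, drop_ratio = 0.5) {
  list(tss_tolerance = tss_tolerance, min_len = min_len, max_len = max_len,
       fold_cutoff = fold_cutoff, drop_ratio = drop_ratio)
}

.empty_srna_table <- function() {
  df <- .empty_df(replicon_id = character(), strand = character(),
                  start = integer(), end = integer(), origin = character(),
                  tss_position = integer(), ps_position = integer(),
                  end_anchor = character(), fold_score = numeric(),
                  passed_filters = logical())
  df$reject_reasons <- character(0)
  df
}

.srna_row <- function(replicon_id, strand, start, end, origin,
                      tss_position = NA_integer_, ps_position = NA_integer_,
                      end_anchor = "transcript_edge") {
  data.frame(replicon_id = replicon_id, strand = strand,
             start = as.integer(start), end = as.integer(end),
             origin = origin, tss_position = as.integer(tss_position),
             ps_position = as.integer(ps_position), end_anchor = end_anchor,
             fold_score = NA_real_, passed_filters = NA,
             reject_reasons = "", stringsAsFactors = FALSE)
}

# oriented helpers over a genomic window (lo..hi, strand)
.five_edge <- function(lo, hi, strand) if (strand == "+") lo else hi
.three_edge <- function(lo, hi, strand) if (strand == "+") hi else lo
# 5'-most element of a coordinate set, restricted to [lo, hi]
.five_most <- function(pos, lo, hi, strand) {
  pos <- pos[pos >= lo & pos <= hi]
  if (length(pos) == 0L) return(NA_integer_)
  if (strand == "+") min(pos) else max(pos)
}
# strictly downstream of x on the strand
.downstream_of <- function(pos, x, strand) {
  if (strand == "+") pos[pos > x] else pos[pos < x]
}

# per-position maximum coverage over tracks of one replicon/strand
.combined_values <- function(tracks, replicon_id, strand) {
  use <- Filter(function(tr) tr$replicon_id == replicon_id &&
                  tr$strand == strand, tracks)
  if (length(use) == 0L) return(NULL)
  Reduce(pmax, lapply(use, `[[`, "values"))
}

# first drop point within lo..hi (oriented scan), or NA
.region_drop_point <- function(tracks, replicon_id, strand, lo, hi,
                               decrease_ratio) {
  v <- .combined_values(tracks, replicon_id, strand)
  if (is.null(v) || hi > length(v) || lo < 1L || lo > hi) return(NA_integer_)
  vals <- v[lo:hi]
  if (strand == "-") vals <- rev(vals)
  find_drop_point(region_slice(replicon_id, strand, lo, hi, vals),
                  decrease_ratio)
}

.site_positions <- function(sites, replicon_id, strand) {
  if (is.null(sites) || nrow(sites) == 0L) return(integer(0))
  sites$position[sites$replicon_id == replicon_id & sites$strand == strand]
}

#' Detect intergenic and antisense sRNA candidates
#'
#' Transcripts that overlap no gene on their own strand are sRNA
#' candidates: antisense when a gene overlaps on the opposite strand,
#' intergenic otherwise. The candidate must begin at a TSS (within
#' `tss_tolerance` nt of the transcript 5' edge). When the transcript
#' exceeds `max_len`, the 3' end is refined to the first coverage drop
#' point or the first processing site, whichever comes first 5'->3'.
#'
#' @param transcripts Transcript calls.
#' @param genes Feature table of genes/CDS.
#' @param tss,ps TSS and processing-site calls.
#' @param tracks Coverage tracks used for drop-point refinement.
#' @param params [srna_params()].
#' @return sRNA candidate table (filters not yet applied; see
#'   [apply_srna_filters()]).
#' @export
detect_srna_intergenic <- function(transcripts, genes, tss, ps, tracks,
                                   params = srna_params()) {
  genes <- genes[genes$feature_type %in% c("gene", "CDS"), , drop = FALSE]
  out <- list()
  for (t in seq_len(nrow(transcripts))) {
    tr <- transcripts[t, ]
    same <- any(genes$replicon_id == tr$replicon_id &
                  genes$strand == tr$strand &
                  .overlaps(genes$start, genes$end, tr$start, tr$end))
    if (same) next
    opp <- any(genes$replicon_id == tr$replicon_id &
                 genes$strand != tr$strand &
                 .overlaps(genes$start, genes$end, tr$start, tr$end))
    origin <- if (opp) "antisense" else "intergenic"
    edge5 <- .five_edge(tr$start, tr$end, tr$strand)
    tpos <- .site_positions(tss, tr$replicon_id, tr$strand)
    near <- tpos[abs(tpos - edge5) <= params$tss_tolerance]
    tss_pos <- if (length(near)) near[which.min(abs(near - edge5))] else
      NA_integer_
    start5 <- if (is.na(tss_pos)) edge5 else tss_pos
    end3 <- .three_edge(tr$start, tr$end, tr$strand)
    anchor <- "transcript_edge"
    ps_used <- NA_integer_
    if (abs(end3 - start5) + 1L > params$max_len) {
      dp <- .region_drop_point(tracks, tr$replicon_id, tr$strand,
                               tr$start, tr$end, params$drop_ratio)
      pp <- .downstream_of(.site_positions(ps, tr$replicon_id, tr$strand),
                           start5, tr$strand)
      pp <- .five_most(pp, tr$start, tr$end, tr$strand)
      dp <- if (!is.na(dp) && length(.downstream_of(dp, start5, tr$strand)))
        dp else NA_integer_
      pick <- c(drop_point = dp, processing_site = pp)
      pick <- pick[!is.na(pick)]
      if (length(pick)) {
        k <- if (tr$strand == "+") which.min(pick) else which.max(pick)
        end3 <- pick[[k]]
        anchor <- names(pick)[k]
        if (anchor == "processing_site") ps_used <- end3
      }
    }
    lo <- min(start5, end3)
    hi <- max(start5, end3)
    out[[length(out) + 1L]] <- .srna_row(tr$replicon_id, tr$strand, lo, hi,
                                         origin, tss_pos, ps_used, anchor)
  }
  if (length(out) == 0L) return(.empty_srna_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect UTR-derived and interCDS sRNA candidates
#'
#' Within transcripts that also contain genes: a 5'UTR-derived candidate
#' starts at a TSS in the 5'UTR and ends at a processing site or coverage
#' drop point; a 3'UTR-derived candidate starts at a TSS or PS in the
#' 3'UTR and ends at the transcript edge or a PS; an interCDS candidate
#' lies between two CDS of one transcript, starting at a PS and ending at
#' a PS or drop point.
#'
#' @inheritParams detect_srna_intergenic
#' @return sRNA candidate table.
#' @export
detect_srna_utr <- function(transcripts, genes, tss, ps, tracks,
                            params = srna_params()) {
  genes <- genes[genes$feature_type %in% c("gene", "CDS"), , drop = FALSE]
  out <- list()
  emit <- function(row) out[[length(out) + 1L]] <<- row
  for (t in seq_len(nrow(transcripts))) {
    tr <- transcripts[t, ]
    gi <- which(genes$replicon_id == tr$replicon_id &
                  genes$strand == tr$strand &
                  .overlaps(genes$start, genes$end, tr$start, tr$end))
    if (length(gi) == 0L) next
    strand <- tr$strand
    ord <- if (strand == "+") order(genes$start[gi]) else order(-genes$end[gi])
    gi <- gi[ord]
    tpos <- .site_positions(tss, tr$replicon_id, strand)
    ppos <- .site_positions(ps, tr$replicon_id, strand)
    anchor_end <- function(start5, lo, hi) {
      pp <- .five_most(.downstream_of(ppos, start5, strand), lo, hi, strand)
      dp <- .region_drop_point(tracks, tr$replicon_id, strand, lo, hi,
                               params$drop_ratio)
      dp <- if (!is.na(dp) && length(.downstream_of(dp, start5, strand)))
        dp else NA_integer_
      pick <- c(processing_site = pp, drop_point = dp)
      pick <- pick[!is.na(pick)]
      if (length(pick) == 0L) return(NULL)
      k <- if (strand == "+") which.min(pick) else which.max(pick)
      list(pos = pick[[k]], anchor = names(pick)[k])
    }
    # ---- 5'UTR region: transcript 5' edge up to the first gene
    first_g <- gi[1L]
    if (strand == "+") {
      lo <- tr$start; hi <- genes$start[first_g] - 1L
    } else {
      lo <- genes$end[first_g] + 1L; hi <- tr$end
    }
    if (hi >= lo) {
      tss5 <- .five_most(tpos, lo, hi, strand)
      if (!is.na(tss5)) {
        ae <- anchor_end(tss5, lo, hi)
        if (!is.null(ae)) {
          emit(.srna_row(tr$replicon_id, strand, min(tss5, ae$pos),
                         max(tss5, ae$pos), "five_utr", tss5,
                         if (ae$anchor == "processing_site") ae$pos else
                           NA_integer_, ae$anchor))
        }
      }
    }
    # ---- 3'UTR region: last gene to the transcript 3' edge
    last_g <- gi[length(gi)]
    if (strand == "+") {
      lo <- genes$end[last_g] + 1L; hi <- tr$end
    } else {
      lo <- tr$start; hi <- genes$start[last_g] - 1L
    }
    if (hi >= lo) {
      t5 <- .five_most(tpos, lo, hi, strand)
      p5 <- .five_most(ppos, lo, hi, strand)
      starts <- c(TSS = t5, PS = p5)
      starts <- starts[!is.na(starts)]
      if (length(starts)) {
        k <- if (strand == "+") which.min(starts) else which.max(starts)
        s5 <- starts[[k]]
        pnext <- .five_most(.downstream_of(ppos, s5, strand), lo, hi, strand)
        e3 <- if (!is.na(pnext)) pnext else .three_edge(lo, hi, strand)
        emit(.srna_row(tr$replicon_id, strand, min(s5, e3), max(s5, e3),
                       "three_utr",
                       if (names(starts)[k] == "TSS") s5 else NA_integer_,
                       if (names(starts)[k] == "PS") s5 else
                         if (!is.na(pnext)) pnext else NA_integer_,
                       if (!is.na(pnext)) "processing_site" else
                         "transcript_edge"))
      }
    }
    # ---- interCDS regions between consecutive genes of the transcript
    if (length(gi) >= 2L) {
      for (k in seq_len(length(gi) - 1L)) {
        a <- gi[k]; b <- gi[k + 1L]
        if (strand == "+") {
          lo <- genes$end[a] + 1L; hi <- genes$start[b] - 1L
        } else {
          lo <- genes$end[b] + 1L; hi <- genes$start[a] - 1L
        }
        if (hi < lo) next
        p5 <- .five_most(ppos, lo, hi, strand)
        if (is.na(p5)) next
        ae <- anchor_end(p5, lo, hi)
        if (is.null(ae)) next
        emit(.srna_row(tr$replicon_id, strand, min(p5, ae$pos),
                       max(p5, ae$pos), "inter_cds", NA_integer_, p5,
                       ae$anchor))
      }
    }
  }
  if (length(out) == 0L) return(.empty_srna_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Built-in secondary-structure stability score
#'
#' Minus the maximum number of non-crossing Watson-Crick / G-U pairs (with
#' a minimum loop of 3 unpaired nt), divided by the sequence length; lower
#' (more negative) means more stable. A pseudo-energy: any provider
#' satisfying "deterministic, lower = more stable, per-nucleotide scale"
#' can replace it (see [fold_provider_vienna()]).
#'
#' @param sequence DNA or RNA string.
#' @return Score in `[-0.5, 0]`.
#' @export
builtin_fold_score <- function(sequence) {
  sequence <- .normalize_dna(sequence)
  n <- nchar(sequence)
  if (n < 1L) stop("empty sequence", call. = FALSE)
  -.max_noncrossing_pairs(sequence, 3L) / n
}

#' Thermodynamic folding provider backed by the RNAfold command-line tool
#'
#' Returns a scoring function with the same contract as
#' [builtin_fold_score()]: minimum free energy (kcal/mol) per nucleotide.
#' Requires the `RNAfold` executable on the PATH; note its kcal/mol scale
#' needs its own cutoff.
#'
#' @return A function `(sequence) -> score`.
#' @export
fold_provider_vienna <- function() {
  if (Sys.which("RNAfold") == "") {
    stop("RNAfold executable not found on PATH", call. = FALSE)
  }
  function(sequence) {
    rna <- chartr("T", "U", .normalize_dna(sequence))
    out <- system2("RNAfold", c("--noPS"), input = rna, stdout = TRUE)
    m <- regmatches(out[2L], regexpr("\\(\\s*-?[0-9.]+\\)$", out[2L]))
    energy <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
    energy / nchar(sequence)
  }
}

#' Apply sRNA quality filters
#'
#' A candidate passes when its length is within `[min_len, max_len]`, its
#' origin-specific anchor is present (TSS for intergenic/antisense/5'UTR
#' candidates, TSS or PS for 3'UTR, PS for interCDS), and its fold score is
#' at most `fold_cutoff`. Each filter can be deactivated. Candidates
#' overlapping a user-supplied set of known sRNAs bypass the filters.
#' Rejected candidates are retained with their reasons.
#'
#' @param candidates sRNA candidate table.
#' @param genome The [genome()] supplying candidate sequences.
#' @param fold Folding provider function (default [builtin_fold_score()]).
#' @param min_len,max_len Length bounds (nt).
#' @param fold_cutoff Maximum (most positive) accepted score.
#' @param require_length,require_anchor,require_fold Filter switches.
#' @param known Optional feature table of known sRNAs; same-strand overlap
#'   grants sRNA status regardless of filters.
#' @return Candidates with `fold_score`, `passed_filters`, and
#'   `reject_reasons` filled in.
#' @export
apply_srna_filters <- function(candidates, genome, fold = builtin_fold_score,
                               min_len = 30L, max_len = 500L,
                               fold_cutoff = -0.05, require_length = TRUE,
                               require_anchor = TRUE, require_fold = TRUE,
                               known = NULL) {
  if (nrow(candidates) == 0L) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    reasons <- character(0)
    len <- candidates$end[i] - candidates$start[i] + 1L
    if (require_length) {
      if (len < min_len) reasons <- c(reasons, sprintf("length<%d", min_len))
      if (len > max_len) reasons <- c(reasons, sprintf("length>%d", max_len))
    }
    if (require_anchor) {
      origin <- candidates$origin[i]
      has_tss <- !is.na(candidates$tss_position[i])
      has_ps <- !is.na(candidates$ps_position[i])
      bad <- switch(origin,
        intergenic = , antisense = , five_utr = !has_tss,
        three_utr = !(has_tss || has_ps),
        inter_cds = !has_ps,
        FALSE)
      if (bad) reasons <- c(reasons, if (origin == "inter_cds") "no PS" else
        "no TSS")
    }
    if (require_fold) {
      seqs <- .oriented_seq(genome$sequence, candidates$start[i],
                            candidates$end[i], candidates$strand[i])
      score <- fold(seqs)
      candidates$fold_score[i] <- score
      if (score > fold_cutoff) reasons <- c(reasons, "unstable fold")
    }
    if (!is.null(known) && nrow(known) > 0L) {
      hit <- any(known$replicon_id == candidates$replicon_id[i] &
                   known$strand == candidates$strand[i] &
                   .overlaps(known$start, known$end, candidates$start[i],
                             candidates$end[i]))
      if (hit) reasons <- character(0)
    }
    candidates$passed_filters[i] <- length(reasons) == 0L
    candidates$reject_reasons[i] <- paste(reasons, collapse = ",")
  }
  candidates
}

#' Convert sRNA candidates to a feature table
#'
#' @param candidates sRNA candidate table (usually after filtering).
#' @return Feature table with feature_type `sRNA`.
#' @export
srna_features <- function(candidates) {
  if (nrow(candidates) == 0L) return(.empty_feature_table())
  attrs <- lapply(seq_len(nrow(candidates)), function(i) {
    a <- c(ID = sprintf("srna_%04d", i), origin = candidates$origin[i],
           end_anchor = candidates$end_anchor[i])
    if (!is.na(candidates$fold_score[i])) {
      a <- c(a, fold_score = format(candidates$fold_score[i], trim = TRUE))
    }
    if (nzchar(candidates$reject_reasons[i])) {
      a <- c(a, reject_reasons = gsub(",", "|",
                                      candidates$reject_reasons[i]))
    }
    a
  })
  feature_table(candidates$replicon_id, "sRNA", candidates$start,
                candidates$end, candidates$strand, attributes = attrs)
}
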