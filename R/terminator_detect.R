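# Rho-independent terminator detection: a sequence heuristic over
# convergent gene pairs (hairpin + T-rich tract in a short inter-gene
# region) and coverage-drop confirmation of any terminator candidate.

# pairing lookup: codes N=1, A=2, C=3, G=4, T=5; Watson-Crick plus G.T
.PAIR_CODES <- c(N = 1L, A = 2L, C = 3L, G = 4L, T = 5L)
.PAIRED <- local({
  m <- matrix(FALSE, 5L, 5L)
  pair <- function(a, b) {
    m[.PAIR_CODES[[a]], .PAIR_CODES[[b]]] <<- TRUE
    m[.PAIR_CODES[[b]], .PAIR_CODES[[a]]] <<- TRUE
  }
  pair("A", "T"); pair("C", "G"); pair("G", "T")
  m
})

.encode_dna <- function(sequence) {
  codes <- .PAIR_CODES[strsplit(sequence, "", fixed = TRUE)[[1L]]]
  codes[is.na(codes)] <- 1L
  unname(codes)
}

#' Enumerate hairpins in a sequence
#'
#' Exhaustive enumeration over (stem length, loop length, offset) of
#' ungapped stem-loops: positions pair arm-against-arm with Watson-Crick
#' and G-T wobble pairs counted as paired and mismatches as unpaired. A
#' hairpin is accepted when the stem is `stem_min`–`stem_max` nt per arm,
#' the loop `loop_min`–`loop_max` nt, and at most `max_unpaired_frac` of
#' stem positions are unpaired. Only maximal hairpins — those not strictly
#' contained in another accepted hairpin's footprint — are reported.
#'
#' @param sequence DNA string (5'->3').
#' @param stem_min,stem_max Stem (per-arm) length bounds in nt.
#' @param loop_min,loop_max Loop length bounds in nt.
#' @param max_unpaired_frac Maximum unpaired fraction of the stem.
#' @param maximal_only Keep only maximal hairpins; `FALSE` reports every
#'   accepted (stem, loop, offset) combination, which the terminator
#'   search uses so that an A/T-rich super-hairpin cannot shadow a
#'   GC-stem hairpin whose T-tract it absorbed.
#' @return Data frame with columns `stem_start`, `stem_len`, `loop_len`,
#'   `unpaired_in_stem`, `start`, `end`, `sequence_context` (coordinates
#'   1-based within `sequence`).
#' @export
find_hairpins <- function(sequence, stem_min = 4L, stem_max = 20L,
                          loop_min = 3L, loop_max = 10L,
                          max_unpaired_frac = 0.25, maximal_only = TRUE) {
  sequence <- .normalize_dna(sequence)
  n <- nchar(sequence)
  x <- .encode_dna(sequence)
  rows <- list()
  for (s in seq.int(stem_min, stem_max)) {
    for (l in seq.int(loop_min, loop_max)) {
      total <- 2L * s + l
      if (total > n) next
      offs <- seq_len(n - total + 1L)
      unp <- integer(length(offs))
      for (i in seq_len(s)) {
        a <- x[offs + i - 1L]
        b <- x[offs + 2L * s + l - i]
        unp <- unp + !(.PAIRED[cbind(a, b)])
      }
      ok <- which(unp <= max_unpaired_frac * s)
      if (length(ok)) {
        rows[[length(rows) + 1L]] <- data.frame(
          stem_start = offs[ok], stem_len = s, loop_len = l,
          unpaired_in_stem = unp[ok],
          start = offs[ok], end = offs[ok] + total - 1L,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(.empty_df(stem_start = integer(), stem_len = integer(),
                     loop_len = integer(), unpaired_in_stem = integer(),
                     start = integer(), end = integer(),
                     sequence_context = character()))
  }
  hp <- do.call(rbind, rows)
  if (maximal_only) {
    # maximality: drop hairpins strictly inside another accepted footprint
    keep <- vapply(seq_len(nrow(hp)), function(i) {
      !any(hp$start <= hp$start[i] & hp$end >= hp$end[i] &
             (hp$end - hp$start) > (hp$end[i] - hp$start[i]))
    }, logical(1))
    hp <- hp[keep, , drop = FALSE]
  }
  hp$sequence_context <- substring(sequence, hp$start, hp$end)
  hp <- hp[order(hp$start, hp$end), , drop = FALSE]
  rownames(hp) <- NULL
  hp
}

.empty_terminator_table <- function() {
  .empty_df(replicon_id = character(), strand = character(),
            start = integer(), end = integer(), method = character(),
            drop_ratio = numeric(), confirmed = logical())
}

#' Detect terminator candidates between convergent gene pairs
#'
#' Only converging gene pairs (3' ends facing each other) are considered.
#' When the inter-gene region is at most `max_region` nt, contains a
#' qualifying hairpin ([find_hairpins()]) and, downstream of the hairpin in
#' the scanned orientation, a 10 nt window with more than `min_t`
#' thymines, a terminator candidate spanning hairpin plus T-tract is
#' emitted. Both orientations of the region (each gene's own 3' side) are
#' scanned, at most one call per orientation.
#'
#' @param genes Feature table (gene/CDS rows are used), any order.
#' @param genome A [genome()].
#' @param max_region Maximum inter-gene region length (nt).
#' @param min_t Required thymine count in the T-rich window is `> min_t`.
#' @param stem_min,stem_max,loop_min,loop_max,max_unpaired_frac Hairpin
#'   bounds, see [find_hairpins()].
#' @return Data frame of terminator candidates with columns `replicon_id`,
#'   `strand`, `start`, `end`, `method`, `drop_ratio` (NA), `confirmed`
#'   (FALSE until [confirm_by_coverage()]).
#' @export
detect_convergent <- function(genes, genome, max_region = 80L, min_t = 5L,
                              stem_min = 4L, stem_max = 20L, loop_min = 3L,
                              loop_max = 10L, max_unpaired_frac = 0.25) {
  genes <- genes[genes$feature_type %in% c("gene", "CDS") &
                   genes$replicon_id == genome$replicon_id, , drop = FALSE]
  if (nrow(genes) < 2L) return(.empty_terminator_table())
  genes <- genes[order(genes$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genes) - 1L)) {
    if (!(genes$strand[i] == "+" && genes$strand[i + 1L] == "-")) next
    rs <- genes$end[i] + 1L
    re <- genes$start[i + 1L] - 1L
    if (re < rs || re - rs + 1L > max_region) next
    for (orient in c("+", "-")) {
      region_seq <- .oriented_seq(genome$sequence, rs, re, orient)
      hit <- .hairpin_with_t_tract(region_seq, min_t, stem_min, stem_max,
                                   loop_min, loop_max, max_unpaired_frac)
      if (is.null(hit)) next
      if (orient == "+") {
        gstart <- rs + hit$span_start - 1L
        gend <- rs + hit$span_end - 1L
      } else {
        gstart <- re - hit$span_end + 1L
        gend <- re - hit$span_start + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        replicon_id = genome$replicon_id, strand = orient,
        start = gstart, end = gend, method = "convergent_heuristic",
        drop_ratio = NA_real_, confirmed = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(.empty_terminator_table())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# first hairpin (5'-most) followed by a 10 nt window with > min_t thymines;
# returns oriented 1-based span over hairpin plus tract, or NULL
.hairpin_with_t_tract <- function(region_seq, min_t, stem_min, stem_max,
                                  loop_min, loop_max, max_unpaired_frac) {
  hp <- find_hairpins(region_seq, stem_min, stem_max, loop_min, loop_max,
                      max_unpaired_frac, maximal_only = FALSE)
  if (nrow(hp) == 0L) return(NULL)
  is_t <- strsplit(region_seq, "", fixed = TRUE)[[1L]] == "T"
  n <- length(is_t)
  csum <- cumsum(is_t)
  for (h in seq_len(nrow(hp))) {
    from <- hp$end[h] + 1L
    if (from + 9L > n) next
    starts <- seq.int(from, n - 9L)
    counts <- csum[starts + 9L] - c(0, csum)[starts]
    w <- which(counts > min_t)
    if (length(w)) {
      return(list(span_start = hp$start[h],
                  span_end = starts[w[1L]] + 9L))
    }
  }
  NULL
}

#' Confirm terminator candidates by coverage drop
#'
#' For each candidate the min/max coverage ratio ([min_max_ratio()]) is
#' computed over the candidate region extended by `flank` nt on both sides
#' (clipped at replicon ends), per library; the candidate is confirmed when
#' the ratio is at most `drop_cutoff` in at least one library. Candidates
#' are retained either way with the `confirmed` flag and the minimum
#' observed `drop_ratio`.
#'
#' @param candidates Terminator candidates (from [detect_convergent()] or
#'   an external GFF3 list read with [read_gff3()] and converted).
#' @param tracks List of [coverage_track()]s; a candidate is checked
#'   against tracks on its own strand (or both strands for strand `"both"`).
#' @param drop_cutoff Maximum min/max ratio counted as a drop (default
#'   0.5).
#' @param flank Flank (nt) added on both sides (default 30).
#' @return `candidates` with `drop_ratio` and `confirmed` filled in.
#' @export
confirm_by_coverage <- function(candidates, tracks, drop_cutoff = 0.5,
                                flank = 30L) {
  if (drop_cutoff <= 0 || drop_cutoff > 1) {
    stop("drop_cutoff must be in (0, 1]", call. = FALSE)
  }
  if (nrow(candidates) == 0L) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    use <- Filter(function(tr) {
      tr$replicon_id == candidates$replicon_id[i] &&
        (candidates$strand[i] == "both" || tr$strand == candidates$strand[i])
    }, tracks)
    if (length(use) == 0L) {
      candidates$drop_ratio[i] <- NA_real_
      candidates$confirmed[i] <- FALSE
      next
    }
    ratios <- vapply(use, function(tr) {
      lo <- max(1L, candidates$start[i] - flank)
      hi <- min(length(tr$values), candidates$end[i] + flank)
      min_max_ratio(slice_track(tr, lo, hi))
    }, numeric(1))
    candidates$drop_ratio[i] <- min(ratios)
    candidates$confirmed[i] <- any(ratios <= drop_cutoff)
  }
  candidates
}

#' Keep the highest-confidence terminator per gene
#'
#' When several confirmed candidates lie downstream of the same gene within
#' `assoc_distance` nt of its 3' end, only the one with the lowest drop
#' ratio is kept (ties broken toward the gene). Unconfirmed and
#' unassociated candidates pass through unchanged.
#'
#' @param candidates Terminator candidates with confirmation flags.
#' @param genes Feature table of genes/CDS.
#' @param assoc_distance Association distance (nt) downstream of a gene
#'   end.
#' @return Filtered candidate table.
#' @export
dedupe_per_gene <- function(candidates, genes, assoc_distance = 300L) {
  if (nrow(candidates) == 0L) return(candidates)
  genes <- genes[genes$feature_type %in% c("gene", "CDS"), , drop = FALSE]
  if (nrow(genes) == 0L) return(candidates)
  conf <- which(candidates$confirmed)
  assoc_gene <- rep(NA_integer_, nrow(candidates))
  assoc_dist <- rep(NA_real_, nrow(candidates))
  for (i in conf) {
    for (g in seq_len(nrow(genes))) {
      if (genes$replicon_id[g] != candidates$replicon_id[i]) next
      if (!(candidates$strand[i] %in% c(genes$strand[g], "both"))) next
      if (genes$strand[g] == "+") {
        d <- candidates$start[i] - genes$end[g]
      } else {
        d <- genes$start[g] - candidates$end[i]
      }
      if (d >= 0 && d <= assoc_distance &&
          (is.na(assoc_dist[i]) || d < assoc_dist[i])) {
        assoc_gene[i] <- g
        assoc_dist[i] <- d
      }
    }
  }
  drop <- logical(nrow(candidates))
  for (g in unique(assoc_gene[!is.na(assoc_gene)])) {
    members <- which(assoc_gene == g)
    if (length(members) < 2L) next
    ord <- order(candidates$drop_ratio[members], assoc_dist[members])
    drop[members[ord[-1L]]] <- TRUE
  }
  out <- candidates[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert an external candidate GFF3 into the terminator candidate table
#'
#' @param features Feature table (e.g., from [read_gff3()]).
#' @return Candidate table suitable for [confirm_by_coverage()], method
#'   `external_confirmed`.
#' @export
terminator_candidates_from_features <- function(features) {
  if (nrow(features) == 0L) return(.empty_terminator_table())
  data.frame(
    replicon_id = features$replicon_id, strand = features$strand,
    start = features$start, end = features$end,
    method = "external_confirmed", drop_ratio = NA_real_,
    confirmed = FALSE, stringsAsFactors = FALSE
  )
}

#' Convert terminator calls to a feature table
#'
#' @param candidates Terminator candidate table.
#' @return Feature table with feature_type `terminator`.
#' @export
terminator_features <- function(candidates) {
  if (nrow(candidates) == 0L) return(.empty_feature_table())
  attrs <- lapply(seq_len(nrow(candidates)), function(i) {
    c(ID = sprintf("terminator_%04d", i),
      method = candidates$method[i],
      drop_ratio = if (is.na(candidates$drop_ratio[i])) "NA" else
        format(candidates$drop_ratio[i], trim = TRUE),
      confirmed = tolower(as.character(candidates$confirmed[i])))
  })
  feature_table(candidates$replicon_id, "terminator", candidates$start,
                candidates$end, candidates$strand, attributes = attrs)
}
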