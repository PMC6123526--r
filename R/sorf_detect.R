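# Small ORF detection: 30-150 bp ORFs with ribosome-binding-site support
# inside CDS-free transcripts and UTR regions.

#' Default sORF detection parameters
#'
#' Canonical start codon only by default; noncanonical starts (GTG, TTG)
#' can be added. The ORF length range includes start and stop codons. The
#' RBS gap is measured from the RBS 3' edge to the base before the start
#' codon.
#'
#' @param start_codons,stop_codons Codon sets.
#' @param min_len,max_len ORF length bounds (bp, start through stop).
#' @param rbs_consensus Shine-Dalgarno consensus searched upstream.
#' @param rbs_max_mismatch Mismatches tolerated in the RBS match.
#' @param rbs_gap_min,rbs_gap_max Accepted gap (nt) between RBS and start
#'   codon.
#' @return Named list of parameters.
#' @export
sorf_params <- function(start_codons = "ATG",
                        stop_codons = c("TAA", "TAG", "TGA"),
                        min_len = 30L, max_len = 150L,
                        rbs_consensus = "AGGAGG", rbs_max_mismatch = 1L,
                        rbs_gap_min = 3L, rbs_gap_max = 15L) {
  list(start_codons = start_codons, stop_codons = stop_codons,
       min_len = min_len, max_len = max_len, rbs_consensus = rbs_consensus,
       rbs_max_mismatch = rbs_max_mismatch, rbs_gap_min = rbs_gap_min,
       rbs_gap_max = rbs_gap_max)
}

#' Find open reading frames in a sequence
#'
#' Every substring beginning at a start codon and ending at the first
#' in-frame stop codon, with total length (start through stop) within
#' `[min_len, max_len]`. Overlapping ORFs in different frames are all
#' reported.
#'
#' @param region_sequence DNA string in 5'->3' orientation.
#' @param start_codons,stop_codons Codon sets.
#' @param min_len,max_len Length bounds (bp).
#' @return Data frame with `offset` (1-based start position), `length`,
#'   `frame` (`(offset - 1) mod 3`), `start_codon`.
#' @export
find_orfs <- function(region_sequence, start_codons = "ATG",
                      stop_codons = c("TAA", "TAG", "TGA"),
                      min_len = 30L, max_len = 150L) {
  seq <- .normalize_dna(region_sequence)
  n <- nchar(seq)
  empty <- .empty_df(offset = integer(), length = integer(),
                     frame = integer(), start_codon = character())
  if (n < min_len) return(empty)
  codons <- substring(seq, 1:(n - 2L), 3:n)
  start_at <- which(codons %in% start_codons)
  stop_at <- which(codons %in% stop_codons)
  if (length(start_at) == 0L || length(stop_at) == 0L) return(empty)
  rows <- lapply(start_at, function(i) {
    inframe <- stop_at[stop_at > i & (stop_at - i) %% 3L == 0L]
    if (length(inframe) == 0L) return(NULL)
    j <- inframe[1L]
    len <- j - i + 3L
    if (len < min_len || len > max_len) return(NULL)
    data.frame(offset = i, length = len, frame = (i - 1L) %% 3L,
               start_codon = codons[i], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Find ribosome-binding-site matches
#'
#' All offsets where a window of `nchar(consensus)` nt matches the
#' consensus with at most `max_mismatch` mismatches.
#'
#' @param upstream_sequence DNA string (5'->3').
#' @param consensus RBS consensus (default the Shine-Dalgarno `AGGAGG`).
#' @param max_mismatch Tolerated mismatches.
#' @return Integer vector of 1-based match offsets.
#' @export
find_rbs <- function(upstream_sequence, consensus = "AGGAGG",
                     max_mismatch = 1L) {
  seq <- .normalize_dna(upstream_sequence)
  k <- nchar(consensus)
  n <- nchar(seq)
  if (n < k) return(integer(0))
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  offs <- seq_len(n - k + 1L)
  mism <- integer(length(offs))
  for (i in seq_len(k)) mism <- mism + (chars[offs + i - 1L] != cons[i])
  offs[mism <= max_mismatch]
}

#' Detect small ORFs with RBS support
#'
#' The search space is every transcript containing no annotated gene/CDS
#' on its strand plus every UTR region. A candidate is emitted when
#' [find_orfs()] yields an ORF and [find_rbs()] locates an RBS lying
#' between a same-strand upstream TSS and the start codon, with the gap
#' between the RBS 3' edge and the base before the start codon within
#' the configured range.
#'
#' @param transcripts Transcript calls.
#' @param genes Feature table of genes/CDS.
#' @param tss TSS calls.
#' @param utrs UTR table from [derive_utrs()] (may be empty).
#' @param genome The [genome()].
#' @param params [sorf_params()].
#' @return Data frame of sORF candidates: `replicon_id`, `strand`, `start`,
#'   `end` (genome coordinates), `frame`, `start_codon`, `rbs_position`
#'   (genome coordinate of the RBS 5' base in reading orientation),
#'   `tss_position`.
#' @export
detect_sorfs <- function(transcripts, genes, tss, utrs, genome,
                         params = sorf_params()) {
  genes <- genes[genes$feature_type %in% c("gene", "CDS"), , drop = FALSE]
  regions <- list()
  for (t in seq_len(nrow(transcripts))) {
    tr <- transcripts[t, ]
    if (tr$replicon_id != genome$replicon_id) next
    has_cds <- any(genes$replicon_id == tr$replicon_id &
                     genes$strand == tr$strand &
                     .overlaps(genes$start, genes$end, tr$start, tr$end))
    if (!has_cds) {
      regions[[length(regions) + 1L]] <- list(lo = tr$start, hi = tr$end,
                                              strand = tr$strand)
    }
  }
  if (!is.null(utrs) && nrow(utrs) > 0L) {
    for (u in seq_len(nrow(utrs))) {
      if (utrs$replicon_id[u] != genome$replicon_id) next
      regions[[length(regions) + 1L]] <- list(lo = utrs$start[u],
                                              hi = utrs$end[u],
                                              strand = utrs$strand[u])
    }
  }
  out <- list()
  for (rg in regions) {
    seq <- .oriented_seq(genome$sequence, rg$lo, rg$hi, rg$strand)
    orfs <- find_orfs(seq, params$start_codons, params$stop_codons,
                      params$min_len, params$max_len)
    if (nrow(orfs) == 0L) next
    tpos <- .site_positions(tss, genome$replicon_id, rg$strand)
    for (o in seq_len(nrow(orfs))) {
      hit <- .sorf_rbs_support(orfs$offset[o], rg, genome, tpos, params)
      if (is.null(hit)) next
      if (rg$strand == "+") {
        gstart <- rg$lo + orfs$offset[o] - 1L
        gend <- gstart + orfs$length[o] - 1L
      } else {
        gend <- rg$hi - orfs$offset[o] + 1L
        gstart <- gend - orfs$length[o] + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        replicon_id = genome$replicon_id, strand = rg$strand,
        start = gstart, end = gend, frame = orfs$frame[o],
        start_codon = orfs$start_codon[o], rbs_position = hit$rbs_position,
        tss_position = hit$tss_position, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(.empty_df(replicon_id = character(), strand = character(),
                     start = integer(), end = integer(), frame = integer(),
                     start_codon = character(), rbs_position = integer(),
                     tss_position = integer()))
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res[order(res$start, res$strand), , drop = FALSE]
}

# RBS support for an ORF starting at `offset` within an oriented region:
# search the upstream window (in genome sequence, so an RBS just outside a
# UTR region still counts), require gap in [rbs_gap_min, rbs_gap_max] and a
# TSS at or upstream of the RBS. Returns genome coordinates or NULL.
.sorf_rbs_support <- function(offset, rg, genome, tss_positions, params) {
  k <- nchar(params$rbs_consensus)
  win <- params$rbs_gap_max + k  # RBS 3' edge at most rbs_gap_max nt away
  # genome coordinate of the start codon's first base
  gstart5 <- if (rg$strand == "+") rg$lo + offset - 1L else rg$hi - offset + 1L
  if (rg$strand == "+") {
    ulo <- max(1L, gstart5 - win)
    uhi <- gstart5 - 1L
  } else {
    ulo <- gstart5 + 1L
    uhi <- min(genome$length, gstart5 + win)
  }
  if (uhi < ulo) return(NULL)
  useq <- .oriented_seq(genome$sequence, ulo, uhi, rg$strand)
  nup <- nchar(useq)
  hits <- find_rbs(useq, params$rbs_consensus, params$rbs_max_mismatch)
  for (h in hits) {
    # gap = bases strictly between the RBS 3' edge and the start codon
    gap <- nup - (h + k - 1L)
    if (gap < params$rbs_gap_min || gap > params$rbs_gap_max) next
    rbs_g <- if (rg$strand == "+") ulo + h - 1L else uhi - h + 1L
    if (length(tss_positions)) {
      upstream_ok <- if (rg$strand == "+") tss_positions <= rbs_g else
        tss_positions >= rbs_g
      if (!any(upstream_ok)) next
      tsel <- if (rg$strand == "+") max(tss_positions[upstream_ok]) else
        min(tss_positions[upstream_ok])
    } else {
      next  # an sORF requires a TSS upstream of its RBS
    }
    return(list(rbs_position = rbs_g, tss_position = tsel))
  }
  NULL
}

#' Convert sORF candidates to a feature table
#'
#' @param candidates sORF candidate table.
#' @return Feature table with feature_type `sORF`.
#' @export
sorf_features <- function(candidates) {
  if (nrow(candidates) == 0L) return(.empty_feature_table())
  attrs <- lapply(seq_len(nrow(candidates)), function(i) {
    c(ID = sprintf("sorf_%04d", i),
      start_codon = candidates$start_codon[i],
      rbs_position = as.character(candidates$rbs_position[i]),
      frame = as.character(candidates$frame[i]))
  })
  feature_table(candidates$replicon_id, "sORF", candidates$start,
                candidates$end, candidates$strand, attributes = attrs)
}
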