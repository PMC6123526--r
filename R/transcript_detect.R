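# Coverage-based transcript calling: threshold the per-position coverage,
# bridge short sub-cutoff gaps, then merge/extend calls with known gene
# positions so a transcript covers complete genes.

#' Call transcripts from coverage tracks
#'
#' Per replicon and strand, the per-position maximum (or minimum, see
#' `combine`) over the selected tracks is thresholded: maximal runs of
#' positions with coverage strictly above `cutoff` are reported, with
#' internal sub-cutoff gaps of at most `tolerance` nt bridged, and runs
#' shorter than `min_length` discarded.
#'
#' TEX-treated libraries are excluded by default: the exonuclease depletes
#' processed RNA and biases 3' coverage, so fragmented and TEX- libraries
#' give the cleaner transcript signal.
#'
#' @param tracks List of [coverage_track()] objects.
#' @param cutoff Coverage cutoff (normalized coverage units); positions must
#'   exceed it strictly.
#' @param tolerance Maximum gap (nt) of sub-cutoff coverage bridged inside a
#'   call.
#' @param min_length Minimum call length (nt).
#' @param combine `"max"` (a transcript expressed in any library is called)
#'   or `"min"` (replicate-minimum mode: all libraries must support it).
#' @param treatments Library treatments used; `NULL` uses every track.
#' @return Data frame of transcript calls with columns `replicon_id`,
#'   `strand`, `start`, `end`, `max_coverage`, `libs` (comma-separated ids
#'   of supporting libraries).
#' @export
call_transcripts <- function(tracks, cutoff = 5, tolerance = 5L,
                             min_length = 20L,
                             combine = c("max", "min"),
                             treatments = c("fragmented", "TEX_minus")) {
  combine <- match.arg(combine)
  stopifnot(cutoff > 0, tolerance >= 0L, min_length >= 1L)
  if (!is.null(treatments)) {
    tracks <- Filter(function(tr) tr$library$treatment %in% treatments, tracks)
  }
  if (length(tracks) == 0L) stop("no tracks for transcript calling",
                                 call. = FALSE)
  key <- vapply(tracks, function(tr) paste(tr$replicon_id, tr$strand),
                character(1))
  out <- lapply(split(tracks, key), function(grp) {
    vals <- lapply(grp, `[[`, "values")
    v <- Reduce(if (combine == "max") pmax else pmin, vals)
    runs <- .threshold_runs(v, cutoff, tolerance, min_length)
    if (nrow(runs) == 0L) return(NULL)
    libs <- vapply(seq_len(nrow(runs)), function(i) {
      idx <- runs$start[i]:runs$end[i]
      sup <- vapply(grp, function(tr) any(tr$values[idx] > cutoff), logical(1))
      paste(vapply(grp[sup], function(tr) tr$library$library_id, character(1)),
            collapse = ",")
    }, character(1))
    data.frame(
      replicon_id = grp[[1L]]$replicon_id, strand = grp[[1L]]$strand,
      start = runs$start, end = runs$end,
      max_coverage = vapply(seq_len(nrow(runs)), function(i) {
        max(v[runs$start[i]:runs$end[i]])
      }, numeric(1)),
      libs = libs, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- .empty_df(replicon_id = character(), strand = character(),
                     start = integer(), end = integer(),
                     max_coverage = numeric(), libs = character())
  }
  rownames(out) <- NULL
  out[order(out$replicon_id, out$strand, out$start), , drop = FALSE]
}

# maximal above-cutoff runs with gap bridging and a length filter
.threshold_runs <- function(v, cutoff, tolerance, min_length) {
  above <- v > cutoff
  if (!any(above)) return(.empty_df(start = integer(), end = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # bridge internal FALSE runs of length <= tolerance
  if (length(r$values) > 2L) {
    internal <- which(!r$values &
                        seq_along(r$values) > 1L &
                        seq_along(r$values) < length(r$values) &
                        r$lengths <= tolerance)
    for (i in internal) above[starts[i]:ends[i]] <- TRUE
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_length
  data.frame(start = starts[keep], end = ends[keep])
}

#' Merge and extend transcript calls with gene annotations
#'
#' Two calls on the same strand that overlap the same gene are fused into
#' one call spanning both, and a call overlapping part of a gene is
#' extended to cover the full gene. Applied to a fixed point, so the
#' operation is idempotent and only ever grows or fuses calls.
#'
#' @param calls Transcript calls from [call_transcripts()].
#' @param genes Feature table of gene/CDS features.
#' @return Transcript calls, merged and extended.
#' @export
merge_with_genes <- function(calls, genes) {
  if (nrow(calls) == 0L || nrow(genes) == 0L) return(calls)
  genes <- genes[genes$feature_type %in% c("gene", "CDS"), , drop = FALSE]
  if (nrow(genes) == 0L) return(calls)
  repeat {
    changed <- FALSE
    for (g in seq_len(nrow(genes))) {
      hit <- which(calls$replicon_id == genes$replicon_id[g] &
                     calls$strand == genes$strand[g] &
                     .overlaps(calls$start, calls$end,
                               genes$start[g], genes$end[g]))
      if (length(hit) == 0L) next
      new_start <- min(calls$start[hit], genes$start[g])
      new_end <- max(calls$end[hit], genes$end[g])
      first <- hit[1L]
      if (length(hit) > 1L || new_start != calls$start[first] ||
          new_end != calls$end[first]) {
        calls$start[first] <- new_start
        calls$end[first] <- new_end
        calls$max_coverage[first] <- max(calls$max_coverage[hit])
        calls$libs[first] <- paste(
          unique(unlist(strsplit(calls$libs[hit], ","))), collapse = ","
        )
        if (length(hit) > 1L) calls <- calls[-hit[-1L], , drop = FALSE]
        changed <- TRUE
      }
    }
    # extension can create call/call overlaps; fuse them too
    calls <- .fuse_overlapping_calls(calls)
    if (!changed) break
  }
  rownames(calls) <- NULL
  calls[order(calls$replicon_id, calls$strand, calls$start), , drop = FALSE]
}

.fuse_overlapping_calls <- function(calls) {
  if (nrow(calls) < 2L) return(calls)
  calls <- calls[order(calls$replicon_id, calls$strand, calls$start), ,
                 drop = FALSE]
  keep <- rep(TRUE, nrow(calls))
  for (i in 2:nrow(calls)) {
    j <- max(which(keep[1:(i - 1L)]))
    if (calls$replicon_id[i] == calls$replicon_id[j] &&
        calls$strand[i] == calls$strand[j] &&
        calls$start[i] <= calls$end[j] + 1L) {
      calls$end[j] <- max(calls$end[j], calls$end[i])
      calls$max_coverage[j] <- max(calls$max_coverage[j], calls$max_coverage[i])
      calls$libs[j] <- paste(
        unique(unlist(strsplit(c(calls$libs[j], calls$libs[i]), ","))),
        collapse = ","
      )
      keep[i] <- FALSE
    }
  }
  calls[keep, , drop = FALSE]
}

#' Summarize gene coverage by transcript calls
#'
#' A gene counts as covered when any same-strand call overlaps it by at
#' least one nucleotide.
#'
#' @param calls Transcript calls.
#' @param genes Feature table of genes.
#' @return List with `genes_total`, `genes_covered`, and `fraction`.
#' @export
expression_summary <- function(calls, genes) {
  genes <- genes[genes$feature_type %in% c("gene", "CDS"), , drop = FALSE]
  total <- nrow(genes)
  if (total == 0L) return(list(genes_total = 0L, genes_covered = 0L,
                               fraction = 0))
  covered <- vapply(seq_len(total), function(g) {
    any(calls$replicon_id == genes$replicon_id[g] &
          calls$strand == genes$strand[g] &
          .overlaps(calls$start, calls$end, genes$start[g], genes$end[g]))
  }, logical(1))
  list(genes_total = total, genes_covered = sum(covered),
       fraction = sum(covered) / total)
}

#' Convert transcript calls to a feature table
#'
#' @param calls Transcript calls.
#' @return Feature table serializable with [write_gff3()].
#' @export
transcript_features <- function(calls) {
  if (nrow(calls) == 0L) return(.empty_feature_table())
  attrs <- lapply(seq_len(nrow(calls)), function(i) {
    c(ID = sprintf("transcript_%04d", i),
      max_coverage = format(calls$max_coverage[i], trim = TRUE),
      libs = calls$libs[i])
  })
  feature_table(calls$replicon_id, "transcript", calls$start, calls$end,
                calls$strand, attributes = attrs)
}
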