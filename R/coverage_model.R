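# Shared coverage primitives: library-size normalization, strand-oriented
# region slicing, min/max drop ratios and drop-point scanning. These are the
# substrate of the transcript, terminator, and sRNA detectors.

#' Normalize coverage tracks to a common library size
#'
#' Each track is scaled by `mean(totals) / total(track)` where totals are
#' per-track coverage sums over tracks with nonzero totals, so that all
#' libraries end up on the same total-coverage scale. TSS/PS detection
#' compares TEX+ against TEX- coverage and is only meaningful on
#' normalized tracks. All-zero tracks are returned unchanged.
#'
#' @param tracks List of [coverage_track()] objects.
#' @return List of tracks with scaled values; within-track value ratios are
#'   preserved exactly.
#' @export
normalize_tracks <- function(tracks) {
  if (length(tracks) == 0L) stop("no tracks to normalize", call. = FALSE)
  totals <- vapply(tracks, function(tr) sum(tr$values), numeric(1))
  nonzero <- totals > 0
  if (!any(nonzero)) return(tracks)
  target <- mean(totals[nonzero])
  lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    if (!nonzero[i]) return(tr)
    tr$values <- tr$values * (target / totals[i])
    tr
  })
}

#' Construct a region slice
#'
#' A window of a coverage track with values held in the 5'->3' orientation
#' of the strand: on the minus strand `values[1]` is the coverage at genome
#' position `end`.
#'
#' @param replicon_id,strand,start,end Window location (1-based inclusive).
#' @param values Numeric values already oriented 5'->3'.
#' @return An object of class `region_slice`.
#' @export
region_slice <- function(replicon_id, strand, start, end, values) {
  .check_strand(strand)
  if (length(values) != end - start + 1L) {
    stop("region_slice values length must equal end - start + 1", call. = FALSE)
  }
  structure(
    list(replicon_id = replicon_id, strand = strand, start = as.integer(start),
         end = as.integer(end), values = as.numeric(values)),
    class = "region_slice"
  )
}

#' Slice a coverage track
#'
#' @param track A [coverage_track()].
#' @param start,end Window, 1-based inclusive, within the track.
#' @return A [region_slice()] oriented 5'->3' for the track's strand.
#' @export
slice_track <- function(track, start, end) {
  n <- length(track$values)
  if (start < 1L || end > n || start > end) {
    stop("slice out of range: [", start, ", ", end, "] on track of length ",
         n, call. = FALSE)
  }
  v <- track$values[start:end]
  if (track$strand == "-") v <- rev(v)
  region_slice(track$replicon_id, track$strand, start, end, v)
}

#' Ratio of lowest to highest coverage in a region
#'
#' The terminator coverage-drop statistic: `min(values) / max(values)`.
#' Flat-zero regions return 1.0 so an unexpressed terminator candidate can
#' never be spuriously confirmed.
#'
#' @param region A [region_slice()].
#' @return A value in `[0, 1]`.
#' @export
min_max_ratio <- function(region) {
  v <- region$values
  if (length(v) == 0L) stop("empty region", call. = FALSE)
  m <- max(v)
  if (m == 0) return(1)
  min(v) / m
}

#' Find the first rapid coverage drop in a region
#'
#' Scans the region 5'->3' and returns the first position whose coverage
#' falls below `decrease_ratio` times the running maximum seen so far.
#' The running-maximum reference (rather than the global maximum) keeps a
#' late secondary peak from masking an earlier genuine drop.
#'
#' @param region A [region_slice()].
#' @param decrease_ratio Threshold in (0, 1).
#' @return Genome coordinate of the drop position, or `NA` if none.
#' @export
find_drop_point <- function(region, decrease_ratio) {
  if (decrease_ratio <= 0 || decrease_ratio >= 1) {
    stop("decrease_ratio must be in (0, 1)", call. = FALSE)
  }
  v <- region$values
  hit <- which(v < decrease_ratio * cummax(v))
  if (length(hit) == 0L) return(NA_integer_)
  i <- hit[1L]
  if (region$strand == "+") region$start + i - 1L else region$end - i + 1L
}
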