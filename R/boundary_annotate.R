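# Transcript-boundary annotation: 5'/3' UTRs anchored on TSSs, transcript
# edges, and confirmed terminators; operons and sub-operons from
# transcripts plus internal non-genic TSSs.

.empty_utr_table <- function() {
  .empty_df(utr_type = character(), replicon_id = character(),
            strand = character(), start = integer(), end = integer(),
            gene_id = character(), anchor = character(), length = integer())
}

#' Derive 5' and 3' UTRs
#'
#' A 5' UTR runs from a gene's primary (or, failing that, secondary) TSS to
#' the base before the gene start, provided TSS and gene lie in the same
#' transcript call. A 3' UTR runs from the base after the 3'-most gene of a
#' transcript to the confirmed terminator end when one lies within the
#' transcript, otherwise to the transcript 3' edge. No UTR is emitted when
#' the anchors are absent.
#'
#' @param tss Classified TSS calls (see [classify_tss()]).
#' @param transcripts Transcript calls.
#' @param terminators Terminator candidate table (confirmed entries are
#'   used as 3' anchors); may be empty.
#' @param genes Feature table of genes/CDS.
#' @param all_tss Also emit alternative 5' UTRs for secondary TSSs.
#' @return Data frame of UTRs with columns `utr_type` (`five_prime` /
#'   `three_prime`), `replicon_id`, `strand`, `start`, `end`, `gene_id`,
#'   `anchor` (`TSS`, `transcript_edge`, `terminator`), `length`.
#' @export
derive_utrs <- function(tss, transcripts, terminators, genes,
                        all_tss = FALSE) {
  genes <- genes[genes$feature_type %in% c("gene", "CDS"), , drop = FALSE]
  out <- list()
  gid <- ifelse(is.na(genes$feature_id),
                paste0("gene", seq_len(nrow(genes))), genes$feature_id)
  has_classes <- nrow(tss) > 0L && "class_genes" %in% names(tss)
  for (g in seq_len(nrow(genes))) {
    tr <- transcripts[transcripts$replicon_id == genes$replicon_id[g] &
                        transcripts$strand == genes$strand[g] &
                        transcripts$start <= genes$start[g] &
                        transcripts$end >= genes$end[g], , drop = FALSE]
    if (nrow(tr) == 0L) next
    tr <- tr[1L, ]
    plus <- genes$strand[g] == "+"
    # --- 5' UTR: TSS anchored, same transcript, upstream of the gene start
    if (has_classes) {
      assoc <- vapply(seq_len(nrow(tss)), function(i) {
        cg <- tss$class_genes[[i]]
        prim <- gid[g] %in% (cg[["primary"]] %||% character(0))
        seco <- gid[g] %in% (cg[["secondary"]] %||% character(0))
        if (prim) 1L else if (seco) 2L else 0L
      }, integer(1))
      cand <- which(assoc > 0L &
                      tss$position >= tr$start & tss$position <= tr$end)
      if (length(cand)) {
        ord <- order(assoc[cand], -tss$step_height[cand])
        use <- if (all_tss) cand[ord] else cand[ord][1L]
        for (i in use) {
          p <- tss$position[i]
          if (plus && p < genes$start[g]) {
            out[[length(out) + 1L]] <- data.frame(
              utr_type = "five_prime", replicon_id = genes$replicon_id[g],
              strand = "+", start = p, end = genes$start[g] - 1L,
              gene_id = gid[g], anchor = "TSS", stringsAsFactors = FALSE)
          } else if (!plus && p > genes$end[g]) {
            out[[length(out) + 1L]] <- data.frame(
              utr_type = "five_prime", replicon_id = genes$replicon_id[g],
              strand = "-", start = genes$end[g] + 1L, end = p,
              gene_id = gid[g], anchor = "TSS", stringsAsFactors = FALSE)
          }
        }
      }
    }
    # --- 3' UTR: only for the 3'-most gene of the transcript
    others <- genes$replicon_id == genes$replicon_id[g] &
      genes$strand == genes$strand[g] &
      .overlaps(genes$start, genes$end, tr$start, tr$end)
    others[g] <- FALSE
    is_last <- if (plus) !any(genes$end[others] > genes$end[g]) else
      !any(genes$start[others] < genes$start[g])
    if (is_last) {
      term <- terminators
      if (nrow(term) > 0L) {
        term <- term[term$confirmed &
                       term$replicon_id == genes$replicon_id[g] &
                       term$start >= tr$start & term$end <= tr$end, ,
                     drop = FALSE]
      }
      if (plus) {
        term <- if (nrow(term)) term[term$start > genes$end[g], , drop = FALSE] else term
        utr_end <- if (nrow(term)) min(term$end) else tr$end
        if (utr_end > genes$end[g]) {
          out[[length(out) + 1L]] <- data.frame(
            utr_type = "three_prime", replicon_id = genes$replicon_id[g],
            strand = "+", start = genes$end[g] + 1L, end = utr_end,
            gene_id = gid[g],
            anchor = if (nrow(term)) "terminator" else "transcript_edge",
            stringsAsFactors = FALSE)
        }
      } else {
        term <- if (nrow(term)) term[term$end < genes$start[g], , drop = FALSE] else term
        utr_start <- if (nrow(term)) max(term$start) else tr$start
        if (utr_start < genes$start[g]) {
          out[[length(out) + 1L]] <- data.frame(
            utr_type = "three_prime", replicon_id = genes$replicon_id[g],
            strand = "-", start = utr_start, end = genes$start[g] - 1L,
            gene_id = gid[g],
            anchor = if (nrow(term)) "terminator" else "transcript_edge",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) return(.empty_utr_table())
  res <- do.call(rbind, out)
  res$length <- res$end - res$start + 1L
  rownames(res) <- NULL
  res
}

#' Histogram of UTR lengths
#'
#' Fixed-width bins `[0, bw)`, `[bw, 2 bw)`, ...; counts conserve (their
#' sum equals the number of UTRs). Empty bins are omitted.
#'
#' @param utrs UTR table from [derive_utrs()].
#' @param bin_width Bin width in nt.
#' @return Data frame with `bin_start`, `bin_end`, `count`.
#' @export
utr_length_histogram <- function(utrs, bin_width = 100L) {
  if (nrow(utrs) == 0L) {
    return(.empty_df(bin_start = integer(), bin_end = integer(),
                     count = integer()))
  }
  lens <- utrs$end - utrs$start + 1L
  bin <- lens %/% bin_width
  tab <- table(bin)
  data.frame(
    bin_start = as.integer(names(tab)) * bin_width,
    bin_end = (as.integer(names(tab)) + 1L) * bin_width,
    count = as.integer(tab)
  )
}

#' Detect operons and sub-operons
#'
#' Every transcript overlapping at least one same-strand gene yields one
#' operon spanning the transcript, with genes ordered 5'->3'. TSSs inside
#' the operon that do not overlap any gene split it into sub-operons: each
#' sub-operon runs from its TSS to the next such TSS (exclusive) or the
#' operon end. Operons with at most one internal non-genic TSS keep a
#' single sub-operon.
#'
#' @param transcripts Transcript calls.
#' @param genes Feature table of genes/CDS.
#' @param tss Classified TSS calls.
#' @return Data frame of operons with columns `operon_id`, `replicon_id`,
#'   `strand`, `start`, `end`, `n_genes`, `monocistronic`, plus
#'   list-columns `gene_ids` and `suboperons` (data frame of `start`,
#'   `end`, `tss_position` per operon).
#' @export
detect_operons <- function(transcripts, genes, tss) {
  genes <- genes[genes$feature_type %in% c("gene", "CDS"), , drop = FALSE]
  gid <- ifelse(is.na(genes$feature_id),
                paste0("gene", seq_len(nrow(genes))), genes$feature_id)
  rows <- list()
  for (t in seq_len(nrow(transcripts))) {
    tr <- transcripts[t, ]
    gi <- which(genes$replicon_id == tr$replicon_id &
                  genes$strand == tr$strand &
                  .overlaps(genes$start, genes$end, tr$start, tr$end))
    if (length(gi) == 0L) next
    ord <- if (tr$strand == "+") order(genes$start[gi]) else
      order(-genes$end[gi])
    gene_ids <- gid[gi][ord]
    # internal TSSs not overlapping any gene split the operon
    splitters <- integer(0)
    if (nrow(tss) > 0L) {
      cand <- which(tss$replicon_id == tr$replicon_id &
                      tss$strand == tr$strand &
                      tss$position >= tr$start & tss$position <= tr$end)
      nongenic <- vapply(cand, function(i) {
        !any(genes$replicon_id == tr$replicon_id &
               genes$start <= tss$position[i] & genes$end >= tss$position[i] &
               genes$strand == tr$strand)
      }, logical(1))
      splitters <- sort(tss$position[cand[nongenic]])
    }
    sub <- .suboperons(tr$start, tr$end, tr$strand, splitters)
    rows[[length(rows) + 1L]] <- list(
      replicon_id = tr$replicon_id, strand = tr$strand,
      start = tr$start, end = tr$end, gene_ids = gene_ids, suboperons = sub
    )
  }
  if (length(rows) == 0L) {
    res <- .empty_df(operon_id = character(), replicon_id = character(),
                     strand = character(), start = integer(),
                     end = integer(), n_genes = integer(),
                     monocistronic = logical())
    res$gene_ids <- list()
    res$suboperons <- list()
    return(res)
  }
  res <- data.frame(
    operon_id = sprintf("operon_%04d", seq_along(rows)),
    replicon_id = vapply(rows, `[[`, character(1), "replicon_id"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    start = vapply(rows, function(r) as.integer(r$start), integer(1)),
    end = vapply(rows, function(r) as.integer(r$end), integer(1)),
    n_genes = vapply(rows, function(r) length(r$gene_ids), integer(1)),
    stringsAsFactors = FALSE
  )
  res$monocistronic <- res$n_genes == 1L
  res$gene_ids <- lapply(rows, `[[`, "gene_ids")
  res$suboperons <- lapply(rows, `[[`, "suboperons")
  res
}

# split [start, end] at the given (genome-sorted) non-genic TSS positions;
# sub-operons run TSS -> next TSS (exclusive) or the operon end, in the
# strand's 5'->3' direction
.suboperons <- function(start, end, strand, splitters) {
  if (length(splitters) < 2L) {
    return(data.frame(start = start, end = end,
                      tss_position = if (length(splitters)) splitters else
                        NA_integer_))
  }
  if (strand == "+") {
    s <- splitters
    data.frame(start = s, end = c(s[-1L] - 1L, end), tss_position = s)
  } else {
    s <- rev(splitters)  # 5'->3' on minus strand is decreasing coordinates
    data.frame(start = c(s[-1L] + 1L, start), end = s, tss_position = s)
  }
}

#' Operon totals
#'
#' @param operons Operon table from [detect_operons()].
#' @return List with `total`, `monocistronic`, `polycistronic`; the first
#'   always equals the sum of the other two.
#' @export
operon_summary <- function(operons) {
  mono <- sum(operons$monocistronic)
  list(total = nrow(operons), monocistronic = mono,
       polycistronic = nrow(operons) - mono)
}

#' Convert UTRs to a feature table
#'
#' @param utrs UTR table.
#' @return Feature table with feature_type `5UTR` / `3UTR`.
#' @export
utr_features <- function(utrs) {
  if (nrow(utrs) == 0L) return(.empty_feature_table())
  type <- ifelse(utrs$utr_type == "five_prime", "5UTR", "3UTR")
  attrs <- lapply(seq_len(nrow(utrs)), function(i) {
    c(ID = sprintf("utr_%04d", i), gene = utrs$gene_id[i],
      anchor = utrs$anchor[i])
  })
  feature_table(utrs$replicon_id, type, utrs$start, utrs$end, utrs$strand,
                attributes = attrs)
}

#' Convert operons (and their sub-operons) to a feature table
#'
#' Sub-operons are child records linked by `Parent` attributes.
#'
#' @param operons Operon table.
#' @return Feature table with feature_types `operon` and `sub_operon`.
#' @export
operon_features <- function(operons) {
  if (nrow(operons) == 0L) return(.empty_feature_table())
  parent_attrs <- lapply(seq_len(nrow(operons)), function(i) {
    c(ID = operons$operon_id[i],
      genes = paste(operons$gene_ids[[i]], collapse = ","),
      monocistronic = tolower(as.character(operons$monocistronic[i])))
  })
  parents <- feature_table(operons$replicon_id, "operon", operons$start,
                           operons$end, operons$strand,
                           attributes = parent_attrs)
  kids <- lapply(seq_len(nrow(operons)), function(i) {
    sub <- operons$suboperons[[i]]
    attrs <- lapply(seq_len(nrow(sub)), function(k) {
      c(ID = sprintf("%s.sub%d", operons$operon_id[i], k),
        Parent = operons$operon_id[i],
        tss = as.character(sub$tss_position[k]))
    })
    feature_table(operons$replicon_id[i], "sub_operon", sub$start, sub$end,
                  operons$strand[i], attributes = attrs)
  })
  rbind(parents, do.call(rbind, kids))
}
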