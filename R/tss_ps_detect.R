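# TSS and processing-site detection from dRNA-seq TEX+/TEX- library pairs
# under a seven-parameter step/enrichment model, TSS classification relative
# to genes, and evaluation against a curated site set.

#' Construct a TSS/PS calling parameter set
#'
#' The seven parameters of the dRNA-seq site-calling model. A position is
#' called as a TSS when its TEX+ coverage is at least `base_height` and
#' either the plain step condition (`step_height >= height` and
#' `step_factor >= factor`) or the enrichment-relaxed condition
#' (`enrichment >= enrichment_factor` with the height/factor thresholds
#' lowered by their reductions) holds. Processing sites use the mirrored
#' pattern on the TEX- track with `processing_site_factor` as the
#' enrichment threshold.
#'
#' Defaults follow common dRNA-seq practice for normalized coverage.
#'
#' @param height Minimum coverage step at the site.
#' @param height_reduction Height relaxation allowed when the site is
#'   TEX-enriched (must not exceed `height`).
#' @param factor Minimum fold-change between the site and its upstream
#'   neighbor.
#' @param factor_reduction Factor relaxation under enrichment (must not
#'   exceed `factor`).
#' @param enrichment_factor Minimum TEX+/TEX- enrichment for the relaxed
#'   branch.
#' @param processing_site_factor Minimum TEX-/TEX+ enrichment for PS
#'   calling.
#' @param base_height Minimum absolute coverage at the site.
#' @return An object of class `param_set` (named numeric vector of the
#'   seven parameters).
#' @export
param_set <- function(height = 0.3, height_reduction = 0.2, factor = 2.0,
                      factor_reduction = 0.5, enrichment_factor = 2.0,
                      processing_site_factor = 1.5, base_height = 0.0) {
  p <- c(height = height, height_reduction = height_reduction,
         factor = factor, factor_reduction = factor_reduction,
         enrichment_factor = enrichment_factor,
         processing_site_factor = processing_site_factor,
         base_height = base_height)
  if (any(p < 0)) stop("all parameters must be >= 0", call. = FALSE)
  if (p[["height_reduction"]] > p[["height"]]) {
    stop("height_reduction must not exceed height", call. = FALSE)
  }
  if (p[["factor_reduction"]] > p[["factor"]]) {
    stop("factor_reduction must not exceed factor", call. = FALSE)
  }
  structure(p, class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %.4g\n", nm, x[[nm]]))
  invisible(x)
}

#' Step and enrichment statistics at one position
#'
#' `step_height` is the coverage increase over the strand-oriented upstream
#' neighbor on the TEX+ track, `step_factor` the corresponding ratio, and
#' `enrichment` the TEX+/TEX- ratio at the position. Ratios use a
#' pseudo-count to avoid division by zero.
#'
#' @param tex_plus,tex_minus Normalized [coverage_track()]s of one library
#'   pair (same replicon and strand).
#' @param position Genome coordinate; must have an upstream neighbor in the
#'   strand's 5'->3' orientation.
#' @param pseudocount Denominator floor for ratios (default 1).
#' @return List with `step_height`, `step_factor`, `enrichment`.
#' @export
site_statistics <- function(tex_plus, tex_minus, position, pseudocount = 1) {
  L <- length(tex_plus$values)
  strand <- tex_plus$strand
  up <- if (strand == "+") position - 1L else position + 1L
  if (up < 1L || up > L || position < 1L || position > L) {
    stop("position ", position, " has no upstream neighbor on strand ",
         strand, call. = FALSE)
  }
  p <- tex_plus$values[position]
  list(
    step_height = p - tex_plus$values[up],
    step_factor = p / max(tex_plus$values[up], pseudocount),
    enrichment = p / max(tex_minus$values[position], pseudocount)
  )
}

# Per-position statistics vectors for a (primary, other) track pair.
# `primary` is the track on which the step is measured (TEX+ for TSS mode,
# TEX- for PS mode); enrichment = primary / other.
.stats_vectors <- function(primary, other, strand, pseudocount = 1) {
  L <- length(primary)
  up <- if (strand == "+") c(NA_real_, primary[-L]) else c(primary[-1L], NA_real_)
  list(
    p = primary,
    step_height = primary - up,
    step_factor = primary / pmax(up, pseudocount),
    enrichment = primary / pmax(other, pseudocount),
    valid = !is.na(up)
  )
}

# Pair TEX+ and TEX- tracks by (replicon, strand, condition, replicate).
.pair_tracks <- function(tex_plus, tex_minus) {
  key <- function(tr) paste(tr$replicon_id, tr$strand, tr$library$condition,
                            tr$library$replicate)
  mk <- vapply(tex_minus, key, character(1))
  pairs <- lapply(tex_plus, function(tp) {
    i <- match(key(tp), mk)
    if (is.na(i)) {
      stop("no TEX- track matching TEX+ library '", tp$library$library_id,
           "' on ", tp$replicon_id, "(", tp$strand, ")", call. = FALSE)
    }
    list(plus = tp, minus = tex_minus[[i]],
         condition = tp$library$condition)
  })
  if (length(pairs) == 0L) stop("no TEX+/TEX- library pairs", call. = FALSE)
  pairs
}

# Precompute stats per pair so repeated threshold evaluation (the GA inner
# loop) is a handful of vector comparisons.
.prepare_site_stats <- function(tex_plus, tex_minus, mode,
                                pseudocount = 1) {
  pairs <- .pair_tracks(tex_plus, tex_minus)
  lapply(pairs, function(pr) {
    if (mode == "TSS") {
      stats <- .stats_vectors(pr$plus$values, pr$minus$values,
                              pr$plus$strand, pseudocount)
    } else {
      stats <- .stats_vectors(pr$minus$values, pr$plus$values,
                              pr$plus$strand, pseudocount)
    }
    c(stats, list(replicon_id = pr$plus$replicon_id,
                  strand = pr$plus$strand, condition = pr$condition))
  })
}

.call_from_stats <- function(prep, params, mode, cluster_width = 3L) {
  enr_thr <- if (mode == "TSS") params[["enrichment_factor"]] else
    params[["processing_site_factor"]]
  per_pair <- lapply(prep, function(st) {
    plain <- st$step_height >= params[["height"]] &
      st$step_factor >= params[["factor"]]
    relaxed <- st$enrichment >= enr_thr &
      st$step_height >= params[["height"]] - params[["height_reduction"]] &
      st$step_factor >= params[["factor"]] - params[["factor_reduction"]]
    called <- st$valid & st$p >= params[["base_height"]] &
      (plain | relaxed) & st$enrichment >= 1
    pos <- which(called)
    if (length(pos) == 0L) return(NULL)
    data.frame(
      replicon_id = st$replicon_id, strand = st$strand, position = pos,
      step_height = st$step_height[pos], step_factor = st$step_factor[pos],
      enrichment = st$enrichment[pos], condition = st$condition,
      stringsAsFactors = FALSE
    )
  })
  pooled <- do.call(rbind, per_pair)
  if (is.null(pooled) || nrow(pooled) == 0L) {
    return(.empty_site_table(mode))
  }
  out <- lapply(split(pooled, paste(pooled$replicon_id, pooled$strand)),
                .cluster_sites, cluster_width = cluster_width)
  out <- do.call(rbind, out)
  out$site_type <- mode
  out$classes <- NA_character_
  rownames(out) <- NULL
  out <- out[order(out$replicon_id, out$strand, out$position), , drop = FALSE]
  out[, c("replicon_id", "strand", "position", "site_type", "classes",
          "step_height", "step_factor", "enrichment", "condition")]
}

.empty_site_table <- function(mode) {
  .empty_df(replicon_id = character(), strand = character(),
            position = integer(), site_type = character(),
            classes = character(), step_height = numeric(),
            step_factor = numeric(), enrichment = numeric(),
            condition = character())
}

# Merge calls within cluster_width nt; the highest step_height wins, ties
# go to the 5'-most position of the strand.
.cluster_sites <- function(df, cluster_width) {
  df <- df[order(df$position), , drop = FALSE]
  grp <- cumsum(c(1L, diff(df$position) > cluster_width))
  out <- lapply(split(df, grp), function(cl) {
    five_most <- if (cl$strand[1L] == "+") cl$position else -cl$position
    best <- order(-cl$step_height, five_most)[1L]
    rep_row <- cl[best, , drop = FALSE]
    rep_row$condition <- paste(sort(unique(cl$condition)), collapse = ",")
    rep_row
  })
  do.call(rbind, out)
}

#' Call TSSs or processing sites from dRNA-seq library pairs
#'
#' TSS mode looks for a sharp coverage step on the TEX+ track combined with
#' TEX+/TEX- enrichment (primary, 5'-triphosphate transcripts survive the
#' exonuclease). PS mode searches the reverse enrichment pattern: the step
#' is measured on the TEX- track and enrichment is TEX-/TEX+, thresholded
#' by `processing_site_factor`. Calls within `cluster_width` nt are merged
#' keeping the highest step; a site called in any condition is reported
#' with all supporting conditions.
#'
#' @param tex_plus,tex_minus Lists of normalized [coverage_track()]s; pairs
#'   are matched by (replicon, strand, condition, replicate).
#' @param params A [param_set()].
#' @param mode `"TSS"` or `"PS"`.
#' @param cluster_width Cluster merge width in nt.
#' @param pseudocount Ratio denominator floor.
#' @return Data frame of site calls with columns `replicon_id`, `strand`,
#'   `position`, `site_type`, `classes`, `step_height`, `step_factor`,
#'   `enrichment`, `condition`.
#' @export
call_sites <- function(tex_plus, tex_minus, params, mode = c("TSS", "PS"),
                       cluster_width = 3L, pseudocount = 1) {
  mode <- match.arg(mode)
  prep <- .prepare_site_stats(tex_plus, tex_minus, mode, pseudocount)
  .call_from_stats(prep, params, mode, cluster_width)
}

#' Classify TSS calls relative to gene annotations
#'
#' Within `utr_window` nt upstream of a gene start (same strand), the call
#' with the highest step height is that gene's primary TSS (ties resolved
#' toward the gene) and the others are secondary. Calls inside a gene body
#' on the same strand are internal; calls within a gene or `antisense_flank`
#' nt of its boundaries on the opposite strand are antisense; everything
#' else is orphan. One TSS may carry several classes with respect to
#' different genes.
#'
#' @param sites TSS calls from [call_sites()].
#' @param genes Feature table of genes/CDS.
#' @param utr_window Upstream window (nt) for primary/secondary classes.
#' @param antisense_flank Flank (nt) around genes for the antisense class.
#' @return `sites` with `classes` filled (comma-separated) and a
#'   `class_genes` list-column mapping each class to associated gene ids.
#' @export
classify_tss <- function(sites, genes, utr_window = 300L,
                         antisense_flank = 100L) {
  if (nrow(sites) == 0L) {
    sites$class_genes <- list()
    return(sites)
  }
  genes <- genes[genes$feature_type %in% c("gene", "CDS"), , drop = FALSE]
  class_sets <- rep(list(character(0)), nrow(sites))
  class_genes <- rep(list(list()), nrow(sites))
  add <- function(i, cls, gene_id) {
    class_sets[[i]] <<- union(class_sets[[i]], cls)
    prev <- class_genes[[i]][[cls]] %||% character(0)
    class_genes[[i]][[cls]] <<- union(prev, gene_id)
  }
  gid <- ifelse(is.na(genes$feature_id),
                paste0("gene", seq_len(nrow(genes))), genes$feature_id)
  for (g in seq_len(nrow(genes))) {
    same <- sites$replicon_id == genes$replicon_id[g] &
      sites$strand == genes$strand[g]
    opp <- sites$replicon_id == genes$replicon_id[g] &
      sites$strand != genes$strand[g]
    if (genes$strand[g] == "+") {
      win_lo <- genes$start[g] - utr_window
      win_hi <- genes$start[g] - 1L
      gs <- genes$start[g]
    } else {
      win_lo <- genes$end[g] + 1L
      win_hi <- genes$end[g] + utr_window
      gs <- genes$end[g]
    }
    cand <- which(same & sites$position >= win_lo & sites$position <= win_hi)
    if (length(cand) > 0L) {
      ord <- order(-sites$step_height[cand], abs(sites$position[cand] - gs))
      add(cand[ord[1L]], "primary", gid[g])
      for (i in cand[ord[-1L]]) add(i, "secondary", gid[g])
    }
    inside <- which(same & sites$position >= genes$start[g] &
                      sites$position <= genes$end[g])
    for (i in inside) add(i, "internal", gid[g])
    anti <- which(opp & sites$position >= genes$start[g] - antisense_flank &
                    sites$position <= genes$end[g] + antisense_flank)
    for (i in anti) add(i, "antisense", gid[g])
  }
  empty <- lengths(class_sets) == 0L
  class_sets[empty] <- list("orphan")
  sites$classes <- vapply(class_sets, function(cl) {
    paste(intersect(c("primary", "secondary", "internal", "antisense",
                      "orphan"), cl), collapse = ",")
  }, character(1))
  sites$class_genes <- class_genes
  sites
}

#' Construct a curated site set
#'
#' A manually annotated reference set of site positions restricted to one
#' genomic region, the training/evaluation operand of the genetic
#' algorithm.
#'
#' @param positions Data frame with columns `replicon_id`, `strand`,
#'   `position`.
#' @param region_start,region_end Evaluated region (1-based inclusive).
#' @return An object of class `curated_set`.
#' @export
curated_set <- function(positions, region_start, region_end) {
  stopifnot(all(c("replicon_id", "strand", "position") %in% names(positions)))
  if (nrow(positions) == 0L) stop("empty curated set", call. = FALSE)
  if (any(positions$position < region_start | positions$position > region_end)) {
    stop("curated positions must lie within [region_start, region_end]",
         call. = FALSE)
  }
  structure(
    list(positions = positions, region_start = as.integer(region_start),
         region_end = as.integer(region_end)),
    class = "curated_set"
  )
}

#' Evaluation statistics of a call set against a curated set
#'
#' @param TP,FP True/false positive counts.
#' @param TP_m Size of the curated set.
#' @param negatives Number of negative positions (region length minus
#'   `TP_m`).
#' @return Object of class `eval_stats` with `TP`, `FP`, `TPR`, `FPR`,
#'   `TP_m`, `negatives`.
#' @export
eval_stats <- function(TP, FP, TP_m, negatives) {
  stopifnot(TP >= 0, FP >= 0, TP_m > 0, TP <= TP_m, negatives > 0)
  structure(
    list(TP = as.integer(TP), FP = as.integer(FP),
         TPR = TP / TP_m, FPR = FP / negatives,
         TP_m = as.integer(TP_m), negatives = as.integer(negatives)),
    class = "eval_stats"
  )
}

#' @export
print.eval_stats <- function(x, ...) {
  cat(sprintf("<eval_stats> TP %d/%d (TPR %.3f), FP %d (FPR %.3g)\n",
              x$TP, x$TP_m, x$TPR, x$FP, x$FPR))
  invisible(x)
}

#' Evaluate site calls against a curated set
#'
#' Only calls within the curated region count. Each call is matched to its
#' nearest curated position within `match_tolerance` nt (greedy
#' nearest-first; a call matches at most one curated position). `TP` is the
#' number of curated positions matched by at least one call, `FP` the
#' number of calls matching none. The false-positive rate uses the
#' negative-position count: region length minus the curated total.
#'
#' @param sites Site calls.
#' @param curated A [curated_set()].
#' @param match_tolerance Matching tolerance in nt.
#' @return An [eval_stats()] object.
#' @export
evaluate_sites <- function(sites, curated, match_tolerance = 2L) {
  if (!inherits(curated, "curated_set")) stop("curated must be a curated_set",
                                              call. = FALSE)
  cur <- curated$positions
  TP_m <- nrow(cur)
  region_len <- curated$region_end - curated$region_start + 1L
  negatives <- region_len - TP_m
  inside <- sites[sites$position >= curated$region_start &
                    sites$position <= curated$region_end, , drop = FALSE]
  if (nrow(inside) == 0L) return(eval_stats(0L, 0L, TP_m, negatives))
  matched_curated <- logical(TP_m)
  fp <- 0L
  for (i in seq_len(nrow(inside))) {
    ok <- cur$replicon_id == inside$replicon_id[i] &
      cur$strand == inside$strand[i]
    d <- ifelse(ok, abs(cur$position - inside$position[i]), Inf)
    j <- which.min(d)
    if (length(j) == 1L && d[j] <= match_tolerance) {
      matched_curated[j] <- TRUE
    } else {
      fp <- fp + 1L
    }
  }
  eval_stats(sum(matched_curated), fp, TP_m, negatives)
}

#' Convert site calls to a feature table
#'
#' @param sites Site calls (TSS or PS).
#' @return Feature table with feature_type `TSS` or `processing_site`.
#' @export
site_features <- function(sites) {
  if (nrow(sites) == 0L) return(.empty_feature_table())
  type <- ifelse(sites$site_type == "TSS", "TSS", "processing_site")
  attrs <- lapply(seq_len(nrow(sites)), function(i) {
    a <- c(ID = sprintf("%s_%04d", tolower(type[i]), i))
    if (!is.na(sites$classes[i]) && nzchar(sites$classes[i])) {
      a <- c(a, class = sites$classes[i])
    }
    c(a, step_height = format(sites$step_height[i], trim = TRUE),
      enrichment = format(sites$enrichment[i], trim = TRUE),
      condition = sites$condition[i])
  })
  feature_table(sites$replicon_id, type, sites$position, sites$position,
                sites$strand, attributes = attrs)
}
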