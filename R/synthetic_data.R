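# Synthetic dRNA-seq / fragmented RNA-seq data with planted ground truth:
# genome + genes, then planted transcripts, TSSs, processing sites,
# terminators, sRNAs and sORFs, then coverage tracks reproducing the TEX
# enrichment patterns the detectors look for.

#' Simulate a genome with non-overlapping genes
#'
#' Genes are laid out in blocks of two plus-strand then two minus-strand
#' genes, which guarantees convergent pairs (3' ends facing each other)
#' every four genes; each convergent gap is short and carries a planted
#' terminator (perfect hairpin followed by a poly-T tract) written into the
#' sequence. Co-directional gaps alternate between operon-scale and
#' independent spacing; leftover genome length is distributed over
#' divergent gaps and the tail so genes span the replicon.
#'
#' @param length Genome length (nt, >= 1000).
#' @param n_genes Number of genes.
#' @param seed Integer seed; output is deterministic per seed.
#' @param gene_len Gene length range (nt).
#' @param operon_gap Gap (nt) used for co-directional pairs destined to
#'   share a transcript.
#' @param convergent_gap Gap (nt) for convergent pairs (holds the planted
#'   terminator).
#' @param divergent_gap Base gap range (nt) between blocks.
#' @return List with `genome` ([genome()]), `genes` (feature table),
#'   `terminators` (planted terminator coordinates), `conv3` (logical per
#'   gene: 3' end faces a convergent gap), and `seed`.
#' @export
simulate_genome <- function(length, n_genes, seed = 1L,
                            gene_len = c(300L, 500L), operon_gap = 80L,
                            convergent_gap = 60L,
                            divergent_gap = c(220L, 320L)) {
  if (length < 1000L) stop("genome length must be >= 1000", call. = FALSE)
  .with_seed(seed, {
    strands <- rep(c("+", "+", "-", "-"), length.out = n_genes)
    lens <- round(runif(n_genes, gene_len[1L], gene_len[2L]))
    # gap preceding gene i (i >= 2), by boundary type
    gaps <- integer(n_genes)
    gaps[1L] <- 200L
    if (n_genes >= 2L) {
      for (i in 2:n_genes) {
        a <- strands[i - 1L]; b <- strands[i]
        gaps[i] <- if (a == "+" && b == "-") convergent_gap
        else if (a == b) sample(c(operon_gap, 240L), 1L)
        else round(runif(1, divergent_gap[1L], divergent_gap[2L]))
      }
    }
    used <- sum(lens) + sum(gaps)
    if (used + 200L > length) {
      stop("infeasible packing: ", n_genes, " genes need ~", used + 200L,
           " nt but genome is ", length, " nt", call. = FALSE)
    }
    # spread leftover across divergent gaps (keeps operon/terminator gaps
    # at their designed sizes)
    divergent <- which(strands[-n_genes] == "-" & strands[-1L] == "+") + 1L
    leftover <- length - used - 200L
    if (length(divergent) > 0L && leftover > 0L) {
      extra <- leftover %/% (length(divergent) + 1L)
      gaps[divergent] <- gaps[divergent] + extra
    }
    starts <- integer(n_genes)
    pos <- 0L
    for (i in seq_len(n_genes)) {
      pos <- pos + gaps[i]
      starts[i] <- pos + 1L
      pos <- pos + lens[i]
    }
    seq_chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    # plant a terminator (stem 8 + loop 4 + complement arm + 7 T) in each
    # convergent gap, 15 nt downstream of the plus gene's end
    term_rows <- list()
    conv3 <- logical(n_genes)
    for (i in seq_len(max(n_genes - 1L, 0L))) {
      if (!(strands[i] == "+" && strands[i + 1L] == "-")) next
      conv3[i] <- TRUE
      conv3[i + 1L] <- TRUE
      arm <- sample(c("G", "C"), 8L, replace = TRUE)
      comp <- rev(chartr("ACGT", "TGCA", arm))
      loop <- sample(c("A", "T"), 4L, replace = TRUE)
      cassette <- c(arm, loop, comp, rep("T", 7L))
      at <- starts[i] + lens[i] - 1L + 16L  # gene end + 16
      seq_chars[at:(at + base::length(cassette) - 1L)] <- cassette
      term_rows[[base::length(term_rows) + 1L]] <- data.frame(
        replicon_id = "chr", strand = "+", start = at,
        end = at + base::length(cassette) - 1L, stringsAsFactors = FALSE
      )
    }
    gid <- sprintf("g%03d", seq_len(n_genes))
    genes <- feature_table(
      replicon_id = "chr", feature_type = "gene", start = starts,
      end = starts + lens - 1L, strand = strands, source = "simulated",
      attributes = lapply(gid, function(g) c(ID = g))
    )
    terminators <- if (base::length(term_rows)) do.call(rbind, term_rows) else
      .empty_df(replicon_id = character(), strand = character(),
                start = integer(), end = integer())
    list(genome = genome("chr", paste(seq_chars, collapse = "")),
         genes = genes, terminators = terminators, conv3 = conv3,
         seed = seed)
  })
}

#' Plant transcripts, TSSs, processing sites, sRNAs, and sORFs
#'
#' Builds the ground truth on top of [simulate_genome()] output: every gene
#' (or co-directional gene pair at operon spacing) gets a transcript with a
#' 5' UTR ending at a planted TSS and a 3' UTR (kept short next to
#' convergent terminator gaps so the coverage drop stays inside the gap);
#' a fraction of multi-gene transcripts get an internal non-genic TSS
#' (sub-operon promoter) and a fraction of transcripts a processing site.
#' sRNA loci (stable hairpin written into the sequence, own TSS) and sORF
#' cassettes (TSS, Shine-Dalgarno RBS, ATG...stop) are placed in gene
#' deserts.
#'
#' @param sim Output of [simulate_genome()].
#' @param seed Integer seed.
#' @param tss_strength TEX+ enrichment factor range applied at planted
#'   TSSs.
#' @param utr5,utr3 5'/3' UTR length ranges (nt).
#' @param convergent_utr3 Fixed 3' UTR length next to a convergent
#'   terminator gap.
#' @param operon_max_gap Co-directional genes closer than this share a
#'   transcript.
#' @param internal_tss_frac Fraction of multi-gene transcripts receiving an
#'   internal non-genic TSS.
#' @param ps_frac Fraction of gene transcripts receiving a processing
#'   site.
#' @param n_srna,srna_len Number and length range of planted intergenic
#'   sRNAs.
#' @param n_sorf Number of planted sORF cassettes.
#' @return An object of class `truth_table`: list with `genome` (sequence
#'   updated by planting), `genes`, `transcripts`, `tss`, `ps`,
#'   `terminators`, `srnas`, `sorfs`, `seed`.
#' @export
plant_features <- function(sim, seed = 1L, tss_strength = c(5, 8),
                           utr5 = c(20L, 80L), utr3 = c(20L, 60L),
                           convergent_utr3 = 10L, operon_max_gap = 100L,
                           internal_tss_frac = 0.5, ps_frac = 0.3,
                           n_srna = 3L, srna_len = c(60L, 150L),
                           n_sorf = 2L) {
  genes <- sim$genes
  gn <- nrow(genes)
  .with_seed(seed, {
    # ---- group genes into transcripts (operon pairs at operon spacing)
    groups <- list()
    i <- 1L
    while (i <= gn) {
      grp <- i
      while (i < gn && genes$strand[i + 1L] == genes$strand[i] &&
             genes$start[i + 1L] - genes$end[i] - 1L <= operon_max_gap) {
        i <- i + 1L
        grp <- c(grp, i)
      }
      groups[[length(groups) + 1L]] <- grp
      i <- i + 1L
    }
    tx <- list(); tss <- list(); ps <- list()
    add_tss <- function(pos, strand, label) {
      tss[[length(tss) + 1L]] <<- data.frame(
        replicon_id = "chr", strand = strand, position = as.integer(pos),
        strength = runif(1, tss_strength[1L], tss_strength[2L]),
        label = label, stringsAsFactors = FALSE)
    }
    for (grp in groups) {
      strand <- genes$strand[grp[1L]]
      lo_g <- min(genes$start[grp]); hi_g <- max(genes$end[grp])
      u5 <- round(runif(1, utr5[1L], utr5[2L]))
      conv <- any(sim$conv3[grp])
      u3 <- if (conv) convergent_utr3 else round(runif(1, utr3[1L], utr3[2L]))
      if (strand == "+") {
        start <- lo_g - u5; end <- hi_g + u3; tss_pos <- start
      } else {
        start <- lo_g - u3; end <- hi_g + u5; tss_pos <- end
      }
      tx[[length(tx) + 1L]] <- data.frame(
        replicon_id = "chr", strand = strand, start = start, end = end,
        kind = "mRNA", stringsAsFactors = FALSE)
      add_tss(tss_pos, strand, "primary")
      if (length(grp) > 1L && runif(1) < internal_tss_frac) {
        a <- grp[1L]; b <- grp[2L]
        mid <- (genes$end[a] + genes$start[b]) %/% 2L
        add_tss(mid, strand, "internal_operon")
      }
      if (runif(1) < ps_frac) {
        g1 <- grp[1L]
        ps[[length(ps) + 1L]] <- data.frame(
          replicon_id = "chr", strand = strand,
          position = (genes$start[g1] + genes$end[g1]) %/% 2L,
          stringsAsFactors = FALSE)
      }
    }
    tx <- do.call(rbind, tx)
    # ---- free intervals for sRNA / sORF planting
    seq_chars <- strsplit(sim$genome$sequence, "", fixed = TRUE)[[1L]]
    occupied <- rbind(
      data.frame(s = tx$start - 25L, e = tx$end + 25L),
      if (nrow(sim$terminators)) data.frame(s = sim$terminators$start - 40L,
                                            e = sim$terminators$end + 40L)
    )
    occupied <- occupied[order(occupied$s), , drop = FALSE]
    free <- list(); cursor <- 50L
    for (k in seq_len(nrow(occupied))) {
      if (occupied$s[k] - 1L >= cursor + 40L) {
        free[[length(free) + 1L]] <- c(cursor, occupied$s[k] - 1L)
      }
      cursor <- max(cursor, occupied$e[k] + 1L)
    }
    if (cursor + 40L <= sim$genome$length - 50L) {
      free[[length(free) + 1L]] <- c(cursor, sim$genome$length - 50L)
    }
    take_slot <- function(len) {
      widths <- vapply(free, function(f) f[2L] - f[1L] + 1L, numeric(1))
      k <- which.max(widths)
      if (length(k) == 0L || widths[k] < len + 60L) {
        stop("no free interval for a planted element of ", len, " nt",
             call. = FALSE)
      }
      lo <- free[[k]][1L] + 30L
      free[[k]][1L] <<- lo + len + 30L
      c(lo, lo + len - 1L)
    }
    # ---- sRNAs: stable hairpin (stem 15 / loop 5) at the locus start
    srnas <- list()
    for (k in seq_len(n_srna)) {
      len <- round(runif(1, srna_len[1L], srna_len[2L]))
      slot <- take_slot(len)
      strand <- if (k %% 2L == 1L) "+" else "-"
      arm <- sample(c("G", "C", "A", "T"), 15L, replace = TRUE)
      cassette <- c(arm, sample(c("A", "T"), 5L, replace = TRUE),
                    rev(chartr("ACGT", "TGCA", arm)))
      seq_chars[slot[1L]:(slot[1L] + length(cassette) - 1L)] <- cassette
      tss_pos <- if (strand == "+") slot[1L] else slot[2L]
      srnas[[k]] <- data.frame(
        replicon_id = "chr", strand = strand, start = slot[1L],
        end = slot[2L], tss_position = tss_pos, stringsAsFactors = FALSE)
      tx <- rbind(tx, data.frame(replicon_id = "chr", strand = strand,
                                 start = slot[1L], end = slot[2L],
                                 kind = "sRNA", stringsAsFactors = FALSE))
      add_tss(tss_pos, strand, "srna")
    }
    # ---- sORF cassettes: pad(5) RBS(6) gap(6) ATG + 13 codons + TAA pad(10)
    safe_codons <- c("GCT", "GCC", "GAT", "GAA", "TCT", "CTG", "AAA",
                     "CGT", "ACC", "TTC")
    sorfs <- list()
    for (k in seq_len(n_sorf)) {
      body <- paste(sample(safe_codons, 13L, replace = TRUE), collapse = "")
      cassette <- paste0(paste(sample(c("C", "T"), 5L, replace = TRUE),
                               collapse = ""),
                         "AGGAGG",
                         paste(sample(c("C", "T"), 6L, replace = TRUE),
                               collapse = ""),
                         "ATG", body, "TAA",
                         paste(sample(c("C", "T"), 10L, replace = TRUE),
                               collapse = ""))
      len <- nchar(cassette)
      slot <- take_slot(len)
      strand <- if (k %% 2L == 1L) "+" else "-"
      written <- if (strand == "+") cassette else .revcomp(cassette)
      seq_chars[slot[1L]:slot[2L]] <- strsplit(written, "", fixed = TRUE)[[1L]]
      # oriented offsets within the cassette: ORF starts at 18, length 45
      if (strand == "+") {
        orf_start <- slot[1L] + 17L; orf_end <- orf_start + 44L
        rbs_pos <- slot[1L] + 5L; tss_pos <- slot[1L]
      } else {
        orf_end <- slot[2L] - 17L; orf_start <- orf_end - 44L
        rbs_pos <- slot[2L] - 5L; tss_pos <- slot[2L]
      }
      sorfs[[k]] <- data.frame(
        replicon_id = "chr", strand = strand, start = min(orf_start, orf_end),
        end = max(orf_start, orf_end), rbs_position = rbs_pos,
        tss_position = tss_pos, stringsAsFactors = FALSE)
      tx <- rbind(tx, data.frame(replicon_id = "chr", strand = strand,
                                 start = slot[1L], end = slot[2L],
                                 kind = "sORF", stringsAsFactors = FALSE))
      add_tss(tss_pos, strand, "sorf")
    }
    empty_pos <- .empty_df(replicon_id = character(), strand = character(),
                           position = integer())
    structure(list(
      genome = genome("chr", paste(seq_chars, collapse = "")),
      genes = genes,
      transcripts = tx,
      tss = do.call(rbind, tss),
      ps = if (length(ps)) do.call(rbind, ps) else empty_pos,
      terminators = sim$terminators,
      srnas = if (length(srnas)) do.call(rbind, srnas) else NULL,
      sorfs = if (length(sorfs)) do.call(rbind, sorfs) else NULL,
      seed = seed
    ), class = "truth_table")
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf(paste0("<truth_table> %d nt, %d genes, %d transcripts, ",
                     "%d TSS, %d PS, %d terminators, %d sRNA, %d sORF\n"),
              x$genome$length, nrow(x$genes), nrow(x$transcripts),
              nrow(x$tss), nrow(x$ps), nrow(x$terminators),
              if (is.null(x$srnas)) 0L else nrow(x$srnas),
              if (is.null(x$sorfs)) 0L else nrow(x$sorfs)))
  invisible(x)
}

#' A default dRNA-seq + fragmented library set
#'
#' @param conditions Number of conditions.
#' @param replicates Replicates per condition.
#' @return List of [seq_library()] objects: TEX+, TEX-, and fragmented per
#'   condition/replicate.
#' @export
default_libraries <- function(conditions = 1L, replicates = 1L) {
  libs <- list()
  for (cond in paste0("cond", seq_len(conditions))) {
    for (rep in seq_len(replicates)) {
      for (tt in c("TEX_plus", "TEX_minus", "fragmented")) {
        libs[[length(libs) + 1L]] <- seq_library(
          paste(tt, cond, paste0("rep", rep), sep = "_"), tt, cond, rep)
      }
    }
  }
  libs
}

#' Simulate coverage tracks from planted truth
#'
#' Every planted transcript produces a plateau of `depth` on its strand.
#' TEX+ tracks run at `tex_ratio` of the plateau (the exonuclease depletes
#' processed RNA), step up by each TSS's planted strength over a
#' `spike_width` window, and drop to `ps_depletion` downstream of each
#' processing site; TEX- tracks are enriched by `ps_spike` downstream of
#' each PS. Fragmented tracks are plain plateaus; coverage falls to zero
#' across the planted terminator gaps. Gaussian noise (sd `noise_sd`,
#' floored at 0) is added last. Deterministic per seed.
#'
#' @param truth A `truth_table` from [plant_features()].
#' @param libraries List of [seq_library()] (e.g. [default_libraries()]).
#' @param depth Plateau coverage.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @param tex_ratio TEX+ within-transcript baseline as a fraction of the
#'   plateau.
#' @param ps_spike TEX- enrichment factor downstream of a PS.
#' @param ps_depletion TEX+ depletion factor downstream of a PS.
#' @param spike_width Width (nt) of TSS/PS signal windows.
#' @return List of [coverage_track()] objects, two strands per library.
#' @export
simulate_coverage <- function(truth, libraries = default_libraries(),
                              depth = 50, noise_sd = 0, seed = 1L,
                              tex_ratio = 0.8, ps_spike = 8,
                              ps_depletion = 0.2, spike_width = 30L) {
  stopifnot(inherits(truth, "truth_table"))
  L <- truth$genome$length
  win <- function(pos, strand) {
    if (strand == "+") pos:min(pos + spike_width - 1L, L)
    else max(pos - spike_width + 1L, 1L):pos
  }
  .with_seed(seed, {
    tracks <- list()
    for (lib in libraries) {
      for (strand in c("+", "-")) {
        base <- numeric(L)
        tx <- truth$transcripts[truth$transcripts$strand == strand, ,
                                drop = FALSE]
        for (t in seq_len(nrow(tx))) base[tx$start[t]:tx$end[t]] <- depth
        v <- switch(lib$treatment,
          fragmented = base,
          TEX_minus = {
            w <- base
            pss <- truth$ps[truth$ps$strand == strand, , drop = FALSE]
            for (q in pss$position) {
              idx <- win(q, strand)
              w[idx] <- w[idx] * ps_spike
            }
            w
          },
          TEX_plus = {
            w <- base * tex_ratio
            tsss <- truth$tss[truth$tss$strand == strand, , drop = FALSE]
            for (t in seq_len(nrow(tsss))) {
              idx <- win(tsss$position[t], strand)
              w[idx] <- w[idx] * tsss$strength[t]
            }
            pss <- truth$ps[truth$ps$strand == strand, , drop = FALSE]
            for (q in pss$position) {
              idx <- win(q, strand)
              w[idx] <- w[idx] * ps_depletion
            }
            w
          })
        if (noise_sd > 0) v <- pmax(v + rnorm(L, 0, noise_sd), 0)
        tracks[[length(tracks) + 1L]] <- coverage_track("chr", strand, lib, v)
      }
    }
    tracks
  })
}

#' Restrict planted TSSs to a region as a curated set
#'
#' Emulates a manually curated training set: the planted TSSs falling in
#' the region, packaged for [optimize_params()] / [evaluate_sites()].
#'
#' @param truth A `truth_table`.
#' @param region Length-2 vector `(start, end)`.
#' @return A [curated_set()].
#' @export
curate_subset <- function(truth, region) {
  stopifnot(inherits(truth, "truth_table"), length(region) == 2L)
  if (region[1L] < 1L || region[2L] > truth$genome$length ||
      region[1L] > region[2L]) {
    stop("region must lie within the genome", call. = FALSE)
  }
  pos <- truth$tss[truth$tss$position >= region[1L] &
                     truth$tss$position <= region[2L], , drop = FALSE]
  if (nrow(pos) == 0L) {
    stop("no planted TSSs in the requested region", call. = FALSE)
  }
  curated_set(pos[, c("replicon_id", "strand", "position")],
              region[1L], region[2L])
}

#' Write a simulation to standard files
#'
#' Emits FASTA, the gene annotation as GFF3, one wiggle per library and
#' strand, a library configuration table, and the truth tables as TSV.
#'
#' @param truth A `truth_table`.
#' @param tracks Tracks from [simulate_coverage()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(truth, tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth$genome, file.path(dir, "genome.fa"))
  write_gff3(truth$genes, file.path(dir, "annotation.gff3"))
  lib_rows <- list()
  for (tr in tracks) {
    fn <- sprintf("%s_%s.wig", tr$library$library_id,
                  ifelse(tr$strand == "+", "fwd", "rev"))
    write_wiggle(tr, file.path(dir, fn))
    lib_rows[[length(lib_rows) + 1L]] <- data.frame(
      path = fn, treatment = tr$library$treatment,
      condition = tr$library$condition, replicate = tr$library$replicate,
      strand = tr$strand, stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, lib_rows), file.path(dir, "libraries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in c("transcripts", "tss", "ps", "terminators", "srnas", "sorfs")) {
    obj <- truth[[nm]]
    if (!is.null(obj) && nrow(obj) > 0L) {
      write.table(obj, file.path(dir, paste0("truth_", nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
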