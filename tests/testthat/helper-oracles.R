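# Independent brute-force oracles. Each one re-derives the operation from
# the definition with a deliberately naive algorithm, sharing no code with
# the package implementation.

# transcript calling: explicit position-wise scan, then gap bridging by
# repeated merging of adjacent runs
oracle_transcripts <- function(values, cutoff, tolerance, min_length) {
  above <- values > cutoff
  runs <- list()
  i <- 1L
  n <- length(values)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  repeat {
    merged <- FALSE
    k <- 1L
    while (k < length(runs)) {
      gap <- runs[[k + 1L]][1L] - runs[[k]][2L] - 1L
      if (gap <= tolerance) {
        runs[[k]] <- c(runs[[k]][1L], runs[[k + 1L]][2L])
        runs[[k + 1L]] <- NULL
        merged <- TRUE
      } else k <- k + 1L
    }
    if (!merged) break
  }
  keep <- Filter(function(r) r[2L] - r[1L] + 1L >= min_length, runs)
  if (length(keep) == 0L) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = vapply(keep, `[`, integer(1), 1L),
             end = vapply(keep, `[`, integer(1), 2L))
}

# drop point: explicit loop with a running maximum
oracle_drop_point <- function(values, ratio) {
  runmax <- -Inf
  for (i in seq_along(values)) {
    runmax <- max(runmax, values[i])
    if (values[i] < ratio * runmax) return(i)
  }
  NA_integer_
}

oracle_pairable <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
}

# hairpins: naive triple loop over offset/stem/loop with per-position
# character comparison, then the same maximality rule (not strictly
# contained in a larger accepted footprint)
oracle_hairpins <- function(sequence, stem_min = 4L, stem_max = 20L,
                            loop_min = 3L, loop_max = 10L,
                            max_unpaired_frac = 0.25) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(chars)
  acc <- list()
  for (o in seq_len(n)) {
    for (s in stem_min:stem_max) {
      for (l in loop_min:loop_max) {
        e <- o + 2L * s + l - 1L
        if (e > n) next
        unp <- 0L
        for (i in seq_len(s)) {
          if (!oracle_pairable(chars[o + i - 1L], chars[o + 2L * s + l - i]))
            unp <- unp + 1L
        }
        if (unp <= max_unpaired_frac * s) {
          acc[[length(acc) + 1L]] <- c(o, s, l, unp, e)
        }
      }
    }
  }
  if (length(acc) == 0L) {
    return(data.frame(stem_start = integer(), stem_len = integer(),
                      loop_len = integer(), unpaired_in_stem = integer(),
                      start = integer(), end = integer()))
  }
  m <- do.call(rbind, acc)
  df <- data.frame(stem_start = m[, 1L], stem_len = m[, 2L],
                   loop_len = m[, 3L], unpaired_in_stem = m[, 4L],
                   start = m[, 1L], end = m[, 5L])
  span <- df$end - df$start
  keep <- vapply(seq_len(nrow(df)), function(i) {
    !any(df$start <= df$start[i] & df$end >= df$end[i] & span > span[i])
  }, logical(1))
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# ORFs: per-frame walk over codons
oracle_orfs <- function(sequence, start_codons = "ATG",
                        stop_codons = c("TAA", "TAG", "TGA"),
                        min_len = 30L, max_len = 150L) {
  chars <- toupper(sequence)
  n <- nchar(chars)
  out <- list()
  for (i in seq_len(max(n - 2L, 0L))) {
    if (!substr(chars, i, i + 2L) %in% start_codons) next
    j <- i + 3L
    while (j + 2L <= n) {
      if (substr(chars, j, j + 2L) %in% stop_codons) {
        len <- j + 2L - i + 1L
        if (len >= min_len && len <= max_len) {
          out[[length(out) + 1L]] <- c(i, len, (i - 1L) %% 3L)
        }
        break
      }
      j <- j + 3L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(offset = integer(), length = integer(),
                      frame = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(offset = m[, 1L], length = m[, 2L], frame = m[, 3L])
}

# RBS: per-window character comparison
oracle_rbs <- function(sequence, consensus = "AGGAGG", max_mismatch = 1L) {
  seqc <- strsplit(toupper(sequence), "")[[1L]]
  consc <- strsplit(toupper(consensus), "")[[1L]]
  k <- length(consc)
  hits <- integer(0)
  for (o in seq_len(max(length(seqc) - k + 1L, 0L))) {
    mm <- sum(seqc[o:(o + k - 1L)] != consc)
    if (mm <= max_mismatch) hits <- c(hits, o)
  }
  hits
}

# maximum non-crossing pairing: exhaustive recursion over the first
# position (pair it with every compatible partner or leave it unpaired)
oracle_max_pairs <- function(sequence, min_loop = 3L) {
  chars <- strsplit(chartr("U", "T", toupper(sequence)), "")[[1L]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (oracle_pairable(chars[i], chars[k])) {
        cand <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
        if (cand > best) best <- cand
      }
    }
    best
  }
  rec(1L, length(chars))
}

# per-position TSS/PS threshold evaluation straight from the rule text
oracle_site_positions <- function(plus, minus, strand, params, mode,
                                  eps = 1) {
  n <- length(plus)
  if (mode == "PS") {
    tmp <- plus; plus <- minus; minus <- tmp
    enr_thr <- params[["processing_site_factor"]]
  } else {
    enr_thr <- params[["enrichment_factor"]]
  }
  hits <- integer(0)
  for (pos in seq_len(n)) {
    up <- if (strand == "+") pos - 1L else pos + 1L
    if (up < 1L || up > n) next
    sh <- plus[pos] - plus[up]
    sf <- plus[pos] / max(plus[up], eps)
    enr <- plus[pos] / max(minus[pos], eps)
    plain <- sh >= params[["height"]] && sf >= params[["factor"]]
    relaxed <- enr >= enr_thr &&
      sh >= params[["height"]] - params[["height_reduction"]] &&
      sf >= params[["factor"]] - params[["factor_reduction"]]
    if (plus[pos] >= params[["base_height"]] && (plain || relaxed) &&
        enr >= 1) {
      hits <- c(hits, pos)
    }
  }
  hits
}

# the six replacement conditions written out directly from counts
oracle_decision <- function(tp_c, fp_c, tp_b, fp_b, tp_m, negatives) {
  tpr_c <- tp_c / tp_m; tpr_b <- tp_b / tp_m
  fpr_c <- fp_c / negatives; fpr_b <- fp_b / negatives
  (tpr_c - tpr_b >= 0.1) ||
    (tpr_c > tpr_b && fpr_c < fpr_b) ||
    (tp_b - tp_c > 0 && fp_b - fp_c >= 5 * (tp_b - tp_c)) ||
    (tp_b - tp_c < 0 && fp_c - fp_b <= 5 * (tp_c - tp_b)) ||
    (tp_m >= 100 && tpr_c - tpr_b >= 0.01 && fpr_c - fpr_b <= 5e-5) ||
    (tp_m >= 100 && tpr_b - tpr_c <= 0.01 && fpr_b - fpr_c >= 5e-5)
}
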