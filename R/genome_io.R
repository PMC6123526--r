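# Standard-format I/O: FASTA genomes, GFF3 feature tables, and wiggle
# coverage tracks, all mapped onto the package's internal data model with
# 1-based inclusive coordinates throughout.

#' Construct a genome record
#'
#' A genome is one replicon: an identifier plus its DNA sequence. Sequences
#' are normalized on construction (uppercased, U converted to T); only the
#' alphabet A, C, G, T, N is accepted.
#'
#' @param replicon_id Non-empty replicon name.
#' @param sequence DNA (or RNA) sequence string.
#' @return An object of class `genome` with fields `replicon_id`,
#'   `sequence`, and `length` (nt).
#' @export
genome <- function(replicon_id, sequence) {
  if (!is.character(replicon_id) || length(replicon_id) != 1L ||
      !nzchar(replicon_id)) {
    stop("replicon_id must be a non-empty string", call. = FALSE)
  }
  seq <- .normalize_dna(sequence)
  if (!nzchar(seq)) stop("empty sequence for '", replicon_id, "'", call. = FALSE)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence for '", replicon_id, "' contains non-ACGTN characters",
         call. = FALSE)
  }
  structure(
    list(replicon_id = replicon_id, sequence = seq, length = nchar(seq)),
    class = "genome"
  )
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d nt\n", x$replicon_id, x$length))
  invisible(x)
}

#' Read a FASTA file into genome records
#'
#' One `genome` per FASTA record; the first whitespace-delimited token of
#' each header is used as the replicon id. Sequences are uppercased and U
#' is converted to T.
#'
#' @param path Path to a FASTA file.
#' @return List of [genome()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(recs) == 0L) stop("no records in FASTA '", path, "'", call. = FALSE)
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(ids))) {
    stop("malformed header (empty id) in FASTA '", path, "'", call. = FALSE)
  }
  widths <- Biostrings::width(recs)
  if (any(widths == 0L)) {
    stop("empty sequence for record '", ids[widths == 0L][1L], "' in '",
         path, "'", call. = FALSE)
  }
  lapply(seq_along(recs), function(i) genome(ids[i], as.character(recs[[i]])))
}

#' Write genome records to a FASTA file
#'
#' @param genomes List of [genome()] objects.
#' @param path Output path.
#' @param width Line width for the sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "sequence"))
  names(set) <- vapply(genomes, `[[`, character(1), "replicon_id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a feature table
#'
#' The in-memory representation of GFF3 records: one row per feature with
#' 1-based inclusive coordinates and an `attributes` list-column of named
#' character vectors. `feature_id` mirrors the ID attribute (NA if absent).
#'
#' @param replicon_id,feature_type,start,end,strand Per-feature vectors.
#' @param source GFF3 source column.
#' @param score Numeric score or NA.
#' @param attributes List of named character vectors, one per feature.
#' @return A `data.frame` with columns `replicon_id`, `source`,
#'   `feature_type`, `start`, `end`, `score`, `strand`, `feature_id`,
#'   `attributes`.
#' @export
feature_table <- function(replicon_id, feature_type, start, end, strand,
                          source = "rnannotate", score = NA_real_,
                          attributes = NULL) {
  n <- length(start)
  if (n == 0L) {
    return(.empty_feature_table())
  }
  .check_strand(strand)
  if (any(start < 1L) || any(end < start)) {
    stop("features require 1 <= start <= end", call. = FALSE)
  }
  if (is.null(attributes)) attributes <- rep(list(character(0)), n)
  ids <- vapply(attributes, function(a) {
    if ("ID" %in% names(a)) unname(a[["ID"]]) else NA_character_
  }, character(1))
  df <- data.frame(
    replicon_id = rep_len(as.character(replicon_id), n),
    source = rep_len(as.character(source), n),
    feature_type = rep_len(as.character(feature_type), n),
    start = as.integer(start),
    end = as.integer(end),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    feature_id = ids,
    stringsAsFactors = FALSE
  )
  df$attributes <- attributes
  df
}

.empty_feature_table <- function() {
  df <- .empty_df(
    replicon_id = character(), source = character(),
    feature_type = character(), start = integer(), end = integer(),
    score = numeric(), strand = character(), feature_id = character()
  )
  df$attributes <- list()
  df
}

#' Read a GFF3 file
#'
#' Strict nine-column parser: coordinates are kept 1-based inclusive,
#' attributes are split into named vectors, and the result is sorted by
#' (replicon, start). Malformed lines (wrong column count, start > end,
#' unknown strand symbol) raise a format error naming the line.
#'
#' @param path Path to a GFF3 file.
#' @return A feature table (see [feature_table()]).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) return(.empty_feature_table())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) == 9L
  if (any(!ncol_ok)) {
    bad <- keep[which(!ncol_ok)[1L]]
    stop("GFF3 format error at line ", bad, " of '", path,
         "': expected 9 tab-separated columns", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- keep[which(is.na(start) | is.na(end))[1L]]
    stop("GFF3 format error at line ", bad, ": non-numeric coordinates",
         call. = FALSE)
  }
  if (any(start > end) || any(start < 1L)) {
    bad <- keep[which(start > end | start < 1L)[1L]]
    stop("GFF3 format error at line ", bad, ": requires 1 <= start <= end",
         call. = FALSE)
  }
  strand <- m[, 7L]
  if (!all(strand %in% c("+", "-"))) {
    bad <- keep[which(!strand %in% c("+", "-"))[1L]]
    stop("GFF3 format error at line ", bad, ": unknown strand symbol '",
         strand[!strand %in% c("+", "-")][1L], "'", call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(ifelse(m[, 6L] == ".", NA, m[, 6L])))
  attributes <- lapply(m[, 9L], .parse_gff_attributes)
  df <- feature_table(
    replicon_id = m[, 1L], feature_type = m[, 3L], start = start, end = end,
    strand = strand, source = m[, 2L], score = score, attributes = attributes
  )
  ids <- df$feature_id[!is.na(df$feature_id)]
  if (anyDuplicated(ids)) {
    stop("GFF3 format error in '", path, "': duplicate ID '",
         ids[duplicated(ids)][1L], "'", call. = FALSE)
  }
  df[order(df$replicon_id, df$start), , drop = FALSE]
}

.parse_gff_attributes <- function(text) {
  if (is.na(text) || text == "." || !nzchar(text)) return(character(0))
  parts <- strsplit(text, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(parts)]
  keys <- sub("=.*$", "", parts)
  vals <- sub("^[^=]*=", "", parts)
  names(vals) <- keys
  vals
}

.format_gff_attributes <- function(attrs) {
  if (length(attrs) == 0L) return(".")
  paste(paste0(names(attrs), "=", unname(attrs)), collapse = ";")
}

#' Write a feature table to GFF3
#'
#' Round-trip stable with [read_gff3()]: every field the model stores is
#' reproduced. An empty table yields a header-only file.
#'
#' @param features A feature table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  header <- "##gff-version 3"
  if (nrow(features) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  score <- ifelse(is.na(features$score), ".",
                  format(features$score, trim = TRUE, scientific = FALSE))
  attrs <- vapply(features$attributes, .format_gff_attributes, character(1))
  lines <- paste(
    features$replicon_id, features$source, features$feature_type,
    features$start, features$end, score, features$strand, ".", attrs,
    sep = "\t"
  )
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Describe an RNA-seq library
#'
#' @param library_id Unique library name.
#' @param treatment One of `"TEX_plus"` (terminator-exonuclease treated
#'   dRNA-seq aliquot), `"TEX_minus"` (untreated aliquot), or
#'   `"fragmented"` (conventional RNA-seq after fragmentation).
#' @param condition Free-text condition label.
#' @param replicate Positive replicate index.
#' @return An object of class `seq_library`.
#' @export
seq_library <- function(library_id, treatment, condition = "cond1",
                        replicate = 1L) {
  treatment <- match.arg(treatment, c("TEX_plus", "TEX_minus", "fragmented"))
  stopifnot(is.character(library_id), nzchar(library_id), replicate >= 1L)
  structure(
    list(library_id = library_id, treatment = treatment,
         condition = condition, replicate = as.integer(replicate)),
    class = "seq_library"
  )
}

#' Construct a coverage track
#'
#' Per-replicon, per-strand, per-library nucleotide coverage: `values[i]`
#' is the coverage at genome position `i` regardless of strand.
#'
#' @param replicon_id Replicon name.
#' @param strand `"+"` or `"-"`.
#' @param library A [seq_library()].
#' @param values Non-negative numeric vector, one entry per nucleotide.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(replicon_id, strand, library, values) {
  .check_strand(strand)
  if (any(values < 0)) stop("coverage values must be >= 0", call. = FALSE)
  structure(
    list(replicon_id = replicon_id, strand = strand, library = library,
         values = as.numeric(values)),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s(%s) %s: %d nt, total %.1f\n",
              x$replicon_id, x$strand, x$library$library_id,
              length(x$values), sum(x$values)))
  invisible(x)
}

#' Read a wiggle coverage file
#'
#' Supports `variableStep` and `fixedStep` declarations with `span=1`.
#' Positions are 1-based; unlisted positions get coverage 0. One track is
#' returned per `chrom` encountered.
#'
#' @param path Path to a wiggle file.
#' @param library The [seq_library()] the file belongs to.
#' @param strand Strand of the file (`"+"` or `"-"`).
#' @param replicon_lengths Named integer vector of replicon lengths.
#' @param allow_negative Accept the dialect that stores reverse-strand
#'   coverage as negative numbers (absolute values are taken). Default is
#'   strict non-negative.
#' @return List of [coverage_track()] objects.
#' @export
read_wiggle <- function(path, library, strand, replicon_lengths,
                        allow_negative = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .check_strand(strand)
  lines <- readLines(path)
  vectors <- list()
  chrom <- NULL
  mode <- NULL
  fixed_pos <- NA_integer_
  fixed_step <- NA_integer_
  get_field <- function(line, key) {
    m <- regmatches(line, regexpr(paste0(key, "=[^ \t]+"), line))
    if (length(m) == 0L) NA_character_ else sub(paste0(key, "="), "", m)
  }
  open_chrom <- function(id, lineno) {
    if (is.na(id) || !nzchar(id)) {
      stop("wiggle format error at line ", lineno, ": missing chrom",
           call. = FALSE)
    }
    if (!id %in% names(replicon_lengths)) {
      stop("wiggle format error at line ", lineno, ": unknown replicon '",
           id, "'", call. = FALSE)
    }
    if (is.null(vectors[[id]])) {
      vectors[[id]] <<- numeric(replicon_lengths[[id]])
    }
    id
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "track") || startsWith(line, "#")) {
      next
    }
    if (startsWith(line, "variableStep")) {
      chrom <- open_chrom(get_field(line, "chrom"), i)
      span <- get_field(line, "span")
      if (!is.na(span) && as.integer(span) != 1L) {
        stop("wiggle format error at line ", i, ": only span=1 supported",
             call. = FALSE)
      }
      mode <- "variable"
      next
    }
    if (startsWith(line, "fixedStep")) {
      chrom <- open_chrom(get_field(line, "chrom"), i)
      span <- get_field(line, "span")
      if (!is.na(span) && as.integer(span) != 1L) {
        stop("wiggle format error at line ", i, ": only span=1 supported",
             call. = FALSE)
      }
      fixed_pos <- as.integer(get_field(line, "start"))
      fixed_step <- as.integer(get_field(line, "step") %||% "1")
      if (is.na(fixed_step)) fixed_step <- 1L
      if (is.na(fixed_pos) || fixed_pos < 1L) {
        stop("wiggle format error at line ", i, ": bad fixedStep start",
             call. = FALSE)
      }
      mode <- "fixed"
      next
    }
    if (is.null(mode)) {
      stop("wiggle format error at line ", i,
           ": data before any step declaration", call. = FALSE)
    }
    toks <- strsplit(line, "[ \t]+")[[1L]]
    if (mode == "variable") {
      if (length(toks) != 2L) {
        stop("wiggle format error at line ", i,
             ": variableStep data needs 'position value'", call. = FALSE)
      }
      pos <- as.integer(toks[1L])
      val <- as.numeric(toks[2L])
    } else {
      pos <- fixed_pos
      val <- as.numeric(toks[1L])
      fixed_pos <- fixed_pos + fixed_step
    }
    if (is.na(pos) || is.na(val)) {
      stop("wiggle format error at line ", i, ": non-numeric entry",
           call. = FALSE)
    }
    if (val < 0) {
      if (allow_negative) val <- abs(val)
      else stop("wiggle format error at line ", i,
                ": negative coverage value ", val, call. = FALSE)
    }
    if (pos < 1L || pos > length(vectors[[chrom]])) {
      stop("wiggle format error at line ", i, ": position ", pos,
           " outside replicon '", chrom, "' (length ",
           length(vectors[[chrom]]), ")", call. = FALSE)
    }
    vectors[[chrom]][pos] <- val
  }
  if (length(vectors) == 0L) {
    stop("no coverage data in wiggle '", path, "'", call. = FALSE)
  }
  lapply(names(vectors), function(id) {
    coverage_track(id, strand, library, vectors[[id]])
  })
}

#' Write coverage tracks to a wiggle file
#'
#' Emits `variableStep` sections listing only nonzero positions, one per
#' track; round-trips losslessly with [read_wiggle()] given the replicon
#' lengths.
#'
#' @param tracks List of [coverage_track()] objects (one strand).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(tracks, path) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in tracks) {
    writeLines(sprintf("variableStep chrom=%s", tr$replicon_id), con)
    nz <- which(tr$values != 0)
    if (length(nz)) {
      writeLines(paste(nz, format(tr$values[nz], trim = TRUE,
                                  scientific = FALSE)), con)
    }
  }
  invisible(path)
}

#' Read a library configuration table
#'
#' Tab-separated with header columns `path`, `treatment`, `condition`,
#' `replicate`, `strand`; one row per wiggle file.
#'
#' @param path Path to the TSV.
#' @return Data frame with one row per wiggle file and an added
#'   `library_id` column (`treatment_condition_rep<k>`).
#' @export
read_library_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("path", "treatment", "condition", "replicate", "strand")
  if (!all(need %in% names(df))) {
    stop("library table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  .check_strand(df$strand)
  df$library_id <- paste(df$treatment, df$condition,
                         paste0("rep", df$replicate), sep = "_")
  key <- paste(df$treatment, df$condition, df$replicate, df$strand)
  if (anyDuplicated(key)) {
    stop("duplicate (treatment, condition, replicate, strand) in library table",
         call. = FALSE)
  }
  df
}
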