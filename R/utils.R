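# Internal helpers shared across detectors. All public coordinates in the
# package are 1-based inclusive; strand is "+" or "-".

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  strand
}

# upstream/downstream step in the 5'->3' orientation of `strand`
.strand_sign <- function(strand) ifelse(strand == "+", 1L, -1L)

# vectorized interval overlap (>= 1 nt)
.overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2

.revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# oriented subsequence: 5'->3' on the given strand
.oriented_seq <- function(sequence, start, end, strand) {
  s <- substr(sequence, start, end)
  if (strand == "-") s <- .revcomp(s) else s
}

.normalize_dna <- function(sequence) {
  s <- chartr("u", "T", toupper(sequence))
  s <- chartr("U", "T", s)
  s
}

.empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(x) x[0]), stringsAsFactors = FALSE)
}

# restore the RNG state after a seeded computation so package functions do
# not clobber the caller's random stream
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
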