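#' @importFrom withr with_seed
#' @importFrom methods is
NULL

# Deterministic per-operation RNG streams: the stream seed is a pure function of
# (user seed, operation name), so adding operations never perturbs existing ones.
.op_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  v <- utf8ToInt(op)
  h <- sum(v * (seq_along(v) %% 97L + 1L)) %% 1e6
  as.integer((abs(seed) %% 1e9) * 2057 + h * 131 + 7) %% 2147483629L
}

.with_stream <- function(seed, op, expr) {
  withr::with_seed(.op_seed(seed, op), expr)
}

.DNA <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")

.random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(.DNA, n, replace = TRUE), collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.comp_chars <- function(ch) {
  # complement of a character vector of single bases (keeps N as N)
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  unname(map[ch])
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# internal 0-based half-open <-> GFF3/GenBank 1-based inclusive
.to_gff <- function(start0, end0) list(start = start0 + 1L, end = end0)
.from_gff <- function(start1, end1) list(start = start1 - 1L, end = end1)

.assert <- function(cond, msg, class = "plastodecay_error") {
  if (!cond) stop(errorCondition(msg, class = c(class, "error", "condition")))
  invisible(TRUE)
}

# length of the union of a set of (start, end) half-open intervals
.union_len <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1L]; ce <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= ce) ce <- max(ce, ends[i]) else {
      tot <- tot + (ce - cs); cs <- starts[i]; ce <- ends[i]
    }
  }
  tot + (ce - cs)
}

.is_primitive_unit <- function(unit) {
  p <- nchar(unit)
  if (p == 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L &&
        strrep(substr(unit, 1L, d), p / d) == unit) return(FALSE)
  }
  TRUE
}
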