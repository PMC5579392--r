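#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef median nls optim optimize quantile rbinom
#'   rnorm runif sd setNames vcov wilcox.test
#' @importFrom utils read.delim write.table head tail
NULL

# IUPAC degenerate nucleotide codes over the RNA alphabet.
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("G", "C"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U, and validates that the result contains only
#' A, C, G, U.
#'
#' @param x character scalar.
#' @param what label used in error messages.
#' @return normalized character scalar.
#' @export
normalize_rna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty character scalar")
  x <- chartr("tT", "uU", x)
  x <- toupper(x)
  bad <- regmatches(x, regexpr("[^ACGU]", x))
  if (length(bad) > 0L)
    stop(what, " contains non-RNA character '", bad, "'")
  x
}

#' Construct a snoRNA sequence record
#'
#' @param id sequence identifier.
#' @param seq nucleotide string (T accepted, normalized to U; case-insensitive).
#' @param source free-text provenance.
#' @return an object of class `snorna`.
#' @export
snorna <- function(id, seq, source = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, seq = normalize_rna(seq, paste0("sequence '", id, "'")),
                 source = source),
            class = "snorna")
}

#' @export
print.snorna <- function(x, ...) {
  cat(sprintf("<snorna> %s (%d nt)\n", x$id, nchar(x$seq)))
  invisible(x)
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

# Number of mismatches of `window` (plain bases) against `motif`
# (IUPAC-degenerate), equal lengths assumed.
iupac_mismatches <- function(window, motif) {
  sum(!mapply(function(b, m) b %in% IUPAC_RNA[[m]], window, motif))
}

#' Match a nucleotide string against an IUPAC-degenerate pattern
#'
#' @param x plain RNA string.
#' @param pattern IUPAC pattern of the same length.
#' @return TRUE if every position of `x` is admitted by `pattern`.
#' @export
iupac_match <- function(x, pattern) {
  xb <- seq_chars(normalize_rna(x, "query"))
  pb <- seq_chars(toupper(chartr("tT", "uU", pattern)))
  if (length(xb) != length(pb)) return(FALSE)
  iupac_mismatches(xb, pb) == 0L
}

# Watson-Crick or wobble partner test.
is_wc_or_wobble <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Read snoRNA sequences from a FASTA file
#'
#' @param path FASTA file (RNA or DNA alphabet; T is normalized to U).
#' @return list of [snorna] objects.
#' @export
read_snorna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  out <- lapply(seq_along(ss), function(i)
    snorna(ids[i], as.character(ss[[i]]), source = path))
  names(out) <- ids
  out
}

#' Write snoRNA sequences to a FASTA file
#'
#' @param seqs list of [snorna] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snorna_fasta <- function(seqs, path) {
  ss <- Biostrings::RNAStringSet(vapply(seqs, function(s) s$seq, character(1)))
  names(ss) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Deterministic child seed derived from a master seed and a stream label,
# kept below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 99991L)
}
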