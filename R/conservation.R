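# Column statistics over snoRNA ortholog alignments: per-column base
# frequencies (the counts underlying a sequence logo), joint frequencies of
# two named k-turn positions (e.g. the -1b,-1n pair), and per-family percent
# conservation of -1n = C with a methylated-vs-unmethylated group comparison.

#' Construct a multiple alignment object
#'
#' @param family_id family label (e.g. the human snoRNA gene name).
#' @param rows named character vector of equal-length gapped sequences over
#'   `{A,C,G,U,-}` (T accepted and normalized; `.` treated as `-`).
#' @return object of class `msa_family`.
#' @export
multiple_alignment <- function(family_id, rows) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  rows <- vapply(rows, function(r) {
    r <- toupper(chartr("tT.", "uU-", r))
    r
  }, character(1))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("alignment rows have unequal lengths")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- names(rows)
  bad <- which(matrix(!(mat %in% c("A", "C", "G", "U", "-")), nrow(mat)),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-alphabet character '%s' in row '%s', column %d",
                 mat[bad[1, 1], bad[1, 2]], rownames(mat)[bad[1, 1]], bad[1, 2]))
  structure(list(family_id = family_id, mat = mat,
                 column_count = ncol(mat)),
            class = "msa_family")
}

#' Read an alignment from aligned FASTA or Stockholm
#'
#' @param path alignment file.
#' @param family_id family label (default: file name without extension).
#' @param format `"fasta"` or `"stockholm"`; guessed from the extension
#'   (`.sto`, `.stk` => Stockholm) when missing.
#' @return an `msa_family` object.
#' @export
read_alignment <- function(path, family_id = NULL, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(sto|stk|stockholm)$", path, ignore.case = TRUE))
      "stockholm" else "fasta"
  if (format == "stockholm") {
    ma <- tryCatch(Biostrings::readRNAMultipleAlignment(path, format = "stockholm"),
                   error = function(e)
                     Biostrings::readDNAMultipleAlignment(path, format = "stockholm"))
    rows <- as.character(Biostrings::unmasked(ma))
  } else {
    ss <- Biostrings::readBStringSet(path)
    rows <- setNames(as.character(ss),
                     vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L))
  }
  if (is.null(family_id))
    family_id <- sub("\\.[^.]*$", "", basename(path))
  multiple_alignment(family_id, rows)
}

#' Per-column base counts and fractions of an alignment
#'
#' @param aln an `msa_family` object.
#' @param include_gaps if TRUE, gaps enter the column denominator; by default
#'   they are excluded (sequence-logo convention).
#' @return list with `counts` (4 x ncol matrix, rows A/C/G/U), `fractions`
#'   (same shape; columns with `effective_n = 0` are NA), and `effective_n`
#'   (non-gap count per column, or total rows if `include_gaps`).
#' @export
column_frequencies <- function(aln, include_gaps = FALSE) {
  stopifnot(inherits(aln, "msa_family"))
  bases <- c("A", "C", "G", "U")
  counts <- vapply(seq_len(ncol(aln$mat)), function(j) {
    col <- aln$mat[, j]
    vapply(bases, function(b) sum(col == b), numeric(1))
  }, numeric(4))
  rownames(counts) <- bases
  eff <- if (include_gaps) rep(nrow(aln$mat), ncol(aln$mat)) else colSums(counts)
  fractions <- sweep(counts, 2, ifelse(eff > 0, eff, NA_real_), "/")
  list(counts = counts, fractions = fractions, effective_n = eff)
}

#' Joint frequency of the nucleotides at two named k-turn positions
#'
#' Given a set of annotated sequences, tabulates the dinucleotide at two
#' k-turn positions (e.g. `-1b` and `-1n`, the C-helix pair reported for box
#' C/D logos) as percentages of the input set. Rows where either position is
#' unresolved are excluded and counted.
#'
#' @param annotations list of [kturn_annotation] objects.
#' @param posA,posB position labels among `-2b,-1b,1b,2b,3b`,
#'   `-2n,-1n,1n,2n,3n`, `L1,L2,L3`.
#' @return list with `table` (data.frame pair/count/percent, percents of the
#'   full input size), `n` (input size) and `n_excluded`.
#' @export
pair_frequencies <- function(annotations, posA = "-1b", posB = "-1n") {
  valid <- c("-2b", "-1b", "1b", "2b", "3b", "-2n", "-1n", "1n", "2n", "3n",
             "L1", "L2", "L3")
  if (!(posA %in% valid) || !(posB %in% valid))
    stop("unknown position label; valid labels: ", paste(valid, collapse = ", "))
  get_base <- function(ann, lab) {
    pm <- ann$position_map
    src <- if (lab %in% names(pm$bulged)) pm$bulged
           else if (lab %in% names(pm$nonbulged)) pm$nonbulged else pm$loop
    src[[lab]]$base
  }
  n <- length(annotations)
  if (n == 0L)
    return(list(table = data.frame(pair = character(), count = integer(),
                                   percent = numeric()),
                n = 0L, n_excluded = 0L))
  a <- vapply(annotations, get_base, character(1), lab = posA)
  b <- vapply(annotations, get_base, character(1), lab = posB)
  ok <- !is.na(a) & !is.na(b)
  tab <- table(paste0(a[ok], b[ok]))
  tab <- sort(tab, decreasing = TRUE)
  list(table = data.frame(pair = names(tab), count = as.integer(tab),
                          percent = 100 * as.integer(tab) / n),
       n = n, n_excluded = sum(!ok))
}

# Map an ungapped position of one alignment row to its alignment column.
ungapped_to_column <- function(row_chars, ungapped_index) {
  nongap <- which(row_chars != "-")
  if (ungapped_index < 1L || ungapped_index > length(nongap))
    stop("reference index ", ungapped_index, " outside the ungapped row")
  nongap[ungapped_index]
}

#' Conservation of the -1n position across an ortholog alignment
#'
#' Projects the reference row's -1n sequence index (taken from a
#' [kturn_annotation] made on the ungapped reference sequence) through the
#' alignment and reports the percentage of rows carrying C in that column.
#'
#' @param aln an `msa_family` object.
#' @param anchor [kturn_annotation] of the reference row (made on its
#'   ungapped sequence).
#' @param reference_id row name of the reference sequence in `aln`.
#' @param methylated logical label supplied by the caller (in vivo m6A
#'   evidence for the human member), carried into the report.
#' @return object of class `conservation_report`: list with `family_id`,
#'   `n_sequences`, `column`, `minus1n_c_percent`, `methylated`.
#' @export
minus1n_conservation <- function(aln, anchor, reference_id, methylated = NA) {
  stopifnot(inherits(aln, "msa_family"), inherits(anchor, "kturn_annotation"))
  if (!(reference_id %in% rownames(aln$mat)))
    stop("reference id '", reference_id, "' not present in the alignment")
  idx <- anchor$position_map$nonbulged[["-1n"]]$index
  if (is.na(idx)) stop("anchor annotation has no resolved -1n position")
  ref <- aln$mat[reference_id, ]
  col <- ungapped_to_column(ref, idx)
  column <- aln$mat[, col]
  nongap <- column != "-"
  if (!any(nongap)) stop("the -1n column is all-gap")
  pct <- 100 * sum(column[nongap] == "C") / sum(nongap)
  structure(list(family_id = aln$family_id, n_sequences = nrow(aln$mat),
                 column = col, minus1n_c_percent = pct,
                 methylated = methylated),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("<conservation_report> %s: -1n = C in %.1f%% of %d sequences (methylated: %s)\n",
              x$family_id, x$minus1n_c_percent, x$n_sequences, x$methylated))
  invisible(x)
}

#' Compare -1n conservation between methylated and unmethylated families
#'
#' Per-group mean and median of `minus1n_c_percent` plus a two-sided
#' Mann-Whitney U test (normal approximation, no continuity correction).
#' The rank test is an addition to the visual comparison this statistic is
#' usually presented with, and is labelled as such in the output.
#'
#' @param reports list of `conservation_report` objects with non-NA
#'   `methylated` labels.
#' @return list with `groups` (data.frame of n/mean/median per group), `U`,
#'   `p_value` (NA when either group is empty) and `note`.
#' @export
group_compare <- function(reports) {
  pct <- vapply(reports, function(r) r$minus1n_c_percent, numeric(1))
  meth <- vapply(reports, function(r) as.logical(r$methylated), logical(1))
  if (anyNA(meth)) stop("every report needs a TRUE/FALSE methylated label")
  g <- function(v) if (length(v) == 0L)
    data.frame(n = 0L, mean = NA_real_, median = NA_real_)
  else data.frame(n = length(v), mean = mean(v), median = median(v))
  groups <- rbind(methylated = g(pct[meth]), unmethylated = g(pct[!meth]))
  U <- NA_real_; p <- NA_real_
  if (all(groups$n > 0L)) {
    x <- pct[meth]; y <- pct[!meth]
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    U <- unname(wt$statistic)
    p <- wt$p.value
    if (is.nan(p)) p <- 1  # all observations tied: sigma = 0, z = 0
  }
  list(groups = groups, U = U, p_value = p,
       note = "Mann-Whitney comparison is an addition; the underlying study presents the group contrast graphically")
}
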