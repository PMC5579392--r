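# Cross-referencing annotated A1n positions with m6A modification-site
# tables (RMBase-style records: gene, modification id, chromosome, 1-based
# position, strand, number of supporting experiments).

#' Construct a single-exon gene model
#'
#' @param gene_name gene symbol.
#' @param chromosome chromosome name.
#' @param start,end 1-based inclusive genomic span.
#' @param strand `"+"` or `"-"`.
#' @param sequence spliced transcript sequence in transcript orientation
#'   (optional; length must equal the span length when given).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_name, chromosome, start, end, strand,
                       sequence = NULL) {
  strand <- normalize_strand(strand)
  stopifnot(end >= start)
  if (!is.null(sequence)) {
    sequence <- normalize_rna(sequence, paste0("gene '", gene_name, "' sequence"))
    if (nchar(sequence) != end - start + 1L)
      stop("sequence length does not equal the genomic span length")
  }
  structure(list(gene_name = gene_name, chromosome = chromosome,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, sequence = sequence),
            class = "gene_model")
}

# "-" may arrive as a unicode minus from typeset tables.
normalize_strand <- function(strand) {
  strand <- gsub("−", "-", strand)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  strand
}

#' Map a transcript A1n index to genomic coordinates
#'
#' Plus strand: `position = start + a1n - 1`; minus strand:
#' `position = end - a1n + 1` (transcript 5'->3' maps to descending genomic
#' coordinate). `a1n` is 1-based in the transcript.
#'
#' @param gene a [gene_model].
#' @param annotation a [kturn_annotation] made on the transcript sequence, or
#'   a bare 1-based transcript index.
#' @return list `(chromosome, position, strand)`.
#' @export
map_a1n_to_genome <- function(gene, annotation) {
  stopifnot(inherits(gene, "gene_model"))
  a1n <- if (inherits(annotation, "kturn_annotation"))
    annotation$position_map$nonbulged[["1n"]]$index else as.integer(annotation)
  len <- gene$end - gene$start + 1L
  if (is.na(a1n) || a1n < 1L || a1n > len)
    stop("A1n index ", a1n, " outside the gene span (length ", len, ")")
  pos <- if (gene$strand == "+") gene$start + a1n - 1L else gene$end - a1n + 1L
  list(chromosome = gene$chromosome, position = pos, strand = gene$strand)
}

#' Invert a genomic position back to a transcript index
#'
#' @param gene a [gene_model].
#' @param position 1-based genomic position within the gene span.
#' @return 1-based transcript index.
#' @export
genome_to_transcript <- function(gene, position) {
  if (position < gene$start || position > gene$end)
    stop("position outside the gene span")
  if (gene$strand == "+") position - gene$start + 1L
  else gene$end - position + 1L
}

#' Read an m6A modification-site table
#'
#' Accepts either a TSV with columns `gene_name`, `mod_id`, `chromosome`,
#' `position` (1-based), `strand`, `support_num` and optionally
#' `kturn_position_label`, or a 6-column BED (`chrom`, `start0`, `end`,
#' `name`, `score` = support, `strand`) whose half-open 0-based interval is
#' converted to the 1-based position of its last base.
#'
#' @param path input file.
#' @param format `"tsv"` or `"bed"`; guessed from the extension.
#' @return data.frame of site records.
#' @export
read_modsites <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("BED input needs 6 columns")
    out <- data.frame(gene_name = bed[[4]], mod_id = bed[[4]],
                      chromosome = bed[[1]], position = bed[[3]],
                      strand = normalize_strand(bed[[6]]),
                      support_num = as.integer(bed[[5]]),
                      kturn_position_label = NA_character_)
  } else {
    out <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_name", "mod_id", "chromosome", "position", "strand",
              "support_num")
    miss <- setdiff(need, names(out))
    if (length(miss) > 0L)
      stop("site table lacks columns: ", paste(miss, collapse = ", "))
    out$strand <- normalize_strand(out$strand)
    if (!("kturn_position_label" %in% names(out)))
      out$kturn_position_label <- NA_character_
  }
  stopifnot(all(out$position >= 1L), all(out$support_num >= 0L))
  out
}

#' Intersect mapped A1n targets with m6A sites
#'
#' Inner join on (chromosome, strand, |position difference| <= slack);
#' targets without a matching site are retained with `methylated = FALSE`.
#'
#' @param targets data.frame with columns `id`, `chromosome`, `position`,
#'   `strand` (plus any carry-through columns, e.g. `role`).
#' @param sites data.frame of site records (see [read_modsites()]).
#' @param slack maximum coordinate distance for a match (default 0 = exact;
#'   modification calls are assumed single-nucleotide resolution).
#' @return `targets` with appended columns `methylated`, `mod_id`,
#'   `site_position`, `support_num`, `distance`; one row per (target, site)
#'   match, or one row with `methylated = FALSE` for unmatched targets.
#' @export
crossref_modsites <- function(targets, sites, slack = 0L) {
  stopifnot(slack >= 0L)
  if (nrow(sites) > 0L && anyDuplicated(sites$mod_id))
    stop("duplicate mod_id: ", sites$mod_id[duplicated(sites$mod_id)][1L])
  if (nrow(targets) == 0L)
    return(cbind(targets, methylated = logical(), mod_id = character(),
                 site_position = integer(), support_num = integer(),
                 distance = integer()))
  targets$strand <- normalize_strand(targets$strand)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, , drop = FALSE]
    hit <- which(sites$chromosome == t$chromosome &
                 sites$strand == t$strand &
                 abs(sites$position - t$position) <= slack)
    if (length(hit) == 0L)
      return(cbind(t, methylated = FALSE, mod_id = NA_character_,
                   site_position = NA_integer_, support_num = NA_integer_,
                   distance = NA_integer_))
    do.call(rbind, lapply(hit, function(j)
      cbind(t, methylated = TRUE, mod_id = sites$mod_id[j],
            site_position = sites$position[j],
            support_num = sites$support_num[j],
            distance = abs(sites$position[j] - t$position))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Collapse paralog gene names: strip one trailing capital letter when at
# least two records share the resulting stem (SNORD62A/SNORD62B -> SNORD62).
collapse_paralogs <- function(gene_names, verbose = TRUE) {
  stems <- ifelse(grepl("^(.*[0-9])([A-Z])$", gene_names),
                  sub("^(.*[0-9])([A-Z])$", "\\1", gene_names), gene_names)
  collapse <- stems != gene_names &
    (stems %in% gene_names | vapply(stems, function(s) sum(stems == s) > 1L,
                                    logical(1)))
  out <- ifelse(collapse, stems, gene_names)
  if (verbose && any(collapse)) {
    ch <- unique(paste(gene_names[collapse], "->", out[collapse]))
    message("collapsed paralog names: ", paste(ch, collapse = ", "))
  }
  out
}

#' Summarize a modification-site table
#'
#' Reconstructs the headline counts of an A1n methylation-site table: number
#' of site records, distinct genomic positions, distinct box C/D RNAs (with
#' multi-locus paralogs collapsed by name stem), the box D / box D' split,
#' and the gene with maximal experimental support.
#'
#' @param joined data.frame with columns `gene_name`, `chromosome`,
#'   `position`, `strand`, `support_num`, `kturn_position_label` (containing
#'   `D'` for box D' records). Rows with `methylated = FALSE` (if the column
#'   exists) are ignored.
#' @param verbose emit a message when paralog names are collapsed.
#' @return object of class `crossref_summary`: list with `n_sites`,
#'   `n_unique_positions`, `n_unique_genes`, `n_boxD_genes`,
#'   `n_boxDprime_genes`, `max_support` (list gene/support_num).
#' @export
summarize_crossref <- function(joined, verbose = TRUE) {
  if ("methylated" %in% names(joined))
    joined <- joined[!is.na(joined$methylated) & joined$methylated, ,
                     drop = FALSE]
  if (nrow(joined) == 0L)
    return(structure(list(n_sites = 0L, n_unique_positions = 0L,
                          n_unique_genes = 0L, n_boxD_genes = 0L,
                          n_boxDprime_genes = 0L,
                          max_support = list(gene = NA_character_,
                                             support_num = NA_integer_)),
                     class = "crossref_summary"))
  gene <- collapse_paralogs(joined$gene_name, verbose = verbose)
  role <- ifelse(grepl("D'|D’", joined$kturn_position_label), "boxD'", "boxD")
  per_gene_roles <- tapply(role, gene, function(r) length(unique(r)))
  if (any(per_gene_roles > 1L))
    stop("conflicting k-turn role labels for gene(s): ",
         paste(names(per_gene_roles)[per_gene_roles > 1L], collapse = ", "))
  pos_key <- paste(joined$chromosome, joined$position, joined$strand)
  gene_role <- tapply(role, gene, `[[`, 1L)
  imax <- which.max(joined$support_num)
  structure(list(
    n_sites = nrow(joined),
    n_unique_positions = length(unique(pos_key)),
    n_unique_genes = length(unique(gene)),
    n_boxD_genes = sum(gene_role == "boxD"),
    n_boxDprime_genes = sum(gene_role == "boxD'"),
    max_support = list(gene = unname(gene[imax]),
                       support_num = as.integer(joined$support_num[imax]))),
    class = "crossref_summary")
}

#' @export
print.crossref_summary <- function(x, ...) {
  cat(sprintf(paste0("<crossref_summary> %d site records at %d unique positions, ",
                     "%d unique RNAs (%d box D + %d box D'); max support %s (%s)\n"),
              x$n_sites, x$n_unique_positions, x$n_unique_genes,
              x$n_boxD_genes, x$n_boxDprime_genes,
              x$max_support$support_num, x$max_support$gene))
  invisible(x)
}
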