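# End-to-end orchestration: motif scan -> per-family conservation ->
# modification-site cross-reference -> optional structure pass, with a
# machine-readable JSON summary and per-stage TSVs. Runs are idempotent:
# identical inputs yield byte-identical JSON (no timestamps in outputs).

#' Run the k-turn methylation-site pipeline
#'
#' Stages (each optional except the scan):
#' \enumerate{
#'   \item \strong{scan}: [scan_sequence_set()] over `fasta`.
#'   \item \strong{conservation}: [minus1n_conservation()] per alignment
#'     file; the reference row is the alignment row whose name matches a
#'     FASTA id (else the first row), annotated on its ungapped sequence.
#'   \item \strong{crossref}: A1n indices mapped through `genes` to genomic
#'     coordinates, joined against `sites`, summarized.
#'   \item \strong{structures}: each PDB classified for paired bases and
#'     sheared G·A content.
#' }
#' A stage failure is recorded in the summary and dependent stages are
#' skipped with provenance. One structured log line per stage carries the
#' md5 of its inputs.
#'
#' @param config list or YAML file path with fields: `fasta` (path,
#'   required), `alignments` (character vector of Stockholm paths),
#'   `genes` (TSV path: `gene_name`, `chromosome`, `start`, `end`,
#'   `strand`; `gene_name` must match FASTA ids), `sites` (site TSV path),
#'   `structures` (PDB paths), `out_dir` (required),
#'   `params` (list: `max_mismatch`, `max_mismatch_internal`, `slack`).
#' @return the summary list, invisibly; artifacts written under `out_dir`:
#'   `scan.tsv`, `conservation.tsv`, `crossref.tsv`, `structures.tsv`,
#'   `summary.json`.
#' @export
run_kturn_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$fasta), !is.null(config$out_dir))
  for (p in c(config$fasta, config$alignments, config$genes, config$sites,
              config$structures))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- config$params %||% list()
  mm <- params$max_mismatch %||% 0L
  mmi <- params$max_mismatch_internal %||% (mm + 1L)
  slack <- params$slack %||% 0L
  summary <- list(stages = list())
  log_stage <- function(stage, paths) {
    h <- paste(substr(unname(tools::md5sum(paths)), 1, 8), collapse = ",")
    message(sprintf("[pipeline] stage=%s inputs=%s md5=%s", stage,
                    paste(basename(paths), collapse = ","), h))
  }
  run_stage <- function(name, inputs, fn) {
    log_stage(name, inputs)
    res <- tryCatch(list(ok = TRUE, value = fn()),
                    error = function(e) list(ok = FALSE, error = conditionMessage(e)))
    summary$stages[[name]] <<- if (res$ok) list(status = "ok")
                               else list(status = "failed", error = res$error)
    res
  }

  # stage 1: motif scan
  scan_res <- run_stage("scan", config$fasta, function() {
    seqs <- read_snorna_fasta(config$fasta)
    scan <- scan_sequence_set(seqs, max_mismatch = mm,
                              max_mismatch_internal = mmi)
    write.table(scan, file.path(config$out_dir, "scan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(seqs = seqs, scan = scan)
  })
  if (scan_res$ok) {
    scan <- scan_res$value$scan
    seqs <- scan_res$value$seqs
    found <- scan[scan$status == "ok", , drop = FALSE]
    summary$scan <- list(n_sequences = nrow(scan),
                         n_annotated = nrow(found),
                         n_gac = sum(found$is_gac, na.rm = TRUE),
                         n_drach = sum(found$is_drach, na.rm = TRUE))
  }

  # stage 2: conservation per alignment family
  if (!is.null(config$alignments)) {
    if (!scan_res$ok) {
      summary$stages[["conservation"]] <- list(status = "skipped",
                                               reason = "scan failed")
    } else {
      cons_res <- run_stage("conservation", config$alignments, function() {
        rows <- lapply(config$alignments, function(p) {
          aln <- read_alignment(p)
          ref <- intersect(rownames(aln$mat), names(seqs))
          ref <- if (length(ref) > 0L) ref[1] else rownames(aln$mat)[1]
          refseq <- gsub("-", "", paste(aln$mat[ref, ], collapse = ""))
          fb <- find_boxes(refseq, max_mismatch = mm,
                           max_mismatch_internal = mmi)
          ann <- annotate_kturn(refseq, c(fb$boxC_start[1], fb$boxC_end[1]),
                                c(fb$boxD_start[1], fb$boxD_end[1]),
                                role = fb$role[1])
          rep <- minus1n_conservation(aln, ann, ref)
          data.frame(family_id = rep$family_id, reference_id = ref,
                     n_sequences = rep$n_sequences, column = rep$column,
                     minus1n_c_percent = rep$minus1n_c_percent)
        })
        tab <- do.call(rbind, rows)
        write.table(tab, file.path(config$out_dir, "conservation.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        tab
      })
      if (cons_res$ok)
        summary$conservation <- list(
          n_families = nrow(cons_res$value),
          mean_minus1n_c_percent = mean(cons_res$value$minus1n_c_percent))
    }
  }

  # stage 3: cross-reference against modification sites
  if (!is.null(config$genes) && !is.null(config$sites)) {
    if (!scan_res$ok) {
      summary$stages[["crossref"]] <- list(status = "skipped",
                                           reason = "scan failed")
    } else {
      xr_res <- run_stage("crossref", c(config$genes, config$sites),
                          function() {
        genes <- read.delim(config$genes, stringsAsFactors = FALSE)
        found <- scan[scan$status == "ok", , drop = FALSE]
        gm <- merge(found, genes, by.x = "id", by.y = "gene_name")
        targets <- do.call(rbind, lapply(seq_len(nrow(gm)), function(i) {
          g <- gm[i, ]
          loc <- map_a1n_to_genome(
            gene_model(g$id, g$chromosome, g$start, g$end, g$strand),
            g$a1n_pos)
          data.frame(id = g$id, role = g$role, chromosome = loc$chromosome,
                     position = loc$position, strand = loc$strand,
                     kturn_position_label =
                       if (g$role == "boxC'D'") "boxD' 1n" else "boxD 1n")
        }))
        sites <- read_modsites(config$sites)
        joined <- crossref_modsites(targets, sites, slack = slack)
        joined$gene_name <- joined$id
        joined$support_num[is.na(joined$support_num)] <- 0L
        write.table(joined, file.path(config$out_dir, "crossref.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        summarize_crossref(joined, verbose = FALSE)
      })
      if (xr_res$ok) summary$crossref <- unclass(xr_res$value)
    }
  }

  # stage 4: structures
  if (!is.null(config$structures)) {
    st_res <- run_stage("structures", config$structures, function() {
      rows <- lapply(config$structures, function(p) {
        res <- suppressWarnings(read_structure(p))
        res <- Filter(function(r) r$complete, res)
        hb <- find_hbonds(res)
        bb <- hb[hb$base_base, , drop = FALSE]
        pk <- unique(t(apply(cbind(bb$donor_idx, bb$acceptor_idx), 1, sort)))
        pairs <- lapply(seq_len(nrow(pk)), function(k)
          classify_pair(res[[pk[k, 1]]], res[[pk[k, 2]]], hbonds = hb))
        sh <- detect_sheared_GA(pairs)
        if (length(pairs) == 0L)
          return(data.frame(structure = basename(p), pair = character(),
                            class = character(), n_hbonds = integer(),
                            sheared = logical(), tandem_sheared = integer()))
        data.frame(structure = basename(p),
                   pair = vapply(pairs, function(q)
                     paste(res_label(q$r1), res_label(q$r2)), character(1)),
                   class = vapply(pairs, `[[`, character(1), "class"),
                   n_hbonds = vapply(pairs, function(q) nrow(q$hbonds),
                                     integer(1)),
                   sheared = vapply(pairs, function(q)
                     any(vapply(sh$sheared, identical, logical(1), q)),
                     logical(1)),
                   tandem_sheared = sh$tandem_count)
      })
      tab <- do.call(rbind, rows)
      write.table(tab, file.path(config$out_dir, "structures.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    })
    if (st_res$ok)
      summary$structures <- list(n_structures = length(config$structures),
                                 n_pairs = nrow(st_res$value),
                                 n_sheared = sum(st_res$value$sheared))
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
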