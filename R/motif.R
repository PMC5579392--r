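# Box C/D k-turn annotation.
#
# Architecture implemented here (standard k-turn nomenclature, numbering
# outward from the bulge; b = bulged strand, n = non-bulged strand):
#
#   box C (consensus RUGAUGA) lies on the BULGED strand:
#       R = -1b | U G A U = bulge loop (L1 L2 L3 + one extra nt) | G = 1b, A = 2b
#   box D (consensus CUGA) lies on the NON-BULGED strand:
#       C | U = 3n | G = 2n | A = 1n, with -1n the nucleotide immediately 3'
#       of box D.
#
# The core pairs are the tandem sheared (trans sugar-Hoogsteen) pairs
# G1b.A1n and A2b.G2n. When -1n is a cytosine the non-bulged strand reads
# 5'-G(2n) A(1n) C(-1n)-3', a GAC methyl-transferase target with the
# conserved A1n as the methylated adenine. In a box C/D k-turn the boxes
# appear in the order C ... D and the C helix is the terminal stem; in the
# internal C'/D' k-turn the order is D' ... C' and the C-helix side is closed
# by the short segment between the boxes, usually as a k-loop.

BOX_C_CONSENSUS <- "RUGAUGA"
BOX_D_CONSENSUS <- "CUGA"

# All windows of `seq` matching `motif` within `max_mismatch` IUPAC
# mismatches. Returns data.frame(start, end, mm), 1-based inclusive.
motif_matches <- function(chars, motif, max_mismatch) {
  mb <- seq_chars(motif)
  w <- length(mb)
  n <- length(chars)
  if (n < w) return(data.frame(start = integer(), end = integer(), mm = integer()))
  starts <- seq_len(n - w + 1L)
  mm <- vapply(starts, function(i) iupac_mismatches(chars[i:(i + w - 1L)], mb),
               numeric(1))
  keep <- mm <= max_mismatch
  data.frame(start = starts[keep], end = starts[keep] + w - 1L,
             mm = as.integer(mm[keep]))
}

#' Find box C / box D candidate pairs in a snoRNA sequence
#'
#' Scans for box C (consensus `RUGAUGA`) and box D (consensus `CUGA`) matches
#' and pairs every box C match with every downstream box D match within the
#' mismatch budget (role `boxCD`). For the best such pair it additionally
#' reports internal candidates in the order box D' ... box C' strictly between
#' the two boxes (role `boxC'D'`), scanned with `max_mismatch_internal`.
#'
#' @param seq a [snorna] object (or a bare string, normalized on the fly).
#' @param max_mismatch per-box mismatch budget for the terminal C/D boxes.
#' @param max_mismatch_internal per-box budget for the internal C'/D' boxes
#'   (default `max_mismatch + 1`; the internal boxes are less conserved).
#' @return data.frame with columns `role`, `boxC_start`, `boxC_end`,
#'   `boxD_start`, `boxD_end`, `mm_boxC`, `mm_boxD`, `score` (total
#'   mismatches). Coordinates are 1-based inclusive. Candidates are ordered by
#'   score, then leftmost box C, then leftmost box D. Empty data.frame when
#'   nothing matches. For `boxC'D'` rows the `boxC_*` columns give the box C'
#'   span and `boxD_*` the box D' span (which starts upstream of box C').
#' @export
find_boxes <- function(seq, max_mismatch = 0L,
                       max_mismatch_internal = max_mismatch + 1L) {
  if (is.character(seq)) seq <- snorna("query", seq)
  stopifnot(inherits(seq, "snorna"), max_mismatch >= 0L,
            max_mismatch_internal >= 0L)
  chars <- seq_chars(seq$seq)
  empty <- data.frame(role = character(), boxC_start = integer(),
                      boxC_end = integer(), boxD_start = integer(),
                      boxD_end = integer(), mm_boxC = integer(),
                      mm_boxD = integer(), score = integer())
  if (length(chars) < nchar(BOX_C_CONSENSUS) + nchar(BOX_D_CONSENSUS))
    return(empty)

  cs <- motif_matches(chars, BOX_C_CONSENSUS, max_mismatch)
  ds <- motif_matches(chars, BOX_D_CONSENSUS, max_mismatch)
  if (nrow(cs) == 0L || nrow(ds) == 0L) primary <- empty
  else {
    grid <- expand.grid(ci = seq_len(nrow(cs)), di = seq_len(nrow(ds)))
    keep <- ds$start[grid$di] > cs$end[grid$ci]
    grid <- grid[keep, , drop = FALSE]
    primary <- data.frame(
      role = rep("boxCD", nrow(grid)),
      boxC_start = cs$start[grid$ci], boxC_end = cs$end[grid$ci],
      boxD_start = ds$start[grid$di], boxD_end = ds$end[grid$di],
      mm_boxC = cs$mm[grid$ci], mm_boxD = ds$mm[grid$di],
      score = cs$mm[grid$ci] + ds$mm[grid$di])
    primary <- primary[order(primary$score, primary$boxC_start,
                             primary$boxD_start), , drop = FALSE]
    rownames(primary) <- NULL
  }

  internal <- empty
  if (nrow(primary) > 0L) {
    lo <- primary$boxC_end[1L]    # interior region of the best candidate
    hi <- primary$boxD_start[1L]
    cs2 <- motif_matches(chars, BOX_C_CONSENSUS, max_mismatch_internal)
    ds2 <- motif_matches(chars, BOX_D_CONSENSUS, max_mismatch_internal)
    cs2 <- cs2[cs2$start > lo & cs2$end < hi, , drop = FALSE]
    ds2 <- ds2[ds2$start > lo & ds2$end < hi, , drop = FALSE]
    if (nrow(cs2) > 0L && nrow(ds2) > 0L) {
      grid <- expand.grid(ci = seq_len(nrow(cs2)), di = seq_len(nrow(ds2)))
      # box D' upstream of box C', with >= 1 nt in between so -1n exists
      keep <- cs2$start[grid$ci] > ds2$end[grid$di] + 1L
      grid <- grid[keep, , drop = FALSE]
      if (nrow(grid) > 0L) {
        internal <- data.frame(
          role = rep("boxC'D'", nrow(grid)),
          boxC_start = cs2$start[grid$ci], boxC_end = cs2$end[grid$ci],
          boxD_start = ds2$start[grid$di], boxD_end = ds2$end[grid$di],
          mm_boxC = cs2$mm[grid$ci], mm_boxD = ds2$mm[grid$di],
          score = cs2$mm[grid$ci] + ds2$mm[grid$di])
        internal <- internal[order(internal$score, internal$boxC_start,
                                   internal$boxD_start), , drop = FALSE]
        rownames(internal) <- NULL
      }
    }
  }
  out <- rbind(primary, internal)
  rownames(out) <- NULL
  out
}

# Named (base, index) element of a position map; index NA if off-sequence.
map_pos <- function(chars, idx) {
  n <- length(chars)
  if (is.na(idx) || idx < 1L || idx > n) list(base = NA_character_, index = NA_integer_)
  else list(base = chars[idx], index = as.integer(idx))
}

#' Annotate a k-turn from a box C / box D pair
#'
#' Builds the full k-turn position map from the two box spans. Box C supplies
#' the bulged strand (`-1b` = its first nucleotide, the 4-nt loop, `1b` and
#' `2b` = its last two); box D supplies the non-bulged strand (`3n`, `2n`,
#' `1n` = its last three), with `-1n` the nucleotide immediately 3' of box D.
#' The conserved core requires `1n = A` and `2n = G`.
#'
#' @param seq a [snorna] object.
#' @param boxC_span,boxD_span integer vectors `c(start, end)`, 1-based
#'   inclusive, from [find_boxes()].
#' @param role `"boxCD"` (box C upstream of box D, terminal k-turn) or
#'   `"boxC'D'"` (box D' upstream of box C', internal k-turn); inferred from
#'   the span order when missing.
#' @return an object of class `kturn_annotation` with elements
#'   `sequence_id`, `position_map` (role, bulged/non-bulged/loop position
#'   lists), `boxC_span`, `boxD_span`, `score`, `box_role` (`"boxD"` or
#'   `"boxD'"`), `c_helix` (`"duplex"`, `"kloop"` or `"open"`), `warnings`.
#' @export
annotate_kturn <- function(seq, boxC_span, boxD_span, role = NULL) {
  if (is.character(seq)) seq <- snorna("query", seq)
  stopifnot(inherits(seq, "snorna"),
            length(boxC_span) == 2L, length(boxD_span) == 2L)
  chars <- seq_chars(seq$seq)
  n <- length(chars)
  if (any(c(boxC_span, boxD_span) < 1L) || any(c(boxC_span, boxD_span) > n))
    stop("box spans lie outside the sequence")
  if (boxC_span[2] - boxC_span[1] != nchar(BOX_C_CONSENSUS) - 1L)
    stop("boxC span must cover ", nchar(BOX_C_CONSENSUS), " nucleotides")
  if (boxD_span[2] - boxD_span[1] != nchar(BOX_D_CONSENSUS) - 1L)
    stop("boxD span must cover ", nchar(BOX_D_CONSENSUS), " nucleotides")
  if (max(boxC_span[1], boxD_span[1]) <= min(boxC_span[2], boxD_span[2]))
    stop("boxC and boxD spans overlap")
  if (is.null(role))
    role <- if (boxC_span[1] < boxD_span[1]) "boxCD" else "boxC'D'"
  role <- match.arg(role, c("boxCD", "boxC'D'"))
  if (role == "boxCD" && boxC_span[2] >= boxD_span[1])
    stop("for role boxCD, box C must lie upstream of box D")
  if (role == "boxC'D'" && boxD_span[2] + 1L >= boxC_span[1])
    stop("for role boxC'D', box D' must lie upstream of box C' with >= 1 nt between")

  warnings <- character()
  # core constraint: 1n = A, 2n = G (read from box D)
  n1 <- chars[boxD_span[1] + 3L]
  n2 <- chars[boxD_span[1] + 2L]
  if (n1 != "A")
    stop("k-turn core unsatisfiable: position 1n is ", n1, ", must be A")
  if (n2 != "G")
    stop("k-turn core unsatisfiable: position 2n is ", n2, ", must be G")

  cS <- boxC_span[1]; cE <- boxC_span[2]
  dS <- boxD_span[1]; dE <- boxD_span[2]
  bulged <- list(
    "-2b" = map_pos(chars, cS - 1L),
    "-1b" = map_pos(chars, cS),
    "1b"  = map_pos(chars, cS + 5L),
    "2b"  = map_pos(chars, cS + 6L),
    "3b"  = map_pos(chars, cE + 1L))
  loop <- list(
    "L1" = map_pos(chars, cS + 1L),
    "L2" = map_pos(chars, cS + 2L),
    "L3" = map_pos(chars, cS + 3L))
  loop_extra <- map_pos(chars, cS + 4L)
  nonbulged <- list(
    "-2n" = map_pos(chars, dE + 2L),
    "-1n" = map_pos(chars, dE + 1L),
    "1n"  = map_pos(chars, dE),
    "2n"  = map_pos(chars, dS + 2L),
    "3n"  = map_pos(chars, dS + 1L))
  if (role == "boxCD" && dE + 1L <= n && dE + 1L >= cS && dE + 1L <= cE)
    stop("boxC and boxD spans incompatible")  # unreachable guard
  if (is.na(nonbulged[["-1n"]]$index))
    warnings <- c(warnings, "truncated: -1n position absent")

  # C-helix side: duplex vs k-loop
  c_helix <- "open"
  if (role == "boxCD") {
    # terminal stem: pair (-1b,-1n), (-2b,-2n) from the flanks
    npair <- 0L
    i <- 0L
    repeat {
      bi <- cS - i; ni <- dE + 1L + i
      if (bi < 1L || ni > n) break
      if (!is_wc_or_wobble(chars[bi], chars[ni])) break
      npair <- npair + 1L; i <- i + 1L
    }
    if (npair >= 2L) c_helix <- "duplex"
  } else {
    # internal: segment between -1n (dE+1) and -1b (cS), exclusive
    seg_len <- cS - dE - 2L
    npair <- 0L
    i <- 1L
    while (dE + 1L + i < cS - i + 1L) {
      if (!is_wc_or_wobble(chars[cS - i], chars[dE + 1L + i])) break
      npair <- npair + 1L; i <- i + 1L
    }
    c_helix <- if (seg_len <= 8L && npair < 2L) "kloop"
               else if (npair >= 2L) "duplex" else "open"
  }
  map_role <- if (c_helix == "kloop") "kloop" else role

  score <- iupac_mismatches(chars[cS:cE], seq_chars(BOX_C_CONSENSUS)) +
           iupac_mismatches(chars[dS:dE], seq_chars(BOX_D_CONSENSUS))

  structure(list(
    sequence_id = seq$id,
    position_map = structure(list(role = map_role, bulged = bulged,
                                  nonbulged = nonbulged, loop = loop,
                                  loop_extra = loop_extra),
                             class = "kturn_position_map"),
    boxC_span = as.integer(boxC_span), boxD_span = as.integer(boxD_span),
    score = as.integer(score),
    box_role = if (role == "boxCD") "boxD" else "boxD'",
    c_helix = c_helix, warnings = warnings),
    class = "kturn_annotation")
}

#' @export
print.kturn_annotation <- function(x, ...) {
  pm <- x$position_map
  cat(sprintf("<kturn_annotation> %s [%s, C-helix: %s] boxC %d-%d, boxD %d-%d, score %d\n",
              x$sequence_id, x$box_role, x$c_helix,
              x$boxC_span[1], x$boxC_span[2], x$boxD_span[1], x$boxD_span[2],
              x$score))
  nb <- vapply(pm$nonbulged, function(p) ifelse(is.na(p$base), ".", p$base), character(1))
  cat("  non-bulged 3n,2n,1n,-1n: ",
      paste(nb[c("3n", "2n", "1n", "-1n")], collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Test an annotated A1n for GAC / DRACH methylation-target context
#'
#' Reads the 5-mer centered on A1n 5'->3' along the non-bulged strand, i.e.
#' positions (3n, 2n, 1n, -1n, -2n). `is_drach` applies the degenerate
#' METTL3-METTL14 target consensus `DRACH` (D = A/G/U, R = A/G, H = A/C/U) to
#' the 5-mer; `is_gac` is TRUE when the central triplet (2n, 1n, -1n) is
#' exactly `GAC` *and* the 5-mer is a DRACH instance (equivalently, it
#' matches `DGACH`): a GAC core whose flanks fall outside the
#' methyltransferase consensus is not flagged as a GAC-type target. The
#' bare triplet is always returned in `triplet`, so `is_gac` implies
#' `is_drach` by construction.
#'
#' @param annotation a [kturn_annotation].
#' @param seq the [snorna] the annotation was made on.
#' @return object of class `methyl_target`: list with `annotation`,
#'   `a1n_index`, `context5`, `triplet`, `is_gac`, `is_drach`, `truncated`.
#' @export
scan_gac_target <- function(annotation, seq) {
  if (is.character(seq)) seq <- snorna("query", seq)
  stopifnot(inherits(annotation, "kturn_annotation"), inherits(seq, "snorna"))
  chars <- seq_chars(seq$seq)
  pm <- annotation$position_map
  a1n <- pm$nonbulged[["1n"]]$index
  stopifnot(!is.na(a1n), chars[a1n] == "A")
  idx <- (a1n - 2L):(a1n + 2L)
  ok <- idx >= 1L & idx <= length(chars)
  ctx <- ifelse(ok, chars[pmax(pmin(idx, length(chars)), 1L)], "-")
  context5 <- paste(ctx, collapse = "")
  truncated <- is.na(pm$nonbulged[["-1n"]]$index)
  if (truncated) {
    is_gac <- FALSE; is_drach <- FALSE
    warning("sequence '", seq$id, "': -1n position absent; GAC/DRACH undefined")
  } else {
    triplet <- paste(ctx[2:4], collapse = "")
    is_drach <- !any(ctx == "-") && iupac_match(context5, "DRACH")
    is_gac <- identical(triplet, "GAC") && is_drach
  }
  structure(list(annotation = annotation, a1n_index = a1n,
                 context5 = context5,
                 triplet = paste(ctx[2:4], collapse = ""),
                 is_gac = is_gac, is_drach = is_drach, truncated = truncated),
            class = "methyl_target")
}

#' Scan a set of snoRNA sequences for k-turns and A1n methylation targets
#'
#' Applies [find_boxes()], [annotate_kturn()] and [scan_gac_target()] to each
#' sequence. The best terminal box C/D candidate is annotated (role `boxD`),
#' and, when present, the best internal C'/D' candidate (role `boxD'`).
#' Per-sequence failures are recorded as rows with a `status` message and do
#' not abort the batch.
#'
#' @param seqs list of [snorna] objects (unique ids required).
#' @param max_mismatch mismatch budget for the terminal boxes (default 0).
#' @param max_mismatch_internal budget for the internal C'/D' boxes (default 1).
#' @return data.frame, one row per detected k-turn (or per failed sequence),
#'   with columns `id`, `role`, `boxC_start`, `boxC_end`, `boxD_start`,
#'   `boxD_end`, `a1n_pos` (1-based), `minus1n_base`, `context5`, `is_gac`,
#'   `is_drach`, `score`, `kloop`, `status`.
#' @export
scan_sequence_set <- function(seqs, max_mismatch = 0L, max_mismatch_internal = 1L) {
  if (length(seqs) == 0L)
    return(data.frame(id = character(), role = character(),
                      boxC_start = integer(), boxC_end = integer(),
                      boxD_start = integer(), boxD_end = integer(),
                      a1n_pos = integer(), minus1n_base = character(),
                      context5 = character(), is_gac = logical(),
                      is_drach = logical(), score = integer(),
                      kloop = logical(), status = character()))
  ids <- vapply(seqs, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])

  one_row <- function(id, role, ann = NULL, tgt = NULL, status = "ok") {
    if (is.null(ann))
      return(data.frame(id = id, role = role, boxC_start = NA_integer_,
                        boxC_end = NA_integer_, boxD_start = NA_integer_,
                        boxD_end = NA_integer_, a1n_pos = NA_integer_,
                        minus1n_base = NA_character_, context5 = NA_character_,
                        is_gac = NA, is_drach = NA, score = NA_integer_,
                        kloop = NA, status = status))
    data.frame(id = id, role = ann$box_role,
               boxC_start = ann$boxC_span[1], boxC_end = ann$boxC_span[2],
               boxD_start = ann$boxD_span[1], boxD_end = ann$boxD_span[2],
               a1n_pos = tgt$a1n_index,
               minus1n_base = {
                 b <- ann$position_map$nonbulged[["-1n"]]$base
                 if (is.na(b)) NA_character_ else b
               },
               context5 = tgt$context5, is_gac = tgt$is_gac,
               is_drach = tgt$is_drach, score = ann$score,
               kloop = ann$c_helix == "kloop", status = status)
  }

  rows <- lapply(seqs, function(s) {
    cand <- find_boxes(s, max_mismatch, max_mismatch_internal)
    prim <- cand[cand$role == "boxCD", , drop = FALSE]
    intl <- cand[cand$role == "boxC'D'", , drop = FALSE]
    out <- list()
    if (nrow(prim) == 0L) {
      out[[1]] <- one_row(s$id, "boxD", status = "no box C/D candidate")
    } else {
      out[[1]] <- tryCatch({
        ann <- annotate_kturn(s, c(prim$boxC_start[1], prim$boxC_end[1]),
                              c(prim$boxD_start[1], prim$boxD_end[1]),
                              role = "boxCD")
        tgt <- suppressWarnings(scan_gac_target(ann, s))
        one_row(s$id, "boxD", ann, tgt,
                if (tgt$truncated) "truncated -1n" else "ok")
      }, error = function(e) one_row(s$id, "boxD", status = conditionMessage(e)))
    }
    if (nrow(intl) > 0L) {
      out[[2]] <- tryCatch({
        ann <- annotate_kturn(s, c(intl$boxC_start[1], intl$boxC_end[1]),
                              c(intl$boxD_start[1], intl$boxD_end[1]),
                              role = "boxC'D'")
        tgt <- suppressWarnings(scan_gac_target(ann, s))
        one_row(s$id, "boxD'", ann, tgt,
                if (tgt$truncated) "truncated -1n" else "ok")
      }, error = function(e) one_row(s$id, "boxD'", status = conditionMessage(e)))
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
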