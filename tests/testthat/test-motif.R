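test_that("find_boxes recovers planted motifs and matches the exhaustive window oracle", {
  s <- "AAAAGUGAUGAAAAAAAAAAAACUGAAAAA"
  fb <- find_boxes(s)
  prim <- fb[fb$role == "boxCD", , drop = FALSE]
  expect_identical(prim$boxC_start, oracle_motif_starts(s, "RUGAUGA"))
  expect_identical(prim$boxD_start[1], oracle_motif_starts(s, "CUGA")[1])
  expect_identical(prim$score, 0L)

  expect_identical(nrow(find_boxes(strrep("A", 40))), 0L)
  expect_identical(nrow(find_boxes("GUGA")), 0L)

  # oracle comparison on random sequences, both mismatch budgets
  for (seed in 1:5) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "U"), 120, replace = TRUE),
               collapse = "")
    for (mm in 0:1) {
      fb <- find_boxes(s, max_mismatch = mm)
      fb <- fb[fb$role == "boxCD", , drop = FALSE]
      oc <- oracle_motif_starts(s, "RUGAUGA", mm)
      od <- oracle_motif_starts(s, "CUGA", mm)
      # every oracle (C, downstream D) pairing must appear and vice versa
      want <- expand.grid(c = oc, d = od)
      want <- want[want$d > want$c + 6L, , drop = FALSE]
      got <- paste(fb$boxC_start, fb$boxD_start)
      expect_setequal(got, paste(want$c, want$d))
    }
  }
})

test_that("candidate sets are monotone in the mismatch budget", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "U"), 150, replace = TRUE), collapse = "")
  prev <- character(0)
  for (mm in 0:2) {
    fb <- find_boxes(s, max_mismatch = mm, max_mismatch_internal = mm)
    key <- paste(fb$role, fb$boxC_start, fb$boxD_start)
    expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("annotate_kturn builds the documented position map", {
  # boxC = GUGAUGA at 3..9, spacer of 11 C's, boxD = CUGA at 21..24,
  # -1n = C at 25
  s <- paste0("GG", "GUGAUGA", strrep("C", 11), "CUGA", "CUAA")
  ann <- annotate_kturn(s, c(3, 9), c(21, 24))
  pm <- ann$position_map
  expect_identical(pm$bulged[["-1b"]]$index, 3L)
  expect_identical(pm$bulged[["-1b"]]$base, "G")
  expect_identical(pm$bulged[["1b"]]$index, 8L)   # G of ..UGA
  expect_identical(pm$bulged[["2b"]]$index, 9L)   # A of ..UGA
  expect_identical(pm$loop[["L1"]]$index, 4L)
  expect_identical(pm$nonbulged[["3n"]]$base, "U")
  expect_identical(pm$nonbulged[["2n"]]$base, "G")
  expect_identical(pm$nonbulged[["1n"]]$index, 24L)
  expect_identical(pm$nonbulged[["1n"]]$base, "A")
  expect_identical(pm$nonbulged[["-1n"]]$index, 25L)
  expect_identical(pm$nonbulged[["-1n"]]$base, "C")
  expect_identical(ann$box_role, "boxD")
  expect_identical(ann$score, 0L)

  # overlapping spans rejected
  expect_error(annotate_kturn(s, c(3, 9), c(8, 11)), "overlap")
  # core violation names the position
  s2 <- paste0("GG", "GUGAUGA", strrep("C", 11), "CUGG", "CUAA")  # 1n = G
  expect_error(annotate_kturn(s2, c(3, 9), c(21, 24)), "1n")
})

test_that("kloop vs duplex C-helix call follows the segment rule", {
  # internal D'...C' with a short unpairable segment -> kloop
  s <- "CUGACAAAAAGUGAUGAGG"
  ann <- annotate_kturn(s, boxC_span = c(11, 17), boxD_span = c(1, 4))
  expect_identical(ann$box_role, "boxD'")
  expect_identical(ann$c_helix, "kloop")
  expect_true(ann$position_map$role == "kloop")

  # terminal k-turn whose flanks form >= 2 WC/wobble pairs -> duplex:
  # -1b = G(3) pairs -1n = C, -2b = C(2) pairs -2n = G
  s2 <- paste0("GC", "GUGAUGA", strrep("A", 6), "CUGA", "CG", "AA")
  ann2 <- annotate_kturn(s2, c(3, 9), c(16, 19))
  expect_identical(ann2$c_helix, "duplex")
})

test_that("scan_gac_target reads the A1n context and applies GAC/DRACH logic", {
  mk <- function(minus1, minus2) {
    s <- paste0("GG", "GUGAUGA", strrep("C", 11), "CUGA", minus1, minus2, "A")
    list(seq = s, ann = annotate_kturn(s, c(3, 9), c(21, 24)))
  }
  x <- mk("C", "U")   # context UGACU
  tg <- scan_gac_target(x$ann, x$seq)
  expect_identical(tg$context5, "UGACU")
  expect_identical(tg$triplet, "GAC")
  expect_true(tg$is_gac)
  expect_true(tg$is_drach)
  expect_identical(tg$a1n_index, 24L)

  g <- mk("G", "U")   # triplet GAG
  tg2 <- scan_gac_target(g$ann, g$seq)
  expect_false(tg2$is_gac)
  expect_false(tg2$is_drach)

  # GAC core but a non-H flank breaks the methylation context
  h <- mk("C", "G")   # context UGACG
  tg3 <- scan_gac_target(h$ann, h$seq)
  expect_identical(tg3$triplet, "GAC")
  expect_false(tg3$is_gac)
  expect_false(tg3$is_drach)

  # truncated: no -1n -> warning and both flags FALSE
  st <- paste0("GG", "GUGAUGA", strrep("C", 11), "CUGA")
  annt <- annotate_kturn(st, c(3, 9), c(21, 24))
  expect_warning(tgt <- scan_gac_target(annt, st), "-1n")
  expect_true(tgt$truncated)
  expect_false(tgt$is_gac)
  expect_false(tgt$is_drach)
})

test_that("a GAC-type target is always a DRACH instance (exhaustive 5-mers)", {
  mers <- all_5mers()
  expect_length(mers, 1024L)
  for (m in mers) {
    drach <- iupac_match(m, "DRACH")
    gac <- identical(substr(m, 2, 4), "GAC") && drach
    if (gac) expect_true(drach)
  }
  # the implication is not vacuous: some GAC-core 5-mers are targets
  expect_true(iupac_match("GGACU", "DRACH"))
})

test_that("scan_sequence_set batches, records failures, and rejects duplicates", {
  expect_identical(nrow(scan_sequence_set(list())), 0L)

  good <- snorna("g1", paste0("GG", "GUGAUGA", strrep("C", 11), "CUGA", "CUA"))
  bad <- snorna("b1", strrep("A", 40))
  sc <- scan_sequence_set(list(good, bad))
  expect_identical(sort(sc$id), c("b1", "g1"))
  expect_identical(sc$status[sc$id == "g1"], "ok")
  expect_match(sc$status[sc$id == "b1"], "no box")
  expect_true(sc$is_gac[sc$id == "g1"])

  dup <- list(snorna("x", "ACGU"), snorna("x", "ACGU"))
  expect_error(scan_sequence_set(dup), "x")
})

test_that("scan of generator output recovers all planted flags", {
  g <- gen_snorna_set(n = 10, minus1n_dist = c(C = 0.5, G = 0.5), seed = 11)
  seqs <- lapply(names(g$sequences), function(i) snorna(i, g$sequences[[i]]))
  sc <- scan_sequence_set(seqs)
  expect_true(all(sc$status == "ok"))
  expect_identical(sum(sc$is_gac), sum(g$truth$minus1n_base == "C"))
  expect_identical(sc$minus1n_base, g$truth$minus1n_base)
})
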