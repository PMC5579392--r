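test_that("generators are bit-reproducible under a fixed seed", {
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  gen_snorna_set(n = 8, seed = 123, path = f1)
  gen_snorna_set(n = 8, seed = 123, path = f2)
  expect_identical(readLines(f1), readLines(f2))

  a <- gen_fret_curve(seed = 99)
  b <- gen_fret_curve(seed = 99)
  expect_identical(a$data$E_FRET, b$data$E_FRET)
  expect_false(identical(a$data$E_FRET, gen_fret_curve(seed = 100)$data$E_FRET))

  d1 <- gen_duplex_coords(planted = "sheared", noise_sd = 0.1, seed = 5)
  d2 <- gen_duplex_coords(planted = "sheared", noise_sd = 0.1, seed = 5)
  expect_identical(d1$residues, d2$residues)
})

test_that("planted boxes are the unique exact motif matches", {
  g <- gen_snorna_set(n = 15, seed = 4)
  for (i in seq_len(15)) {
    s <- g$sequences[[i]]
    tr <- g$truth[i, ]
    expect_identical(oracle_motif_starts(s, "RUGAUGA"), tr$boxC_start)
    expect_identical(oracle_motif_starts(s, "CUGA"), tr$boxD_start)
    expect_identical(substr(s, tr$a1n_index, tr$a1n_index), "A")
    expect_identical(substr(s, tr$a1n_index + 1L, tr$a1n_index + 1L),
                     tr$minus1n_base)
  }
})

test_that("the -1n identity distribution is honored within sampling error", {
  g <- gen_snorna_set(n = 300, minus1n_dist = c(C = 0.5, G = 0.5), seed = 10)
  frac <- mean(g$truth$minus1n_base == "C")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 300))
  expect_error(gen_snorna_set(n = 3, minus1n_dist = c(X = 1)), "A,C,G,U")
  expect_error(gen_snorna_set(n = 0))
})

test_that("gen_alignment writes readable Stockholm and tracks conservation", {
  path <- tempfile(fileext = ".sto")
  g <- gen_alignment(n_rows = 25, p_sub = 0.1, minus1n_conservation = 0.6,
                     p_del = 0.08, seed = 3, path = path)
  back <- read_alignment(path)
  expect_identical(back$mat, g$aln$mat)
  col <- g$truth$minus1n_column
  expect_equal(mean(g$aln$mat[, col] == "C"), g$truth$realized_c_fraction)
  # the root row never carries gaps and keeps -1n = C
  expect_identical(unname(g$aln$mat["root", col]), "C")
  expect_error(gen_alignment(n_rows = 0), "n_rows")
})

test_that("gen_modsites places true sites at A1n loci and decoys away", {
  gs <- gen_snorna_set(n = 8, seed = 6)
  genes <- data.frame(gene_name = gs$truth$id, chromosome = "chr1",
                      start = 1000 + 500 * seq_len(8),
                      end = 1000 + 500 * seq_len(8) +
                        nchar(gs$sequences) - 1L,
                      strand = rep(c("+", "-"), 4),
                      a1n_index = gs$truth$a1n_index)
  m <- gen_modsites(genes, n_decoys = 10, seed = 7)
  expect_identical(sum(m$truth$is_true), 8L)
  expect_identical(sum(!m$truth$is_true), 10L)
  true_rows <- m$sites[m$sites$mod_id %in% m$truth$mod_id[m$truth$is_true], ]
  for (i in seq_len(8)) {
    gm <- gene_model(genes$gene_name[i], genes$chromosome[i], genes$start[i],
                     genes$end[i], genes$strand[i])
    loc <- map_a1n_to_genome(gm, genes$a1n_index[i])
    row <- true_rows[true_rows$gene_name == genes$gene_name[i], ]
    expect_identical(row$position, loc$position)
    expect_identical(row$strand, loc$strand)
  }
  # decoys sit >= 5 nt from every true site on the same chromosome/strand
  decoys <- m$sites[grepl("_decoy$", m$sites$gene_name), ]
  same <- merge(decoys, true_rows, by = c("chromosome", "strand"))
  if (nrow(same) > 0)
    expect_true(all(abs(same$position.x - same$position.y) >= 5L))
})

test_that("gen_duplex_coords builds complementary strands with truth labels", {
  g <- gen_duplex_coords(seq1 = "GCAUGC", planted = "none", seed = 1)
  expect_identical(g$truth$base1, c("G", "C", "A", "U", "G", "C"))
  expect_identical(g$truth$base2, c("C", "G", "U", "A", "C", "G"))
  expect_true(all(g$truth$class == "cis WC/WC"))
  expect_identical(g$truth$resno2, 12:7)

  s <- gen_duplex_coords(planted = "sheared", planted_step = 2, seed = 1)
  expect_identical(s$truth$class[2], "trans Sugar/Hoogsteen")
  expect_identical(s$truth$base1[2], "G")
  expect_identical(s$truth$base2[2], "A")

  d <- gen_duplex_coords(planted = "displaced", seed = 1)
  expect_identical(d$truth$class[3], "unpaired")
  r2 <- d$residues[[nrow(d$truth) + 3]]
  expect_identical(r2$resid, "6MA")
  expect_true("CM6" %in% r2$atoms$name)

  expect_error(gen_duplex_coords(noise_sd = -1), "noise_sd")
  expect_error(gen_duplex_coords(planted = "sheared", planted_step = 99))
})

test_that("FRET and ITC generators honor their noise settings", {
  clean <- gen_fret_curve(noise_sd = 0, seed = 1)
  expect_equal(clean$data$E_FRET,
               efret_model(clean$data$P_T, clean$truth$E0, clean$truth$dE,
                           clean$truth$K_A, clean$truth$R_T))
  noisy <- gen_fret_curve(noise_sd = 0.01, seed = 1)
  resid <- noisy$data$E_FRET -
    efret_model(noisy$data$P_T, 0.1, 0.5, 2e7, 2e-7)
  expect_gt(sd(resid), 0.004)
  expect_lt(sd(resid), 0.02)

  itc <- gen_itc_series(noise_sd = 0, seed = 1)
  expect_equal(itc$exp$heats,
               itc_one_site_heats(itc$exp, itc$truth$dH, itc$truth$K,
                                  itc$truth$n))
  expect_error(gen_fret_curve(noise_sd = -0.1), "noise_sd")
})

test_that("snoRNA FASTA I/O round-trips", {
  path <- tempfile(fileext = ".fa")
  g <- gen_snorna_set(n = 5, seed = 44, path = path)
  seqs <- read_snorna_fasta(path)
  expect_identical(vapply(seqs, function(s) s$seq, character(1)),
                   g$sequences)
  out <- tempfile(fileext = ".fa")
  write_snorna_fasta(seqs, out)
  expect_identical(vapply(read_snorna_fasta(out), function(s) s$seq,
                          character(1)),
                   g$sequences)
})
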