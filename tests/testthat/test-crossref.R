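test_that("transcript-to-genome mapping follows strand arithmetic", {
  gp <- gene_model("g", "chr1", 101, 150, "+")
  gm <- gene_model("g", "chr1", 101, 150, "-")
  # 1-based index 10 (the 10th transcript base)
  expect_identical(map_a1n_to_genome(gp, 10)$position, 110L)
  expect_identical(map_a1n_to_genome(gm, 10)$position, 141L)
  expect_identical(map_a1n_to_genome(gm, 10)$strand, "-")

  expect_error(map_a1n_to_genome(gp, 0), "outside")
  expect_error(map_a1n_to_genome(gp, 51), "outside")
  expect_error(gene_model("g", "chr1", 10, 5, "+"))
  expect_error(gene_model("g", "chr1", 1, 5, "x"), "strand")
})

test_that("map then invert round-trips for random genes on both strands", {
  set.seed(9)
  for (k in 1:200) {
    start <- sample(1:1e6, 1)
    len <- sample(50:300, 1)
    strand <- sample(c("+", "-"), 1)
    g <- gene_model("g", "chrZ", start, start + len - 1L, strand)
    idx <- sample(len, 1)
    loc <- map_a1n_to_genome(g, idx)
    expect_identical(genome_to_transcript(g, loc$position), as.integer(idx))
  }
})

test_that("read_modsites accepts the TSV schema and 6-column BED", {
  sites <- read_modsites(fixture_path("a1n_m6a_sites_human.tsv"))
  expect_identical(nrow(sites), 19L)
  expect_true(all(c("gene_name", "mod_id", "chromosome", "position",
                    "strand", "support_num",
                    "kturn_position_label") %in% names(sites)))
  expect_true(all(sites$strand %in% c("+", "-")))

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t100\tsiteA\t7\t+",
               "chr2\t199\t200\tsiteB\t3\t-"), bed)
  b <- read_modsites(bed)
  expect_identical(b$position, c(100L, 200L))   # 1-based last base
  expect_identical(b$support_num, c(7L, 3L))
  expect_identical(b$strand, c("+", "-"))

  bad <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t100\tsiteA", bad)
  expect_error(read_modsites(bad), "6 columns")
})

test_that("crossref join agrees with the all-pairs oracle and keeps misses", {
  set.seed(21)
  targets <- data.frame(
    id = sprintf("t%02d", 1:25),
    chromosome = sample(c("chr1", "chr2"), 25, replace = TRUE),
    position = sample(1000:1040, 25, replace = TRUE),
    strand = sample(c("+", "-"), 25, replace = TRUE))
  sites <- data.frame(
    gene_name = sprintf("g%02d", 1:30),
    mod_id = sprintf("m%02d", 1:30),
    chromosome = sample(c("chr1", "chr2"), 30, replace = TRUE),
    position = sample(1000:1040, 30, replace = TRUE),
    strand = sample(c("+", "-"), 30, replace = TRUE),
    support_num = sample(1:9, 30, replace = TRUE))
  for (slack in c(0L, 1L, 3L)) {
    j <- crossref_modsites(targets, sites, slack = slack)
    expect_identical(sum(j$methylated),
                     oracle_join_count(targets, sites, slack))
    # every target appears; unmatched rows carry methylated = FALSE
    expect_setequal(unique(j$id), targets$id)
    expect_true(all(is.na(j$mod_id[!j$methylated])))
    expect_true(all(j$distance[j$methylated] <= slack))
  }

  dup <- rbind(sites, sites[1, ])
  expect_error(crossref_modsites(targets, dup, slack = 0L), "mod_id")
})

test_that("summarize_crossref collapses paralogs and splits box roles", {
  joined <- data.frame(
    gene_name = c("SNORD62A", "SNORD62B", "SNORD99", "SNORD12"),
    chromosome = c("chr9", "chr9", "chr1", "chr2"),
    position = c(100L, 250L, 300L, 400L),
    strand = c("+", "+", "-", "+"),
    support_num = c(2L, 5L, 9L, 1L),
    kturn_position_label = c("boxD 1n", "boxD 1n", "boxD 1n", "boxD' 1n"))
  sm <- suppressMessages(summarize_crossref(joined))
  expect_identical(sm$n_sites, 4L)
  expect_identical(sm$n_unique_positions, 4L)
  expect_identical(sm$n_unique_genes, 3L)     # SNORD62A/B collapse
  expect_identical(sm$n_boxD_genes, 2L)
  expect_identical(sm$n_boxDprime_genes, 1L)
  expect_identical(sm$max_support$gene, "SNORD99")
  expect_identical(sm$max_support$support_num, 9L)
  expect_message(summarize_crossref(joined), "SNORD62")

  # rows flagged methylated = FALSE are ignored
  joined$methylated <- c(TRUE, TRUE, FALSE, TRUE)
  sm2 <- suppressMessages(summarize_crossref(joined))
  expect_identical(sm2$n_sites, 3L)

  # a gene with conflicting role labels is an error
  bad <- joined[, setdiff(names(joined), "methylated")]
  bad$kturn_position_label[2] <- "boxD' 1n"
  expect_error(suppressMessages(summarize_crossref(bad)), "SNORD62")
})

test_that("gene models validate sequences and unicode strands", {
  expect_error(gene_model("g", "chr1", 1, 10, "+", sequence = "ACGU"),
               "length")
  g <- gene_model("g", "chr1", 1, 4, "−", sequence = "acgt")
  expect_identical(g$strand, "-")
  expect_identical(g$sequence, "ACGU")
})
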