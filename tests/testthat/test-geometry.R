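# Helpers local to this file -------------------------------------------------

rand_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

res_xyz <- function(r) as.matrix(r$atoms[, c("x", "y", "z")])

atom_of <- function(r, name) {
  i <- match(name, r$atoms$name)
  c(r$atoms$x[i], r$atoms$y[i], r$atoms$z[i])
}

pair_dist <- function(r1, a1, r2, a2) sqrt(sum((atom_of(r1, a1) - atom_of(r2, a2))^2))

classify_duplex <- function(res, n_pairs) {
  vapply(seq_len(n_pairs), function(i)
    classify_pair(res[[i]], res[[n_pairs + i]])$class, character(1))
}

# Superposition ---------------------------------------------------------------

test_that("superpose matches the bio3d least-squares oracle", {
  set.seed(1)
  for (k in 1:5) {
    ref <- matrix(rnorm(30, sd = 4), 10, 3)
    R <- rand_rotation()
    mob <- t(R %*% t(ref)) + matrix(rnorm(30, sd = 0.3), 10, 3) +
      matrix(c(5, -2, 7), 10, 3, byrow = TRUE)
    sp <- superpose(mob, ref)
    expect_equal(sp$rmsd, oracle_superpose_rmsd(mob, ref), tolerance = 1e-6)
    # rotation is proper and orthonormal
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-10)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-10)
    # applying the fit reproduces the reported rmsd
    expect_equal(rmsd_of(apply_superposition(sp, mob), ref), sp$rmsd,
                 tolerance = 1e-12)
  }
})

test_that("superpose recovers an exact rigid transform and rejects degeneracy", {
  set.seed(2)
  ref <- matrix(rnorm(24, sd = 3), 8, 3)
  R <- rand_rotation()
  mob <- t(R %*% t(ref)) + matrix(c(1, 2, 3), 8, 3, byrow = TRUE)
  sp <- superpose(mob, ref)
  expect_lt(sp$rmsd, 1e-10)
  expect_equal(sp$rotation %*% R, diag(3), tolerance = 1e-8)

  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(superpose(line, line), "collinear")
  expect_error(superpose(ref[1:2, ], ref[1:2, ]))
})

# H-bond detection ------------------------------------------------------------

test_that("find_hbonds reports the built-in sheared G.A hydrogen bonds", {
  g <- gen_duplex_coords(planted = "sheared", noise_sd = 0, seed = 1)
  n <- nrow(g$truth)
  r1 <- g$residues[[3]]        # guanine of the planted pair
  r2 <- g$residues[[n + 3]]    # adenine
  hb <- find_hbonds(list(r1, r2))
  bb <- hb[hb$base_base, ]
  key <- paste(bb$donor_atom, bb$acceptor_atom)
  expect_true("N2 N7" %in% key)   # G N2 -> A N7
  expect_true("N6 N3" %in% key)   # A N6 -> G N3
  expect_equal(bb$distance[key == "N2 N7"], 2.8, tolerance = 1e-6)
  expect_equal(bb$distance[key == "N6 N3"], 3.4, tolerance = 1e-6)
  # distances are sorted and within the cutoff
  expect_true(!is.unsorted(hb$distance))
  expect_true(all(hb$distance <= 3.5))
})

test_that("a distant pair yields no hydrogen bonds", {
  g <- gen_duplex_coords(planted = "none", noise_sd = 0, seed = 1)
  n <- nrow(g$truth)
  hb <- find_hbonds(list(g$residues[[1]], g$residues[[n + 4]]))
  expect_identical(nrow(hb), 0L)
})

# Pair classification ---------------------------------------------------------

test_that("classification reproduces the generator truth, noise-free", {
  for (planted in c("none", "sheared", "displaced")) {
    g <- gen_duplex_coords(planted = planted, noise_sd = 0, seed = 1)
    got <- classify_duplex(g$residues, nrow(g$truth))
    expect_identical(substr(got, 1, nchar(g$truth$class)), g$truth$class)
  }
})

test_that("classification is invariant under rigid-body transforms", {
  set.seed(7)
  g <- gen_duplex_coords(planted = "sheared", noise_sd = 0, seed = 1)
  n <- nrow(g$truth)
  base <- classify_duplex(g$residues, n)
  for (k in 1:3) {
    moved <- transform_residues(g$residues, rand_rotation(),
                                rnorm(3, sd = 50))
    expect_identical(classify_duplex(moved, n), base)
  }
})

test_that("detect_sheared_GA filters sheared pairs and counts tandems", {
  g <- gen_duplex_coords(planted = "sheared", noise_sd = 0, seed = 1)
  n <- nrow(g$truth)
  pairs <- lapply(seq_len(n), function(i)
    classify_pair(g$residues[[i]], g$residues[[n + i]]))
  sh <- detect_sheared_GA(pairs)
  expect_length(sh$sheared, 1L)
  expect_identical(sh$sheared[[1]]$r1$resno, 3L)
  expect_identical(sh$tandem_count, 0L)

  # duplicate the sheared pair one step along both strands -> tandem
  g2 <- transform_residues(list(g$residues[[3]], g$residues[[n + 3]]),
                           diag(3), c(0, 0, 2.8))
  g2[[1]]$resno <- 4L
  g2[[2]]$resno <- g$residues[[n + 3]]$resno - 1L
  p2 <- classify_pair(g2[[1]], g2[[2]])
  sh2 <- detect_sheared_GA(c(pairs, list(p2)))
  expect_length(sh2$sheared, 2L)
  expect_identical(sh2$tandem_count, 1L)
})

# N6 methylation and clash ----------------------------------------------------

test_that("add_n6_methyl places an sp2 carbon in the base plane", {
  g <- gen_duplex_coords(planted = "sheared", noise_sd = 0, seed = 1)
  n <- nrow(g$truth)
  a <- g$residues[[n + 3]]
  anti <- add_n6_methyl(a, "anti")
  syn <- add_n6_methyl(a, "syn")
  expect_equal(pair_dist(anti, "CM6", anti, "N6"), 1.45, tolerance = 1e-9)
  # anti is farther from N1 than syn
  expect_gt(pair_dist(anti, "CM6", anti, "N1"),
            pair_dist(syn, "CM6", syn, "N1"))
  expect_identical(anti$methyl_rotamer, "anti")
  expect_error(add_n6_methyl(g$residues[[3]]), "adenine")
})

test_that("clash_check distinguishes rotamers against the partner ribose", {
  g <- gen_duplex_coords(planted = "sheared", noise_sd = 0, seed = 1)
  n <- nrow(g$truth)
  gre <- g$residues[[3]]
  ade <- g$residues[[n + 3]]
  syn <- clash_check(add_n6_methyl(ade, "syn"), gre)
  expect_true(syn$clashing)
  expect_lt(syn$min_distance, 3.0)
  expect_identical(unname(syn$closest["methyl"]), "CM6")

  # brute-force oracle: minimum CM6-ribose distance over all ribose atoms
  aug <- add_n6_methyl(ade, "syn")
  cm6 <- atom_of(aug, "CM6")
  rib <- gre$atoms[gre$atoms$name %in%
                     c("C1'", "C2'", "C3'", "C4'", "O4'", "O2'"), ]
  dmin <- min(sqrt((rib$x - cm6[1])^2 + (rib$y - cm6[2])^2 +
                     (rib$z - cm6[3])^2))
  expect_equal(syn$min_distance, dmin, tolerance = 1e-12)

  expect_error(clash_check(ade, gre), "add_n6_methyl")
  expect_error(clash_check(aug, gre, cutoff = -1))
})

# Structure file round-trip ---------------------------------------------------

test_that("write_residues_pdb round-trips through read_structure", {
  g <- gen_duplex_coords(planted = "displaced", noise_sd = 0, seed = 1)
  path <- tempfile(fileext = ".pdb")
  write_residues_pdb(g$residues, path)
  res <- read_structure(path)
  expect_length(res, length(g$residues))
  # the modified adenine maps back to parent base A, resid preserved
  resids <- vapply(res, function(r) r$resid, character(1))
  bases <- vapply(res, function(r) r$base, character(1))
  expect_true("6MA" %in% resids)
  expect_identical(bases[resids == "6MA"], "A")
  # coordinates survive to PDB precision (1e-3)
  orig <- do.call(rbind, lapply(g$residues, res_xyz))
  back <- do.call(rbind, lapply(res, res_xyz))
  ord1 <- order(round(orig[, 1], 3), round(orig[, 2], 3))
  ord2 <- order(round(back[, 1], 3), round(back[, 2], 3))
  expect_equal(orig[ord1, ], back[ord2, ], tolerance = 1e-3,
               ignore_attr = TRUE)
  # classification from the file agrees with in-memory truth
  byres <- split(res, vapply(res, function(r) r$chain, character(1)))
  n <- nrow(g$truth)
  a_chain <- byres$A[order(vapply(byres$A, function(r) r$resno, integer(1)))]
  b_chain <- byres$B[order(vapply(byres$B, function(r) r$resno, integer(1)),
                           decreasing = TRUE)]
  got <- vapply(seq_len(n), function(i)
    classify_pair(a_chain[[i]], b_chain[[i]])$class, character(1))
  expect_identical(substr(got, 1, nchar(g$truth$class)), g$truth$class)
})
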