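# Seeded synthetic-data generators. Every analysis stage in the package can
# be exercised closed-loop against machine-readable ground truth emitted
# alongside each artifact. Each generator draws from its own derived random
# stream (see derive_seed) so adding one generator never perturbs another.
#
# The 3D duplex builder uses idealized planar base templates (regular
# hexagon of side 1.39 A with a fused regular pentagon for purines,
# exocyclic substituents on the external bisectors) plus a planar-pentagon
# ribose. Pair poses (cis Watson-Crick; sheared trans Sugar/Hoogsteen G.A;
# the displaced non-paired G/N6-methyl-A arrangement) are found once,
# deterministically, by minimizing squared deviations from target H-bond
# distances under an interatomic overlap penalty. Helical stacking uses
# conventional A-form-like parameters (rise 2.8 A, twist 32.7 deg) -- these
# are documented constants, not fitted values.

# Run a thunk under a derived, temporary random stream.
with_stream <- function(seed, stream, thunk) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(derive_seed(seed, stream))
  thunk()
}

rand_bases <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)

#' Generate a synthetic box C/D snoRNA set with planted k-turn boxes
#'
#' Each sequence carries an exact box C (`RUGAUGA`) and a downstream exact
#' box D (`CUGA`); the base immediately 3' of box D (the -1n position) is
#' drawn from `minus1n_dist`, and the following base (-2n) from `A,C,U` so
#' that a planted `-1n = C` always forms a canonical DRACH methylation
#' context. Flanks and the internal spacer are resampled
#' until the planted boxes are the unique motif matches, so the truth table
#' is unambiguous by construction (decoy-free; see `gen_modsites` for
#' decoys at the site level).
#'
#' @param n number of sequences.
#' @param spacer_len length of the segment between box C and box D.
#' @param flank5,flank3 flank lengths (5' of box C / 3' of box D); `flank5
#'   >= 2` and `flank3 >= 2` so the -2b..-1b and -1n..-2n positions exist.
#' @param minus1n_dist named probability vector over `A,C,G,U` for the -1n
#'   base (default: always `C`).
#' @param seed integer seed.
#' @param path optional FASTA output path.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame: id, boxC_start/end, boxD_start/end, a1n_index,
#'   minus1n_base).
#' @export
gen_snorna_set <- function(n = 20L, spacer_len = 30L, flank5 = 5L,
                           flank3 = 8L, minus1n_dist = c(C = 1),
                           seed = 1L, path = NULL) {
  stopifnot(n >= 1L, spacer_len >= 1L, flank5 >= 2L, flank3 >= 2L)
  p <- minus1n_dist / sum(minus1n_dist)
  if (any(p < 0) || !all(names(p) %in% c("A", "C", "G", "U")))
    stop("minus1n_dist must be non-negative over A,C,G,U")
  with_stream(seed, "snorna", function() {
    seqs <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      minus1n <- sample(names(p), 1L, prob = p)
      for (try in 1:200) {
        boxC <- paste0(sample(c("A", "G"), 1L), "UGAUGA")
        # -2n (first base 3' of -1n) is drawn from H = {A,C,U} so a planted
        # -1n = C always sits in a canonical DRACH methylation context
        # (3n = U from box D already satisfies D).
        minus2n <- sample(c("A", "C", "U"), 1L)
        s <- paste0(paste(rand_bases(flank5), collapse = ""), boxC,
                    paste(rand_bases(spacer_len), collapse = ""), "CUGA",
                    minus1n, minus2n,
                    paste(rand_bases(flank3 - 2L), collapse = ""))
      ch <- seq_chars(s)
        cm <- motif_matches(ch, BOX_C_CONSENSUS, 0L)
        dm <- motif_matches(ch, BOX_D_CONSENSUS, 0L)
        if (nrow(cm) == 1L && nrow(dm) == 1L) break
        if (try == 200) stop("could not generate a decoy-free sequence")
      }
      cs <- flank5 + 1L
      ds <- flank5 + 7L + spacer_len + 1L
      seqs[i] <- s
      truth[[i]] <- data.frame(id = sprintf("synth_%03d", i),
                               boxC_start = cs, boxC_end = cs + 6L,
                               boxD_start = ds, boxD_end = ds + 3L,
                               a1n_index = ds + 3L, minus1n_base = minus1n)
    }
    truth <- do.call(rbind, truth)
    names(seqs) <- truth$id
    if (!is.null(path)) {
      writeLines(paste0(">", names(seqs), "\n", seqs), path)
    }
    list(sequences = seqs, truth = truth)
  })
}

#' Generate a synthetic ortholog alignment with controlled -1n conservation
#'
#' Rows derive from a planted-k-turn root by per-column substitution with
#' probability `p_sub`; the -1n column is handled separately: each non-root
#' row keeps `C` with probability `minus1n_conservation`, otherwise draws
#' uniformly from `A,G,U`. Optional per-position deletion gaps with
#' probability `p_del` (box positions and -1n are never deleted).
#'
#' @param n_rows number of rows including the root (`>= 1`).
#' @param p_sub per-column substitution probability for non-root rows.
#' @param minus1n_conservation probability a non-root row keeps C at -1n.
#' @param p_del per-position gap probability for non-root rows.
#' @param seed integer seed.
#' @param path optional Stockholm output path.
#' @return list with `aln` (an `msa_family`), `root_id`, `root_sequence`
#'   (ungapped), `truth` (configured and realized -1n C fraction, -1n
#'   column index).
#' @export
gen_alignment <- function(n_rows = 10L, p_sub = 0.1,
                          minus1n_conservation = 1.0, p_del = 0,
                          seed = 1L, path = NULL) {
  if (n_rows < 1L) stop("n_rows must be >= 1")
  stopifnot(p_sub >= 0, p_sub <= 1, p_del >= 0, p_del < 1,
            minus1n_conservation >= 0, minus1n_conservation <= 1)
  root <- gen_snorna_set(n = 1L, seed = derive_seed(seed, "aln_root"))
  root_seq <- unname(root$sequences[1])
  tr <- root$truth[1, ]
  keep <- c(tr$boxC_start:tr$boxC_end, tr$boxD_start:tr$boxD_end,
            tr$a1n_index + 1L)
  m1col <- tr$a1n_index + 1L
  with_stream(seed, "alignment", function() {
    bases <- c("A", "C", "G", "U")
    L <- nchar(root_seq)
    rootc <- seq_chars(root_seq)
    rows <- matrix("", n_rows, L)
    rows[1, ] <- rootc
    if (n_rows > 1L) for (r in 2:n_rows) {
      rc <- rootc
      sub <- runif(L) < p_sub
      sub[m1col] <- FALSE
      if (any(sub))
        rc[sub] <- vapply(rc[sub], function(b)
          sample(setdiff(bases, b), 1L), character(1))
      rc[m1col] <- if (runif(1) < minus1n_conservation) "C"
                   else sample(c("A", "G", "U"), 1L)
      if (p_del > 0) {
        del <- runif(L) < p_del
        del[keep] <- FALSE
        rc[del] <- "-"
      }
      rows[r, ] <- rc
    }
    ids <- c("root", if (n_rows > 1L) sprintf("ortholog_%02d", 2:n_rows))
    row_str <- apply(rows, 1, paste, collapse = "")
    names(row_str) <- ids
    aln <- multiple_alignment("synthetic_family", row_str)
    if (!is.null(path))
      writeLines(c("# STOCKHOLM 1.0",
                   sprintf("%-14s %s", ids, row_str), "//"), path)
    realized <- mean(rows[, m1col] == "C")
    list(aln = aln, root_id = "root", root_sequence = root_seq,
         truth = list(minus1n_column = m1col,
                      configured_conservation = minus1n_conservation,
                      realized_c_fraction = realized))
  })
}

#' Generate a synthetic m6A site table against known gene models
#'
#' For each gene a true site is emitted at the genomic position of its A1n
#' with probability `subset_fraction`; `n_decoys` decoy sites are placed at
#' least 5 nt away from every true A1n position. Support counts are sampled
#' uniformly from `support_range`.
#'
#' @param genes data.frame with columns `gene_name`, `chromosome`, `start`,
#'   `end`, `strand`, `a1n_index` (1-based transcript index) and optionally
#'   `kturn_position_label`.
#' @param subset_fraction probability each true site is emitted.
#' @param n_decoys number of decoy records.
#' @param support_range integer range to sample support counts from.
#' @param seed integer seed.
#' @param path optional TSV output path (read back by [read_modsites()]).
#' @return list with `sites` (data.frame in the site-table schema) and
#'   `truth` (data.frame: mod_id, gene_name, is_true).
#' @export
gen_modsites <- function(genes, subset_fraction = 1.0, n_decoys = 0L,
                         support_range = 1:11, seed = 1L, path = NULL) {
  stopifnot(subset_fraction >= 0, subset_fraction <= 1, n_decoys >= 0L,
            all(c("gene_name", "chromosome", "start", "end", "strand",
                  "a1n_index") %in% names(genes)))
  with_stream(seed, "modsites", function() {
    rows <- list(); truth <- list(); k <- 0L
    true_pos <- character(0)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      gm <- gene_model(g$gene_name, g$chromosome, g$start, g$end, g$strand)
      loc <- map_a1n_to_genome(gm, g$a1n_index)
      true_pos <- c(true_pos, paste(loc$chromosome, loc$position, loc$strand))
      if (runif(1) <= subset_fraction) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          gene_name = g$gene_name, mod_id = sprintf("syn_site_%04d", k),
          chromosome = loc$chromosome, position = loc$position,
          strand = loc$strand,
          support_num = sample(support_range, 1L),
          kturn_position_label = if ("kturn_position_label" %in% names(g))
            g$kturn_position_label else "boxD 1n")
        truth[[k]] <- data.frame(mod_id = rows[[k]]$mod_id,
                                 gene_name = g$gene_name, is_true = TRUE)
      }
    }
    for (d in seq_len(n_decoys)) {
      g <- genes[sample(nrow(genes), 1L), ]
      repeat {
        pos <- sample(g$start:g$end, 1L)
        if (!any(paste(g$chromosome, pos, g$strand) == true_pos) &&
            all(abs(pos - as.integer(sub(".* (\\d+) .*", "\\1",
              true_pos[startsWith(true_pos, paste0(g$chromosome, " "))]))) >= 5L
              | !startsWith(true_pos, paste0(g$chromosome, " "))))
          break
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        gene_name = paste0(g$gene_name, "_decoy"), mod_id =
          sprintf("syn_site_%04d", k),
        chromosome = g$chromosome, position = pos, strand = g$strand,
        support_num = sample(support_range, 1L),
        kturn_position_label = NA_character_)
      truth[[k]] <- data.frame(mod_id = rows[[k]]$mod_id,
                               gene_name = g$gene_name, is_true = FALSE)
    }
    sites <- if (k > 0L) do.call(rbind, rows) else
      data.frame(gene_name = character(), mod_id = character(),
                 chromosome = character(), position = integer(),
                 strand = character(), support_num = integer(),
                 kturn_position_label = character())
    if (!is.null(path))
      write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(sites = sites,
         truth = if (k > 0L) do.call(rbind, truth) else
           data.frame(mod_id = character(), gene_name = character(),
                      is_true = logical()))
  })
}

#' Generate a synthetic FRET titration from the two-state isotherm
#'
#' Evaluates [efret_model()] on a protein concentration ladder at the
#' default RNA concentration of 200 nM and adds Gaussian noise. The default
#' endpoints (`E0 = 0.1`, `dE = 0.5`) give a saturation plateau of 0.6, the
#' behavior of an unmethylated k-turn; lowering `dE` to 0.2 emulates the
#' reduced plateau of a methylated substrate.
#'
#' @param P_T protein ladder (molar); default 0 plus 24 log-spaced points
#'   over 1 nM .. 10 uM.
#' @param R_T RNA concentration (molar).
#' @param E0,dE,K_A true isotherm parameters.
#' @param noise_sd Gaussian noise s.d. on E_FRET, `>= 0`.
#' @param seed integer seed.
#' @param path optional TSV output path (read back by [read_fret_tsv()]).
#' @return list with `data` (a [fret_titration]) and `truth` (the
#'   parameters).
#' @export
gen_fret_curve <- function(P_T = c(0, 10^seq(-9, -5, length.out = 24)),
                           R_T = 200e-9, E0 = 0.1, dE = 0.5, K_A = 2e7,
                           noise_sd = 0.01, seed = 1L, path = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_stream(seed, "fret", function() {
    E <- efret_model(P_T, E0, dE, K_A, R_T) + rnorm(length(P_T), 0, noise_sd)
    data <- fret_titration(P_T, E, R_T)
    if (!is.null(path))
      writeLines(c(sprintf("# R_T_molar = %.10g", R_T), "P_T_molar\tE_FRET",
                   sprintf("%.10g\t%.10g", P_T, E)), path)
    list(data = data, truth = list(E0 = E0, dE = dE, K_A = K_A, R_T = R_T,
                                   noise_sd = noise_sd))
  })
}

#' Generate a synthetic ITC injection series
#'
#' One-set-of-sites heats under the default instrument protocol: a 0.4 ul
#' pre-injection followed by 19 x 2 ul injections into a 200 ul cell with
#' 20 uM RNA titrated by 200 uM protein at 298 K.
#'
#' @param inj_vol injection schedule (litres).
#' @param cell_conc,syringe_conc,cell_vol,temperature cell composition, see
#'   [itc_experiment()].
#' @param dH,K,n true parameters (cal/mol, 1/M, sites).
#' @param noise_sd Gaussian noise s.d. on each heat (cal), `>= 0`.
#' @param seed integer seed.
#' @param path optional TSV output path (read back by [read_itc_tsv()]).
#' @return list with `exp` (an [itc_experiment] carrying heats) and `truth`.
#' @export
gen_itc_series <- function(inj_vol = c(0.4e-6, rep(2e-6, 19L)),
                           cell_conc = 20e-6, syringe_conc = 200e-6,
                           cell_vol = 200e-6, temperature = 298,
                           dH = -12000, K = 2e6, n = 1, noise_sd = 0,
                           seed = 1L, path = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  exp0 <- itc_experiment(inj_vol, heats = NULL, cell_conc = cell_conc,
                         syringe_conc = syringe_conc, cell_vol = cell_vol,
                         temperature = temperature)
  with_stream(seed, "itc", function() {
    q <- itc_one_site_heats(exp0, dH, K, n) + rnorm(length(inj_vol), 0, noise_sd)
    exp0$heats <- q
    if (!is.null(path))
      writeLines(c(sprintf("# cell_conc_M = %.10g", cell_conc),
                   sprintf("# syringe_conc_M = %.10g", syringe_conc),
                   sprintf("# cell_vol_L = %.10g", cell_vol),
                   sprintf("# temperature_K = %.10g", temperature),
                   "inj_vol_L\theat_cal",
                   sprintf("%.10g\t%.12g", inj_vol, q)), path)
    list(exp = exp0, truth = list(dH = dH, K = K, n = n, noise_sd = noise_sd))
  })
}

## ---------------------------------------------------------------------
## Idealized 3D nucleotide templates and the duplex builder

normalize3 <- function(v) v / sqrt(sum(v^2))

rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

rot_about <- function(axis, theta) {
  a <- normalize3(axis); c <- cos(theta); s <- sin(theta)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + s * K + (1 - c) * (K %*% K)
}

# Planar base skeleton: regular hexagon (side 1.39), fused regular pentagon
# for purines, exocyclic substituents on external bisectors, C1' on the
# glycosidic nitrogen. Returns a matrix with atom rownames, z = 0 for all
# base atoms.
base_skeleton <- function(base) {
  side <- 1.39
  ang <- c(90, 30, -30, -90, -150, 150) * pi / 180
  hexm <- side * cbind(cos(ang), sin(ang), 0)
  rownames(hexm) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  exo <- function(v, center, d) v + d * normalize3(v - center)
  origin <- c(0, 0, 0)
  m <- hexm
  if (base %in% PURINES) {
    p4 <- hexm["C4", ]; p5 <- hexm["C5", ]
    mid <- (p4 + p5) / 2
    a5 <- side / (2 * tan(pi / 5))
    pc <- mid + a5 * normalize3(mid)          # pentagon center, away from hexagon
    steps <- function(sgn) {
      v <- p4 - pc
      out <- matrix(0, 3, 3)
      for (k in 1:4) {
        v <- as.vector(rot_z(sgn * 2 * pi / 5) %*% v)
        if (k <= 3) out[k, ] <- pc + v
      }
      list(out = out, closes = sqrt(sum((pc + v - p5)^2)) < 1e-6)
    }
    s <- steps(1); if (!s$closes) s <- steps(-1)
    stopifnot(s$closes)
    pent <- s$out
    rownames(pent) <- c("N9", "C8", "N7")
    m <- rbind(m, pent)
    m <- rbind(m, "C1'" = exo(m["N9", ], pc, 1.47))
    if (base == "A") m <- rbind(m, N6 = exo(m["C6", ], origin, 1.34))
    if (base == "G") m <- rbind(m, O6 = exo(m["C6", ], origin, 1.23),
                                N2 = exo(m["C2", ], origin, 1.34))
  } else {
    m <- rbind(m, "C1'" = exo(m["N1", ], origin, 1.47),
               O2 = exo(m["C2", ], origin, 1.23))
    if (base == "C") m <- rbind(m, N4 = exo(m["C4", ], origin, 1.34))
    if (base == "U") m <- rbind(m, O4 = exo(m["C4", ], origin, 1.23))
  }
  m
}

# Attach a planar-pentagon ribose at C1'. The furanose ring lies in the
# plane spanned by the outward glycosidic direction and the base normal;
# O2' is tilted toward the sugar-edge side (this idealization places O2'
# where the sugar edge expects it; pucker is deliberately ignored).
attach_ribose <- function(m, base) {
  gly_n <- if (base %in% PURINES) "N9" else "N1"
  c1 <- m["C1'", ]
  ex <- normalize3(c1 - m[gly_n, ])
  ez <- c(0, 0, 1)
  ey <- pracma_cross(ez, ex)
  # sugar-edge side: toward N3 (purine) or O2 (pyrimidine)
  se <- if (base %in% PURINES) m["N3", ] else m["O2", ]
  if (sum((se - c1) * ey) < 0) ey <- -ey
  side <- 1.45
  R5 <- side / (2 * sin(pi / 5))
  pc <- c1 + R5 * normalize3(0.9 * ex + 0.44 * ez)
  ring_for <- function(sgn) {
    v <- c1 - pc
    out <- matrix(0, 4, 3)
    for (k in 1:4) {
      v <- as.vector(rot_about(ey, sgn * 2 * pi / 5) %*% v)
      out[k, ] <- pc + v
    }
    rownames(out) <- c("C2'", "C3'", "C4'", "O4'")
    out
  }
  r <- ring_for(1)
  if (r["C2'", 3] > ring_for(-1)["C2'", 3]) r <- ring_for(-1)
  rad <- function(v) normalize3(v - pc)
  o2p <- r["C2'", ] + 1.42 * normalize3(0.35 * rad(r["C2'", ]) + 0.95 * ey +
                                          0.55 * ez)
  o3p <- r["C3'", ] + 1.42 * normalize3(rad(r["C3'", ]) + 0.3 * ey)
  c5p <- r["C4'", ] + 1.51 * normalize3(rad(r["C4'", ]) + 0.8 * ez)
  o5p <- c5p + 1.42 * ez
  rbind(m, r, "O2'" = o2p, "O3'" = o3p, "C5'" = c5p, "O5'" = o5p)
}

nt_template <- function(base) attach_ribose(base_skeleton(base), base)

template_to_residue <- function(m, chain, resno, base, resid = base) {
  nt_residue(chain, resno, base,
             data.frame(name = rownames(m),
                        element = substr(rownames(m), 1, 1),
                        x = m[, 1], y = m[, 2], z = m[, 3]),
             resid = resid)
}

# Direct pose construction: for each H-bond target (a1 on base1, a2 on
# base2, distance d), a virtual position is placed at a1 + d * u where u is
# the outward direction of a1 from base1's ring centroid (the idealized
# H-bond direction); base2 is then rigidly fitted (rotation about z +
# in-plane translation, after an optional 180-degree flip about x for
# antiparallel Watson-Crick normals) so its target atoms land on the
# virtual points. This keeps donor-antecedent-acceptor angles near linear
# by construction.
construct_pair_pose <- function(m1, m2, targets, flipped,
                                common_direction = FALSE) {
  if (flipped) m2 <- m2 %*% diag(c(1, -1, -1))
  ring <- intersect(c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9"),
                    rownames(m1))
  ctr <- colMeans(m1[ring, , drop = FALSE])
  dirs <- lapply(targets, function(t) normalize3(m1[t$a1, ] - ctr))
  if (common_direction) {
    # blend each radial direction with their mean: parallel enough to keep
    # the virtual points' spacing consistent with the partner edge, radial
    # enough to preserve donor-antecedent-acceptor angles
    u <- normalize3(Reduce(`+`, dirs) / length(dirs))
    dirs <- lapply(dirs, function(v) normalize3(v + 2 * u))
  }
  dst <- do.call(rbind, lapply(seq_along(targets), function(k)
    m1[targets[[k]]$a1, ] + targets[[k]]$d * dirs[[k]]))
  src <- do.call(rbind, lapply(targets, function(t) m2[t$a2, ]))
  cs <- colMeans(src[, 1:2, drop = FALSE])
  cd <- colMeans(dst[, 1:2, drop = FALSE])
  X <- sweep(src[, 1:2, drop = FALSE], 2, cs)
  Y <- sweep(dst[, 1:2, drop = FALSE], 2, cd)
  sv <- svd(crossprod(X, Y))
  dsign <- sign(det(sv$v %*% t(sv$u)))
  if (dsign == 0) dsign <- 1
  R2 <- sv$v %*% diag(c(1, dsign)) %*% t(sv$u)
  shift <- cd - as.vector(R2 %*% cs)
  list(par = c(atan2(R2[2, 1], R2[1, 1]), shift[1], shift[2]))
}

# In-plane rigid placement by optimization: squared deviations from target
# distances (heavily weighted), floor distances for `repel` pairs, and a
# soft interatomic overlap penalty. Used for the displaced arrangement,
# which is not edge-to-edge and has no natural direct construction.
solve_pair_pose <- function(m1, m2, targets, flipped, repel = list(),
                            start = NULL) {
  if (flipped) m2 <- m2 %*% diag(c(1, -1, -1))
  place <- function(par) {
    sweep(m2 %*% t(rot_z(par[1])), 2, c(par[2], par[3], 0), "+")
  }
  obj <- function(par) {
    p2 <- place(par)
    err <- 0
    for (t in targets) {
      d <- sqrt(sum((m1[t$a1, ] - p2[t$a2, ])^2))
      err <- err + (t$w %||% 100) * (d - t$d)^2
    }
    for (t in repel) {
      d <- sqrt(sum((m1[t$a1, ] - p2[t$a2, ])^2))
      err <- err + 100 * max(0, t$d - d)^2
    }
    dd2 <- outer(rowSums(m1^2), rowSums(p2^2), "+") - 2 * m1 %*% t(p2)
    pen <- matrix(20 * pmax(0, 2.7 - sqrt(pmax(dd2, 0)))^2,
                  nrow(m1), nrow(p2))
    for (t in targets)
      pen[match(t$a1, rownames(m1)), match(t$a2, rownames(p2))] <- 0
    err + sum(pen)
  }
  starts <- if (!is.null(start)) list(start) else {
    unlist(lapply(seq(0, 2 * pi, length.out = 13)[-13], function(th)
      lapply(c(6, 8, 10), function(dx) c(th, dx, 0))), recursive = FALSE)
  }
  best <- NULL
  for (s0 in starts) {
    o <- optim(s0, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best <- optim(best$par, obj, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-12))
  list(coords = place(best$par), value = best$value)
}

pose_cache <- new.env(parent = emptyenv())

# Trans sugar-Hoogsteen G·A construction. The adenine Hoogsteen edge is
# fitted against the guanine sugar edge along the edge's outward normal
# (the antiparallel template flip puts the adenine ring on the open side),
# the two H-bond distances are refined exactly, and both bases are then
# counter-rotated about the axes through their own H-bonded atoms. For
# coplanar templates the two-distance constraint leaves the glycosidic
# orientation degenerate (the adenine sugar-base direction lies almost on
# the C1'-C1' axis); the counter-tilts emulate the strong non-planarity of
# real sheared pairs, selecting the trans conformer with a wide margin
# while leaving both H-bond distances untouched (each rotation axis passes
# through that base's two bonded atoms). The resulting pose places the
# adenine N6 amine ~3 A from the guanine O2' -- the crowding that an
# N6-methyl turns into a steric clash.
construct_sheared_pose <- function(m1, m2) {
  tg <- pair_targets("G", "A", "sheared")
  m2f <- m2 %*% diag(c(1, -1, -1))
  n2 <- m1["N2", 1:2]
  n3 <- m1["N3", 1:2]
  ctr <- colMeans(base_skeleton("G")[, 1:2])
  ev <- n3 - n2
  nrm <- c(ev[2], -ev[1]) / sqrt(sum(ev^2))
  if (sum(nrm * (n2 - ctr)) < 0) nrm <- -nrm
  dst <- rbind(n2 + tg[[1]]$d * nrm, n3 + tg[[2]]$d * nrm)
  src <- m2f[c(tg[[1]]$a2, tg[[2]]$a2), 1:2]
  cs <- colMeans(src)
  cd <- colMeans(dst)
  sv <- svd(crossprod(sweep(src, 2, cs), sweep(dst, 2, cd)))
  dsign <- sign(det(sv$v %*% t(sv$u)))
  if (dsign == 0) dsign <- 1
  R2 <- sv$v %*% diag(c(1, dsign)) %*% t(sv$u)
  shift <- cd - as.vector(R2 %*% cs)
  sol <- solve_pair_pose(m1, m2, tg, flipped = TRUE,
                         start = c(atan2(R2[2, 1], R2[1, 1]), shift))
  tilt <- function(m, a1, a2, phi) {
    ax <- normalize3(m[a2, ] - m[a1, ])
    sweep(sweep(m, 2, m[a1, ]) %*% t(rot_about(ax, phi)), 2, m[a1, ], "+")
  }
  list(m1 = tilt(m1, "N2", "N3", 30 * pi / 180),
       m2 = tilt(sol$coords, "N7", "N6", -60 * pi / 180),
       value = sol$value)
}

# H-bond distance targets per planted pair class.
pair_targets <- function(b1, b2, class) {
  if (class == "wc") {
    key <- paste0(b1, b2)
    return(switch(key,
      GC = list(list(a1 = "O6", a2 = "N4", d = 2.91),
                list(a1 = "N1", a2 = "N3", d = 2.95),
                list(a1 = "N2", a2 = "O2", d = 2.86)),
      CG = list(list(a1 = "N4", a2 = "O6", d = 2.91),
                list(a1 = "N3", a2 = "N1", d = 2.95),
                list(a1 = "O2", a2 = "N2", d = 2.86)),
      AU = list(list(a1 = "N1", a2 = "N3", d = 2.82),
                list(a1 = "N6", a2 = "O4", d = 2.95)),
      UA = list(list(a1 = "N3", a2 = "N1", d = 2.82),
                list(a1 = "O4", a2 = "N6", d = 2.95)),
      stop("no Watson-Crick targets for ", key)))
  }
  if (class == "sheared")   # G on strand 1, A on strand 2
    return(list(list(a1 = "N2", a2 = "N7", d = 2.8),
                list(a1 = "N3", a2 = "N6", d = 3.4)))
  if (class == "displaced") # G on strand 1, methylated A on strand 2
    return(list(list(a1 = "O2'", a2 = "N6", d = 2.8)))
  stop("unknown pair class: ", class)
}

# Pose (pair of coordinate matrices, recentred on the C1'-C1' midpoint) for
# a planted pair class; computed once per class and cached.
planted_pair <- function(b1, b2, class) {
  key <- paste(b1, b2, class)
  if (!is.null(pose_cache[[key]])) return(pose_cache[[key]])
  m1 <- nt_template(b1)
  m2 <- nt_template(b2)
  if (class == "sheared") {
    sh <- construct_sheared_pose(m1, m2)
    mid <- (sh$m1["C1'", ] + sh$m2["C1'", ]) / 2
    out <- list(m1 = sweep(sh$m1, 2, mid), m2 = sweep(sh$m2, 2, mid),
                objective = sh$value)
    pose_cache[[key]] <- out
    return(out)
  }
  sol <- if (class == "displaced") {
    solve_pair_pose(m1, m2, pair_targets(b1, b2, class), flipped = FALSE,
                    repel = list(list(a1 = "N2", a2 = "N7", d = 6.5),
                                 list(a1 = "N3", a2 = "N6", d = 6.5)))
  } else if (class == "wc") {
    # parallel H-bond geometry: construct directly, no refinement. With
    # this template family the edge atom order matches without the
    # antiparallel flip (all base atoms are coplanar either way).
    tg <- pair_targets(b1, b2, class)
    st <- construct_pair_pose(m1, m2, tg, flipped = FALSE,
                              common_direction = TRUE)
    list(coords = sweep(m2 %*% t(rot_z(st$par[1])), 2,
                        c(st$par[2], st$par[3], 0), "+"),
         value = NA_real_)
  } else stop("unknown pair class: ", class)
  mid <- (m1["C1'", ] + sol$coords["C1'", ]) / 2
  out <- list(m1 = sweep(m1, 2, mid), m2 = sweep(sol$coords, 2, mid),
              objective = sol$value)
  pose_cache[[key]] <- out
  out
}

WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")

#' Generate an idealized RNA duplex with an optional planted pair geometry
#'
#' Builds `n_pairs` stacked base pairs with conventional helical parameters
#' (default rise 2.8 A, twist 32.7 deg). All steps are cis Watson-Crick
#' pairs of `seq1` against its complement, except an optional planted step:
#' a sheared (trans Sugar/Hoogsteen) G·A geometry realizing the
#' G(N2)-A(N7) = 2.8 A and A(N6)-G(N3) = 3.4 A contacts, or a displaced
#' non-paired G / N6-methyladenine arrangement with A(N6)-G(O2') = 2.8 A
#' and both former H-bond distances > 6 A.
#'
#' @param seq1 strand-1 sequence (default alternating `GC...`); the planted
#'   step forces G on strand 1 and A on strand 2.
#' @param planted `"none"`, `"sheared"` or `"displaced"`.
#' @param planted_step 1-based step index of the planted pair.
#' @param rise,twist helical rise (A) and twist (degrees) per step.
#' @param noise_sd isotropic Gaussian coordinate noise s.d. (A), `>= 0`.
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param path optional PDB output path.
#' @return list with `residues` (strand 1 then strand 2; chain A residues
#'   `1..n`, chain B residues `2n..n+1` antiparallel) and `truth`
#'   (data.frame: step, resno1, base1, resno2, base2, class).
#' @export
gen_duplex_coords <- function(seq1 = NULL, planted = c("none", "sheared",
                                                       "displaced"),
                              planted_step = 3L, n_pairs = 6L, rise = 2.8,
                              twist = 32.7, noise_sd = 0, seed = 1L,
                              path = NULL) {
  planted <- match.arg(planted)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(seq1))
    seq1 <- paste(rep(c("G", "C"), length.out = n_pairs), collapse = "")
  b1 <- seq_chars(seq1)
  n_pairs <- length(b1)
  if (planted != "none") {
    stopifnot(planted_step >= 1L, planted_step <= n_pairs)
    b1[planted_step] <- "G"
  }
  b2 <- unname(WC_PARTNER[b1])
  strand1 <- vector("list", n_pairs)
  strand2 <- vector("list", n_pairs)
  truth <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    cls <- "wc"
    base2 <- b2[i]
    if (planted != "none" && i == planted_step) {
      cls <- planted
      base2 <- "A"
    }
    pose <- planted_pair(b1[i], base2, cls)
    Rz <- rot_z((i - 1L) * twist * pi / 180)
    shift <- c(0, 0, (i - 1L) * rise)
    m1 <- sweep(pose$m1 %*% t(Rz), 2, shift, "+")
    m2 <- sweep(pose$m2 %*% t(Rz), 2, shift, "+")
    resid2 <- if (cls == "displaced") "6MA" else base2
    strand1[[i]] <- template_to_residue(m1, "A", i, b1[i])
    strand2[[i]] <- template_to_residue(m2, "B", 2L * n_pairs + 1L - i,
                                        base2, resid = resid2)
    if (cls == "displaced")
      strand2[[i]] <- add_n6_methyl(strand2[[i]], "anti")
    truth[[i]] <- data.frame(
      step = i, resno1 = i, base1 = b1[i],
      resno2 = 2L * n_pairs + 1L - i, base2 = base2,
      class = switch(cls, wc = "cis WC/WC",
                     sheared = "trans Sugar/Hoogsteen",
                     displaced = "unpaired"))
  }
  residues <- c(strand1, strand2)
  if (noise_sd > 0) {
    residues <- with_stream(seed, "duplex_noise", function() {
      lapply(residues, function(r) {
        na <- nrow(r$atoms)
        r$atoms$x <- r$atoms$x + rnorm(na, 0, noise_sd)
        r$atoms$y <- r$atoms$y + rnorm(na, 0, noise_sd)
        r$atoms$z <- r$atoms$z + rnorm(na, 0, noise_sd)
        r
      })
    })
  }
  if (!is.null(path)) write_residues_pdb(residues, path)
  list(residues = residues, truth = do.call(rbind, truth))
}

#' Apply a rigid-body transform to residues
#'
#' @param residues list of [nt_residue] objects.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed residue list.
#' @export
transform_residues <- function(residues, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  lapply(residues, function(r) {
    xyz <- t(rotation %*% t(as.matrix(r$atoms[, c("x", "y", "z")]))) +
      matrix(translation, nrow(r$atoms), 3, byrow = TRUE)
    r$atoms$x <- xyz[, 1]; r$atoms$y <- xyz[, 2]; r$atoms$z <- xyz[, 3]
    r
  })
}

#' Write residues to a PDB file
#'
#' @param residues list of [nt_residue] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_residues_pdb <- function(residues, path) {
  lines <- character(0)
  serial <- 0L
  for (r in residues) for (k in seq_len(nrow(r$atoms))) {
    serial <- serial + 1L
    nm <- r$atoms$name[k]
    nm_f <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
    lines <- c(lines, sprintf(
      "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, nm_f, r$resid, r$chain, r$resno,
      r$atoms$x[k], r$atoms$y[k], r$atoms$z[k], 1, 0,
      substr(nm, 1, 1)))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
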