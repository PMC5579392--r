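# Independent oracles used across the suite. Each reimplements the checked
# quantity by a different route than the package code (brute force, an
# external library, or an algebraic identity) so agreement is evidence, not
# tautology.

# Brute-force equilibrium complex concentration from the mass balance
# K_A = C / ((P_T - C)(R_T - C)). For conditioning, solve numerically for
# the free concentration s of the limiting species (s + K s (L - S + s) = S
# with S = min, L = max of the totals; every term is a positive sum), then
# C = S - s.
oracle_complex_conc <- function(P_T, R_T, K_A) {
  vapply(P_T, function(p) {
    if (p == 0) return(0)
    S <- min(p, R_T); L <- max(p, R_T)
    f <- function(s) s * (1 + K_A * (L - S + s)) - S
    s <- stats::uniroot(f, c(0, S), tol = .Machine$double.eps)$root
    # uniroot stops at an absolute x-tolerance; polish to full relative
    # precision with Newton steps on the same mass balance
    for (k in 1:4) s <- s - f(s) / (1 + K_A * (L - S + 2 * s))
    S - s
  }, numeric(1))
}

# Exhaustive window matcher over a plain base-set table (no shared code with
# the package's IUPAC machinery).
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U", R = c("A", "G"), Y = c("C", "U"),
  S = c("G", "C"), W = c("A", "U"), K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))
oracle_motif_starts <- function(seq_string, motif, max_mismatch = 0L) {
  s <- strsplit(seq_string, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  w <- length(m)
  if (length(s) < w) return(integer(0))
  hits <- integer(0)
  for (i in 1:(length(s) - w + 1)) {
    mm <- 0L
    for (k in 1:w) if (!(s[i + k - 1] %in% ORACLE_IUPAC[[m[k]]])) mm <- mm + 1L
    if (mm <= max_mismatch) hits <- c(hits, i)
  }
  hits
}

# All 4^5 plain 5-mers.
all_5mers <- function() {
  b <- c("A", "C", "G", "U")
  g <- expand.grid(b, b, b, b, b, stringsAsFactors = FALSE)
  apply(g[, 5:1], 1, paste, collapse = "")
}

# Kabsch oracle through bio3d: optimal rotation via bio3d::rot.lsq applied
# to centered coordinates.
oracle_superpose_rmsd <- function(mobile, reference) {
  xx <- as.vector(t(mobile))
  yy <- as.vector(t(reference))
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = yy, mobile = matrix(xx, nrow = 1)))
  sqrt(mean((as.vector(fitted) - yy)^2 * 3))
}

# All-pairs brute-force site join (chromosome, strand, |dpos| <= slack).
oracle_join_count <- function(targets, sites, slack) {
  n <- 0L
  for (i in seq_len(nrow(targets))) for (j in seq_len(nrow(sites))) {
    if (targets$chromosome[i] == sites$chromosome[j] &&
        targets$strand[i] == sites$strand[j] &&
        abs(targets$position[i] - sites$position[j]) <= slack)
      n <- n + 1L
  }
  n
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "snokturn")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata", name)
  p
}
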