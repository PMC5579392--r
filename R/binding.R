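# Binding isotherms for protein-induced k-turn folding.
#
# FRET: a two-state protein-RNA binding model in which the FRET efficiency
# reports the fraction of RNA folded by bound protein,
#
#   E(P_T) = E0 + dE * C / R_T,
#
# where C is the equilibrium complex concentration, the physically
# meaningful (smaller) root of
#
#   C^2 - C * (P_T + R_T + 1/K_A) + P_T * R_T = 0.
#
# The printed form of this equation in the source literature carries a
# typographically garbled discriminant; the implementation here is the
# algebraically consistent mass-balance solution, which reproduces both
# limits: E(0) = E0 and E(P_T -> Inf) = E0 + dE.
#
# ITC: the one-set-of-sites (Wiseman) model with discrete displaced-volume
# bookkeeping for injections into a fixed-volume cell.

#' Construct a FRET titration series
#'
#' @param P_T total protein concentrations (molar), non-negative and strictly
#'   increasing.
#' @param E_FRET measured FRET efficiencies (nominally in `[0, 1]`).
#' @param R_T total RNA concentration (molar), a scalar.
#' @return object of class `fret_titration`.
#' @export
fret_titration <- function(P_T, E_FRET, R_T) {
  stopifnot(length(P_T) == length(E_FRET), length(P_T) >= 3L,
            all(P_T >= 0), all(diff(P_T) > 0), R_T > 0)
  structure(list(P_T = as.numeric(P_T), E_FRET = as.numeric(E_FRET),
                 R_T = as.numeric(R_T)),
            class = "fret_titration")
}

#' Read a FRET titration from TSV
#'
#' Two columns `P_T_molar`, `E_FRET`; the RNA concentration is carried in a
#' header comment line `# R_T_molar = <value>`.
#'
#' @param path TSV file.
#' @return a [fret_titration].
#' @export
read_fret_tsv <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  m <- regmatches(hdr, regexpr("R_T_molar\\s*=\\s*[0-9.eE+-]+", hdr))
  if (length(m) == 0L) stop("header comment '# R_T_molar = <value>' required")
  R_T <- as.numeric(sub(".*=\\s*", "", m[[1]]))
  d <- read.delim(path, comment.char = "#")
  fret_titration(d$P_T_molar, d$E_FRET, R_T)
}

# Smaller root of C^2 - C*(P + R + 1/K) + P*R = 0, computed in the
# cancellation-free form 2PR / (b + sqrt(b^2 - 4PR)).
complex_conc <- function(P_T, R_T, K_A) {
  b <- P_T + R_T + 1 / K_A
  disc <- pmax(b^2 - 4 * P_T * R_T, 0)
  2 * P_T * R_T / (b + sqrt(disc))
}

#' Two-state FRET binding isotherm
#'
#' @param P_T total protein concentration(s), molar (vectorized).
#' @param E0 FRET efficiency at zero protein.
#' @param dE full range of the efficiency change.
#' @param K_A apparent association constant (M^-1), `> 0`.
#' @param R_T total RNA concentration (molar), `> 0`.
#' @return predicted FRET efficiencies; `E0` exactly at `P_T = 0`,
#'   approaching `E0 + dE` at saturation, and equal to the stoichiometric
#'   limit `E0 + dE * min(P_T, R_T) / R_T` as `K_A -> Inf`.
#' @export
efret_model <- function(P_T, E0, dE, K_A, R_T) {
  if (any(P_T < 0) || R_T <= 0) stop("concentrations must be non-negative (R_T > 0)")
  if (K_A <= 0) stop("K_A must be > 0")
  E0 + dE * complex_conc(P_T, R_T, K_A) / R_T
}

#' Fit the FRET binding isotherm to a titration
#'
#' Least-squares fit of [efret_model()] with parameters `E0`, `dE` and
#' `log(K_A)`. Initialization: `E0` = first datum, `dE` = last - first,
#' `K_A = 2 / R_T`; box constraints `E0, dE` in `[-0.5, 1.5]` and `K_A > 0`
#' on the log scale. In the stoichiometric regime (protein binding much
#' tighter than `1/R_T`) the curve shape carries almost no information about
#' `K_A`; the fit therefore profiles `log(K_A)` and reports
#' `ka_identifiable = FALSE` when the residual sum of squares is flat within
#' a factor e^2 of the optimum.
#'
#' @param data a [fret_titration] with at least 4 points.
#' @param weights optional per-point weights (default unweighted).
#' @return object of class `fret_fit`: list with `E0`, `dE`, `K_A`, `se`
#'   (named vector, log scale for `K_A`), `fitted`, `residuals`, `rss`,
#'   `ka_identifiable`, `dE_degenerate`, `R_T`.
#' @export
fit_fret <- function(data, weights = NULL) {
  stopifnot(inherits(data, "fret_titration"))
  n <- length(data$P_T)
  if (n < 4L) stop("need >= 4 points to fit 3 parameters")
  w <- if (is.null(weights)) rep(1, n) else weights
  R_T <- data$R_T
  y <- data$E_FRET
  P <- data$P_T
  resid_fun <- function(par) {
    sqrt(w) * (y - efret_model(P, par[1], par[2], exp(par[3]), R_T))
  }
  start <- c(E0 = y[1], dE = y[n] - y[1], lkA = log(2 / R_T))
  lower <- c(-0.5, -0.5, log(1e-2 / R_T))
  upper <- c(1.5, 1.5, log(1e12 / R_T))
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-15, maxiter = 500))
  if (fit$info == 0 || fit$info == 9)
    stop("FRET fit did not converge (last iterate: ",
         paste(sprintf("%.4g", fit$par), collapse = ", "),
         "; residual norm ", sprintf("%.4g", sqrt(fit$deviance)), ")")
  par <- fit$par
  rss <- fit$deviance
  s2 <- max(rss / max(n - 3L, 1L), .Machine$double.eps)
  # profile log(K_A) +- 2 with E0, dE refit
  profile_rss <- function(lka) {
    pf <- minpack.lm::nls.lm(par = start[1:2],
                             lower = lower[1:2], upper = upper[1:2],
                             fn = function(p2) sqrt(w) *
                               (y - efret_model(P, p2[1], p2[2], exp(lka), R_T)),
                             control = minpack.lm::nls.lm.control(
                               ftol = 1e-15, ptol = 1e-15, maxiter = 200))
    pf$deviance
  }
  up <- profile_rss(par[3] + 2)
  dn <- profile_rss(par[3] - 2)
  ka_identifiable <- ((up - rss) / s2 > 4) && ((dn - rss) / s2 > 4)
  dE_degenerate <- abs(par[2]) < 1e-3
  if (dE_degenerate) ka_identifiable <- FALSE
  se <- tryCatch({
    J <- fit$hessian  # nls.lm returns J'J approx of the hessian
    sqrt(diag(solve(J)) * s2)
  }, error = function(e) rep(NA_real_, 3))
  names(se) <- c("E0", "dE", "log_K_A")
  fitted <- efret_model(P, par[1], par[2], exp(par[3]), R_T)
  structure(list(E0 = unname(par[1]), dE = unname(par[2]),
                 K_A = unname(exp(par[3])), se = se, fitted = fitted,
                 residuals = y - fitted, rss = rss,
                 ka_identifiable = ka_identifiable,
                 dE_degenerate = dE_degenerate, R_T = R_T),
            class = "fret_fit")
}

#' @export
print.fret_fit <- function(x, ...) {
  cat(sprintf("<fret_fit> E0 = %.4f, dE = %.4f, K_A = %.3g M^-1 (%sidentifiable)\n",
              x$E0, x$dE, x$K_A, if (x$ka_identifiable) "" else "NOT "))
  invisible(x)
}

#' Construct an ITC experiment
#'
#' @param inj_vol injection volumes (litres), all `> 0`.
#' @param heats measured integrated heats per injection (cal); may be NULL
#'   when the object is used for simulation only.
#' @param cell_conc macromolecule (RNA) concentration in the cell (molar).
#' @param syringe_conc titrant (protein) concentration in the syringe (molar).
#' @param cell_vol working cell volume (litres), default `200e-6`.
#' @param temperature temperature (K), default 298.
#' @return object of class `itc_experiment`.
#' @export
itc_experiment <- function(inj_vol, heats = NULL, cell_conc, syringe_conc,
                           cell_vol = 200e-6, temperature = 298) {
  stopifnot(all(inj_vol > 0), cell_vol > 0, temperature > 0,
            cell_conc > 0, syringe_conc > 0)
  if (!is.null(heats)) stopifnot(length(heats) == length(inj_vol))
  if (sum(inj_vol) > cell_vol)
    stop("cumulative injected volume exceeds the cell volume")
  structure(list(inj_vol = as.numeric(inj_vol), heats = heats,
                 cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_vol = cell_vol, temperature = temperature),
            class = "itc_experiment")
}

#' Read an ITC injection series from TSV
#'
#' Columns `inj_vol_L`, `heat_cal`; cell/syringe concentrations, cell volume
#' and temperature are carried in header comments
#' `# cell_conc_M = ...`, `# syringe_conc_M = ...`, `# cell_vol_L = ...`,
#' `# temperature_K = ...`.
#'
#' @param path TSV file.
#' @return an [itc_experiment].
#' @export
read_itc_tsv <- function(path) {
  hdr <- grep("^#", readLines(path, n = 20L), value = TRUE)
  get <- function(key, default = NULL) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s*=\\s*[0-9.eE+-]+"), hdr))
    m <- unlist(m)
    if (length(m) == 0L) {
      if (is.null(default)) stop("header comment '# ", key, " = <value>' required")
      return(default)
    }
    as.numeric(sub(".*=\\s*", "", m[[1]]))
  }
  d <- read.delim(path, comment.char = "#")
  itc_experiment(d$inj_vol_L, d$heat_cal,
                 cell_conc = get("cell_conc_M"),
                 syringe_conc = get("syringe_conc_M"),
                 cell_vol = get("cell_vol_L", 200e-6),
                 temperature = get("temperature_K", 298))
}

#' Predicted heats for the one-set-of-sites ITC model
#'
#' Discrete displaced-volume bookkeeping: each injection of volume `dV`
#' mixes titrant into the cell and expels an equal volume of the mixed
#' content, so cell species are diluted by `V0 / (V0 + dV)` while titrant is
#' replenished from the syringe. After each injection the bound complex is
#' the physical root of the one-site quadratic with site concentration
#' `n * [M]`, and the injection heat is `dH * V0 * (C_i - C_{i-1} * V0 /
#' (V0 + dV_i))` -- the enthalpy of the complex newly formed in the cell.
#'
#' @param exp an [itc_experiment].
#' @param dH molar binding enthalpy (cal mol^-1).
#' @param K association constant (M^-1), `> 0`.
#' @param n stoichiometry (titrant bound per macromolecule).
#' @return numeric vector of predicted heats (cal), one per injection.
#' @export
itc_one_site_heats <- function(exp, dH, K, n) {
  stopifnot(inherits(exp, "itc_experiment"), is.finite(dH), is.finite(K),
            is.finite(n), K > 0)
  V0 <- exp$cell_vol
  Mt <- exp$cell_conc
  Xt <- 0
  Cb_prev <- 0
  q <- numeric(length(exp$inj_vol))
  for (i in seq_along(exp$inj_vol)) {
    dV <- exp$inj_vol[i]
    dil <- V0 / (V0 + dV)
    Mt <- Mt * dil
    Xt <- (Xt * V0 + exp$syringe_conc * dV) / (V0 + dV)
    sites <- n * Mt
    b <- sites + Xt + 1 / K
    disc <- max(b^2 - 4 * sites * Xt, 0)
    Cb <- 2 * sites * Xt / (b + sqrt(disc))
    q[i] <- dH * V0 * (Cb - Cb_prev * dil)
    Cb_prev <- Cb
  }
  q
}

# Gas constant used for derived thermodynamics, cal mol^-1 K^-1.
R_GAS_CAL <- 1.9872

#' Fit the one-set-of-sites model to an ITC experiment
#'
#' Least-squares fit of [itc_one_site_heats()] in (`dH`, `log K`, `n`); the
#' first injection (small pre-injection) is excluded by default. Derived
#' quantities use `dG = -R T ln K` (R = 1.9872 cal mol^-1 K^-1),
#' `dS = (dH - dG) / T` and `Kd = 1/K`.
#'
#' @param exp an [itc_experiment] with measured heats and >= 5 injections.
#' @param drop_first exclude the first injection from the fit (default TRUE).
#' @return object of class `itc_fit`: `dH` (cal mol^-1), `K` (M^-1), `n`,
#'   `dG`, `dS`, `Kd`, `temperature`, `se`, `fitted` (all injections),
#'   `residuals` (fitted injections), `rss`.
#' @export
fit_itc <- function(exp, drop_first = TRUE) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (is.null(exp$heats)) stop("experiment carries no measured heats")
  if (length(exp$inj_vol) < 5L) stop("need >= 5 injections")
  use <- if (drop_first) -1L else seq_along(exp$heats)
  y <- exp$heats[use]
  resid_fun <- function(par) {
    q <- itc_one_site_heats(exp, par[1], exp(par[2]), par[3])
    y - q[use]
  }
  tot <- sum(exp$heats)
  dH0 <- tot / (exp$cell_conc * exp$cell_vol)   # ~ n*dH at saturation
  start <- c(dH = dH0, lK = log(10 / exp$cell_conc), n = 1)
  fit <- minpack.lm::nls.lm(par = start,
                            lower = c(-Inf, log(1e2), 0.05),
                            upper = c(Inf, log(1e12), 20),
                            fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-15, maxiter = 1000))
  if (fit$info == 0 || fit$info == 9)
    stop("ITC fit did not converge (last iterate: ",
         paste(sprintf("%.4g", fit$par), collapse = ", "),
         "; residual norm ", sprintf("%.4g", sqrt(fit$deviance)), ")")
  par <- fit$par
  K <- unname(exp(par[2]))
  T <- exp$temperature
  dG <- -R_GAS_CAL * T * log(K)
  s2 <- max(fit$deviance / max(length(y) - 3L, 1L), .Machine$double.eps)
  se <- tryCatch(sqrt(diag(solve(fit$hessian)) * s2),
                 error = function(e) rep(NA_real_, 3))
  names(se) <- c("dH", "log_K", "n")
  fitted <- itc_one_site_heats(exp, par[1], K, par[3])
  structure(list(dH = unname(par[1]), K = K, n = unname(par[3]),
                 dG = dG, dS = (unname(par[1]) - dG) / T, Kd = 1 / K,
                 temperature = T, se = se, fitted = fitted,
                 residuals = y - fitted[use], rss = fit$deviance),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("<itc_fit> dH = %.3g cal/mol, K = %.3g M^-1, n = %.3f | dG = %.3g, dS = %.3g, Kd = %.3g M\n",
              x$dH, x$K, x$n, x$dG, x$dS, x$Kd))
  invisible(x)
}
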