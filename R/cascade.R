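## Receptor occupancy, the Gs -> adenylyl cyclase -> cAMP kinetic cascade,
## and Hill-fit dose-response summaries.
##
## Receptor-ligand binding is treated at quasi-equilibrium: the occupied
## fraction is the equilibrium L/(L + Kd) (two-ligand competition in
## antagonist mode), held constant during each simulation. The cascade is
## a minimal mass-action Gs branch:
##
##   dG*/dt   = k_G_act * R_occ_active * G  -  k_G_hyd * G*
##   dcAMP/dt = k_basal + k_AC_cat * G* * ATP  -  k_PDE * cAMP
##   dATP/dt  = -k_AC_cat * G* * ATP            (optional depletion)
##
## with G = G_total - G* and k_basal = k_PDE * cAMP_basal so that the
## zero-occupancy state is a fixed point at the basal cAMP level. The rate
## constants are exposed placeholders, not fits to A2A data: the simulation
## ranks ligands by the structure of the response (potency shifts,
## saturation), not by absolute cAMP values.

#' Affinity record from pKd
#'
#' @param pKd dimensionless `-log10(Kd)` with Kd in molar.
#' @return list with `pKd`, `Kd_molar` and `Kd_uM`.
#' @export
affinity <- function(pKd) {
  if (!is.finite(pKd)) stop_fmt("pKd must be finite")
  list(pKd = pKd, Kd_molar = 10^(-pKd), Kd_uM = 10^(6 - pKd))
}

#' Equilibrium receptor occupancy
#'
#' `L / (L + Kd)`: the fraction of receptors bound by ligand at
#' equilibrium.
#'
#' @param aff an [affinity()] (or a bare pKd).
#' @param ligand_conc_uM ligand concentration(s) in micromolar, `>= 0`.
#' @return occupancy fraction(s) in `[0, 1]`.
#' @export
occupancy <- function(aff, ligand_conc_uM) {
  if (is.numeric(aff)) aff <- affinity(aff)
  if (any(ligand_conc_uM < 0)) stop_fmt("ligand concentration must be >= 0")
  ligand_conc_uM / (ligand_conc_uM + aff$Kd_uM)
}

#' Two-ligand competitive occupancy
#'
#' Standard competition at equilibrium for a ligand and a reference
#' agonist sharing the orthosteric site.
#'
#' @param aff_ligand,aff_agonist [affinity()] records (or bare pKd values).
#' @param L,A ligand and agonist concentrations in micromolar, `>= 0`.
#' @return list with `ligand_bound` and `agonist_bound` fractions; the
#'   free fraction is `1 - ligand_bound - agonist_bound`.
#' @export
competitive_occupancy <- function(aff_ligand, aff_agonist, L, A) {
  if (is.numeric(aff_ligand)) aff_ligand <- affinity(aff_ligand)
  if (is.numeric(aff_agonist)) aff_agonist <- affinity(aff_agonist)
  if (any(L < 0) || any(A < 0)) stop_fmt("concentrations must be >= 0")
  if (aff_ligand$Kd_uM == 0 && aff_agonist$Kd_uM == 0)
    stop_fmt("both Kd values are zero")
  denom <- 1 + L / aff_ligand$Kd_uM + A / aff_agonist$Kd_uM
  list(ligand_bound = (L / aff_ligand$Kd_uM) / denom,
       agonist_bound = (A / aff_agonist$Kd_uM) / denom)
}

#' Cascade parameters
#'
#' Concentrations in micromolar, first-order rates in 1/s, second-order
#' rates in 1/(uM s). The defaults use the 2 uM receptor concentration of
#' the reference simulations; every constant is configurable.
#'
#' @param receptor_total total receptor concentration (uM).
#' @param G_total total G protein (uM).
#' @param ATP_total ATP pool (uM).
#' @param cAMP_basal basal cAMP level (uM); basal synthesis is set to
#'   balance degradation at this level.
#' @param k_G_act G-protein activation rate per occupied receptor
#'   (1/(uM s)).
#' @param k_G_hyd G* hydrolysis rate (1/s).
#' @param k_AC_cat adenylyl-cyclase catalytic rate (1/(uM s)).
#' @param k_PDE phosphodiesterase degradation rate (1/s).
#' @param deplete_atp whether cAMP synthesis consumes the ATP pool.
#' @param agonist_tone reference agonist for antagonist mode: list with
#'   `pKd` and `conc_uM` (default: pKd 7 agonist at its EC80, 4 x Kd).
#' @return list of class `cascade_parameters`.
#' @export
cascade_parameters <- function(receptor_total = 2,
                               G_total = 10,
                               ATP_total = 5000,
                               cAMP_basal = 0.05,
                               k_G_act = 0.5,
                               k_G_hyd = 0.1,
                               k_AC_cat = 1e-4,
                               k_PDE = 0.5,
                               deplete_atp = TRUE,
                               agonist_tone = list(pKd = 7, conc_uM = 4 * 10^(6 - 7))) {
  p <- list(receptor_total = receptor_total, G_total = G_total,
            ATP_total = ATP_total, cAMP_basal = cAMP_basal,
            k_G_act = k_G_act, k_G_hyd = k_G_hyd, k_AC_cat = k_AC_cat,
            k_PDE = k_PDE, deplete_atp = isTRUE(deplete_atp),
            agonist_tone = agonist_tone)
  conc <- unlist(p[c("receptor_total", "G_total", "ATP_total", "cAMP_basal")])
  rates <- unlist(p[c("k_G_act", "k_G_hyd", "k_AC_cat", "k_PDE")])
  if (any(conc < 0)) stop_fmt("concentrations must be >= 0")
  if (any(rates < 0)) stop_fmt("rate constants must be >= 0")
  structure(p, class = "cascade_parameters")
}

#' Log-spaced dose grid
#'
#' @param from,to grid bounds in micromolar (defaults 1e-3 to 1e3).
#' @param n number of points (default 24).
#' @return strictly increasing vector of doses in uM.
#' @export
dose_grid <- function(from = 1e-3, to = 1e3, n = 24L) {
  if (from <= 0 || to <= from) stop_fmt("need 0 < from < to")
  10^seq(log10(from), log10(to), length.out = n)
}

#' Simulate the cAMP time course at one occupancy level
#'
#' @param params [cascade_parameters()].
#' @param occupied_fraction fraction of receptors bound by *agonist*
#'   (activating occupancy), held at its equilibrium value.
#' @param t_end simulated time (s).
#' @param n_steps number of output steps over the window (default 1000).
#' @param cAMP0 initial cAMP (defaults to the basal level).
#' @return data.frame: `time`, `G_active`, `cAMP`, `ATP`.
#' @export
simulate_cascade <- function(params, occupied_fraction, t_end = 300,
                             n_steps = 1000L, cAMP0 = NULL) {
  stopifnot(inherits(params, "cascade_parameters"))
  if (occupied_fraction < 0 || occupied_fraction > 1)
    stop_fmt("occupied fraction must lie in [0, 1]")
  if (t_end <= 0) stop_fmt("t_end must be positive")
  R_occ <- params$receptor_total * occupied_fraction
  k_basal <- params$k_PDE * params$cAMP_basal
  state <- c(Gs = 0,
             cAMP = cAMP0 %||% params$cAMP_basal,
             ATP = params$ATP_total)
  deriv <- function(t, y, p) {
    dGs <- params$k_G_act * R_occ * (params$G_total - y["Gs"]) -
      params$k_G_hyd * y["Gs"]
    synth <- params$k_AC_cat * y["Gs"] * y["ATP"]
    dcAMP <- k_basal + synth - params$k_PDE * y["cAMP"]
    dATP <- if (params$deplete_atp) -synth else 0
    list(c(dGs, dcAMP, dATP))
  }
  times <- seq(0, t_end, length.out = n_steps + 1)
  out <- deSolve::lsoda(state, times, deriv, NULL, rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1] < 0) stop_fmt("cascade integration failed to converge")
  data.frame(time = out[, "time"], G_active = out[, "Gs"],
             cAMP = out[, "cAMP"], ATP = out[, "ATP"])
}

#' Dose-response curve over a concentration grid
#'
#' One quasi-equilibrium cascade simulation per dose; the response is the
#' change in end-time cAMP versus the zero-dose baseline. In agonist mode
#' the ligand itself activates; in antagonist mode the ligand competes
#' against a fixed reference agonist tone and the response is the
#' (negative) loss of cAMP.
#'
#' @param params [cascade_parameters()] (antagonist mode requires
#'   `agonist_tone`).
#' @param aff ligand [affinity()] (or bare pKd).
#' @param grid doses in uM from [dose_grid()].
#' @param mode `"agonist"` or `"antagonist"`.
#' @param t_end,n_steps passed to [simulate_cascade()].
#' @return list of class `dose_response_curve`: `dose_uM`, `response_uM`,
#'   `mode`, `hill` (the [fit_hill()] summary), simulation metadata.
#' @export
dose_response <- function(params, aff, grid = dose_grid(),
                          mode = c("agonist", "antagonist"),
                          t_end = 300, n_steps = 1000L) {
  mode <- match.arg(mode)
  if (is.numeric(aff)) aff <- affinity(aff)
  if (any(diff(grid) <= 0) || any(grid <= 0))
    stop_fmt("dose grid must be strictly increasing and positive")
  if (mode == "antagonist" && is.null(params$agonist_tone))
    stop_fmt("antagonist mode requires an agonist_tone in the parameters")
  end_cAMP <- function(occ) {
    tc <- simulate_cascade(params, occ, t_end = t_end, n_steps = n_steps)
    tc$cAMP[nrow(tc)]
  }
  occ_at <- function(L) {
    if (mode == "agonist") occupancy(aff, L)
    else competitive_occupancy(aff, affinity(params$agonist_tone$pKd),
                               L, params$agonist_tone$conc_uM)$agonist_bound
  }
  baseline <- end_cAMP(occ_at(0))
  response <- vapply(grid, function(L) end_cAMP(occ_at(L)) - baseline, 0)
  curve <- structure(list(dose_uM = grid, response_uM = response, mode = mode,
                          pKd = aff$pKd, t_end = t_end, n_steps = n_steps,
                          baseline_cAMP = baseline),
                     class = "dose_response_curve")
  curve$hill <- fit_hill(curve)
  curve
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> %s mode, pKd %.2f, %d doses [%g, %g] uM\n",
              x$mode, x$pKd, length(x$dose_uM), min(x$dose_uM), max(x$dose_uM)))
  h <- x$hill
  if (isTRUE(h$degenerate)) cat("  flat curve: degenerate Hill fit\n")
  else cat(sprintf("  Hill fit: x50 = %.4g uM, n = %.2f, span [%.3g, %.3g] uM%s\n",
                   h$x50_uM, h$hill_n, h$bottom, h$top,
                   if (isTRUE(h$unreliable)) " (x50 outside dose grid)" else ""))
  invisible(x)
}

#' @export
plot.dose_response_curve <- function(x, ...) {
  graphics::plot(x$dose_uM, x$response_uM, log = "x", type = "b", pch = 16,
                 xlab = "dose (uM)", ylab = "cAMP change (uM)",
                 main = sprintf("%s dose-response (pKd %.2f)", x$mode, x$pKd), ...)
  if (!isTRUE(x$hill$degenerate))
    graphics::abline(v = x$hill$x50_uM, lty = 2, col = "grey40")
  invisible(x)
}

#' Four-parameter Hill fit of a dose-response curve
#'
#' Least-squares fit of `response = bottom + (top - bottom) /
#' (1 + (x50 / dose)^n)`. The midpoint is an EC50 for rising curves and an
#' IC50 for falling ones. The fit is flagged unreliable when the midpoint
#' falls outside the dose grid and degenerate when the curve is flat.
#'
#' @param curve a `dose_response_curve`, or a list/data.frame with
#'   `dose_uM` and `response_uM` (>= 5 points).
#' @return list: `top`, `bottom`, `x50_uM`, `hill_n`, `degenerate`,
#'   `unreliable`.
#' @export
fit_hill <- function(curve) {
  x <- curve$dose_uM; y <- curve$response_uM
  if (length(x) < 5) stop_fmt("need at least 5 dose points")
  span <- diff(range(y))
  if (span < 1e-9 * max(1, max(abs(y))) || span == 0)
    return(list(top = NA_real_, bottom = NA_real_, x50_uM = NA_real_,
                hill_n = NA_real_, degenerate = TRUE, unreliable = TRUE))
  rising <- y[length(y)] >= y[1]
  b0 <- if (rising) min(y) else max(y)
  t0 <- if (rising) max(y) else min(y)
  half <- (b0 + t0) / 2
  x50_0 <- x[which.min(abs(y - half))]
  model <- function(par) par[1] + (par[2] - par[1]) / (1 + (exp(par[3]) / x)^par[4])
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(bottom = b0, top = t0, lx50 = log(x50_0), n = 1),
      fn = function(par) y - model(par),
      lower = c(-Inf, -Inf, log(min(x)) - 12, 0.05),
      upper = c(Inf, Inf, log(max(x)) + 12, 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4)
    return(list(top = NA_real_, bottom = NA_real_, x50_uM = NA_real_,
                hill_n = NA_real_, degenerate = TRUE, unreliable = TRUE))
  cf <- fit$par
  x50 <- exp(cf[["lx50"]])
  list(top = cf[["top"]], bottom = cf[["bottom"]], x50_uM = x50,
       hill_n = cf[["n"]], degenerate = FALSE,
       unreliable = x50 < min(x) || x50 > max(x))
}

#' Affinity gate
#'
#' Retains candidates whose predicted pKd is at or above the cutoff
#' (boundary inclusive). pKd 5.5 corresponds to Kd = 10^-5.5 M, about
#' 3.16 uM; the cutoff is configurable.
#'
#' @param candidates data.frame with a `pKd` column.
#' @param min_pKd minimum retained pKd (default 5.5).
#' @return the retained rows, order preserved; warns when empty.
#' @export
affinity_gate <- function(candidates, min_pKd = 5.5) {
  if (is.null(candidates$pKd) || any(is.na(candidates$pKd))) {
    bad <- if (is.null(candidates$pKd)) "all" else
      paste(candidates$id[is.na(candidates$pKd)], collapse = ", ")
    stop_fmt("missing pKd for candidate(s): %s", bad)
  }
  out <- candidates[candidates$pKd >= min_pKd, , drop = FALSE]
  if (!nrow(out)) warn_fmt("affinity gate at pKd >= %.2f retained no candidates", min_pKd)
  out
}
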