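# Gas-fermentation physiology arithmetic: N2-referenced gas rates, specific
# rates, yields, substrate:product stoichiometry, growth rate / doubling time,
# and carbon balance for steady-state chemostat and batch cultures.
#
# Sign convention throughout: specific rates q are positive for uptake and
# negative for production (so q_H2 < 0 on CO means net H2 production via the
# biological water-gas shift).

#' Physiology parameters
#'
#' @param mAcetate molar mass of acetate in g mol^-1 (default 60.05).
#' @param carbonAtoms named integer vector of carbon atoms per species.
#' @param biomassGPerCmol grams of dry biomass per C-mol (default 25.0, a
#'   standard CH1.8O0.5N0.2-type composition); configurable because measured
#'   elemental compositions vary and carbon balances depend on it.
#' @return A validated named list.
#' @export
physioParams <- function(mAcetate = 60.05,
                         carbonAtoms = c(CO = 1, CO2 = 1, acetate = 2, H2 = 0),
                         biomassGPerCmol = 25.0) {
  if (mAcetate <= 0 || biomassGPerCmol <= 0)
    mtxStop("invalid_parameter", "masses must be positive")
  list(mAcetate = mAcetate, carbonAtoms = carbonAtoms,
       biomassGPerCmol = biomassGPerCmol)
}

#' Specific gas rates from inlet/outlet GC compositions (N2-referenced)
#'
#' The off-gas volumetric flow is unknown because gas consumption changes it;
#' N2 is inert, so the outlet molar flow is recovered from the N2 mole-fraction
#' ratio: `outFlow = inFlow * yN2in / yN2out`. Specific rates are then
#' `q_i = (inFlow * y_i,in - outFlow * y_i,out) / (V * X)`, positive for
#' uptake; N2's own rate is exactly zero by construction, and the result is
#' invariant to any consistent rescaling of the outlet composition.
#'
#' @param inletFlow inlet molar flow in mmol h^-1.
#' @param inletFractions,outletFractions named mole-fraction vectors (must
#'   include `N2 > 0`; each stream sums to at most 1).
#' @param volume broth volume in L.
#' @param biomass biomass concentration X in g L^-1.
#' @return Named numeric vector of specific rates in mmol g^-1 h^-1 (uptake
#'   positive, production negative).
#' @examples
#' gasRatesFromGC(100, c(CO = 0.5, N2 = 0.5),
#'                c(CO = 0.2, CO2 = 0.3, N2 = 0.5), volume = 0.2, biomass = 1)
#' @export
gasRatesFromGC <- function(inletFlow, inletFractions, outletFractions,
                           volume, biomass) {
  for (v in list(inletFractions, outletFractions))
    if (any(v < 0) || sum(v) > 1 + 1e-9)
      mtxStop("invalid_input", "mole fractions must be >= 0 and sum to <= 1")
  yin <- inletFractions["N2"]; yout <- outletFractions["N2"]
  if (is.na(yin) || is.na(yout) || yout <= 0 || yin <= 0)
    mtxStop("invalid_input", "both streams need N2 > 0 (internal standard)")
  if (volume <= 0 || biomass <= 0)
    mtxStop("invalid_input", "volume and biomass must be positive")
  outFlow <- inletFlow * yin / yout
  species <- union(names(inletFractions), names(outletFractions))
  getf <- function(v, s) ifelse(is.na(v[s]), 0, v[s])
  q <- vapply(species, function(s)
    (inletFlow * getf(inletFractions, s) - outFlow * getf(outletFractions, s)) /
      (volume * biomass), numeric(1))
  q["N2"] <- 0
  q
}

#' Specific acetate production rate at steady state
#'
#' In a chemostat at dilution rate D with no acetate in the feed, the specific
#' production rate is `q_Ace = 1000 * D * c_Ace / (M_acetate * X)` in
#' mmol g^-1 h^-1 (positive as printed in steady-state tables).
#'
#' @param D dilution rate in h^-1.
#' @param acetate acetate concentration c_Ace in g L^-1.
#' @param biomass biomass X in g L^-1.
#' @param params a [physioParams()] list.
#' @return q_Ace in mmol g^-1 h^-1.
#' @examples
#' specificAcetateRate(0.20, 2.12, 0.26)  # ~27.2
#' @export
specificAcetateRate <- function(D, acetate, biomass, params = physioParams()) {
  if (any(biomass <= 0)) mtxStop("invalid_input", "biomass must be > 0")
  if (any(D <= 0)) mtxStop("invalid_input", "D must be > 0")
  if (any(acetate < 0)) mtxStop("invalid_input", "acetate must be >= 0")
  1000 * D * acetate / (params$mAcetate * biomass)
}

#' Acetate yield per biomass
#'
#' `Y_Ace/Biomass = c_Ace / (M_acetate * X)` in mol g^-1, reported to 2
#' decimals.
#'
#' @inheritParams specificAcetateRate
#' @return Yield in mol acetate per g biomass (2 decimals).
#' @examples
#' yieldAcetatePerBiomass(2.18, 0.24)  # 0.15
#' @export
yieldAcetatePerBiomass <- function(acetate, biomass, params = physioParams()) {
  if (any(biomass <= 0)) mtxStop("invalid_input", "biomass must be > 0")
  round(acetate / (params$mAcetate * biomass), 2L)
}

#' Biomass yield on a gas substrate
#'
#' `Y_Biomass/S = 1000 * D / q_S` in g mol^-1, defined only while the
#' substrate is being net-consumed (q_S > 0).
#'
#' @param D dilution rate in h^-1.
#' @param qSubstrate specific uptake rate of the substrate in mmol g^-1 h^-1
#'   (uptake positive).
#' @return Yield in g biomass per mol substrate.
#' @examples
#' yieldBiomassPerSubstrate(0.20, 122.2)  # 1.64
#' @export
yieldBiomassPerSubstrate <- function(D, qSubstrate) {
  if (any(qSubstrate <= 0))
    mtxStop("invalid_input",
             "substrate is not being consumed (q <= 0); yield undefined")
  1000 * D / qSubstrate
}

#' Substrate consumed per acetate formed
#'
#' Stoichiometric ratio `q_S / q_Ace`, reported to 1 decimal. Homoacetogenic
#' stoichiometry predicts 4 CO (or 4 H2 + 2 CO2) per acetate; carboxydotrophic
#' growth with high biomass yield shows elevated CO demand (~5.5 per acetate).
#'
#' @param qSubstrate specific substrate uptake rate (mmol g^-1 h^-1, > 0 for
#'   a meaningful ratio; sign is kept).
#' @param qAce specific acetate production rate (> 0).
#' @return Ratio, 1 decimal.
#' @examples
#' substratePerAcetate(80.0, 14.6)  # 5.5
#' @export
substratePerAcetate <- function(qSubstrate, qAce) {
  if (any(qAce <= 0)) mtxStop("invalid_input", "qAce must be > 0")
  round(qSubstrate / qAce, 1L)
}

#' Carbon balance of a steady state
#'
#' Percentage of consumed substrate carbon recovered in products plus biomass:
#' `100 * (sum_production |q_i| nC_i + q_Ace * 2 + 1000 * D / biomassGPerCmol)
#' / (sum_uptake q_i nC_i)`, using the signed-q convention (gas uptake
#' positive, production negative; q_Ace positive as printed). The biomass term
#' converts the specific biomass production rate D (g g^-1 h^-1) to C-mmol
#' through the configurable biomass carbon mass.
#'
#' @param qGas named vector of signed specific gas rates (subset of
#'   `CO`, `CO2`, `H2`), mmol g^-1 h^-1.
#' @param qAce specific acetate production rate (positive), mmol g^-1 h^-1.
#' @param D dilution rate in h^-1.
#' @param params a [physioParams()] list.
#' @return Carbon balance in percent (1 decimal).
#' @examples
#' carbonBalance(c(CO = 80.0, CO2 = -47.0, H2 = -16.7), qAce = 14.6, D = 0.10)
#' @export
carbonBalance <- function(qGas, qAce, D, params = physioParams()) {
  nC <- params$carbonAtoms[names(qGas)]
  if (anyNA(nC))
    mtxStop("invalid_input", "unknown species in qGas: %s",
            paste(names(qGas)[is.na(nC)], collapse = ", "))
  uptakeC <- sum(pmax(qGas, 0) * nC)
  if (uptakeC <= 0)
    mtxStop("invalid_input", "no net carbon uptake; balance undefined")
  prodC <- sum(pmax(-qGas, 0) * nC) + qAce * params$carbonAtoms[["acetate"]] +
    1000 * D / params$biomassGPerCmol
  round(100 * prodC / uptakeC, 1L)
}

#' Growth rate and doubling time from an OD time course
#'
#' Fits `ln(OD) ~ time` by least squares inside the exponential-phase window;
#' the slope is the specific growth rate mu (h^-1) and the doubling time is
#' `ln(2) / mu` (reported to 1 decimal).
#'
#' @param time time points in h (strictly increasing).
#' @param od OD values (> 0 inside the window).
#' @param window `c(tStart, tEnd)` fit window in h (default: all points).
#' @return List with `mu` (h^-1), `doublingTime` (h, 1 decimal), `n` points
#'   used, and the `fit` lm object.
#' @examples
#' t <- 0:8
#' growthRate(t, 0.1 * exp(0.25 * t))  # mu = 0.25, Td = 2.8
#' @export
growthRate <- function(time, od, window = range(time)) {
  if (is.unsorted(time, strictly = TRUE))
    mtxStop("invalid_input", "time points must be strictly increasing")
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 3L)
    mtxStop("invalid_input", "need >= 3 points inside the fit window")
  if (any(od[sel] <= 0))
    mtxStop("invalid_input", "OD must be positive inside the fit window")
  fit <- lm(log(od[sel]) ~ time[sel])
  mu <- unname(coef(fit)[2L])
  list(mu = mu, doublingTime = round(log(2) / mu, 1L), n = sum(sel), fit = fit)
}

#' Doubling time from a growth rate
#'
#' @param mu specific growth rate in h^-1 (> 0).
#' @return `ln(2)/mu` in h, 1 decimal.
#' @examples
#' doublingTime(0.25)  # 2.8
#' doublingTime(0.12)  # 5.8
#' @export
doublingTime <- function(mu) {
  if (any(mu <= 0)) mtxStop("invalid_input", "mu must be > 0")
  round(log(2) / mu, 1L)
}

#' Steady-state physiology report
#'
#' Computes the derived quantities of a steady-state table row by row:
#' q_Ace, Y_Ace/Biomass, Y_Biomass/S on the declared substrate, the
#' substrate:acetate ratio, and the carbon balance.
#'
#' @param table data.frame with columns `D`, `biomass`, `acetate`, signed
#'   `qH2`, `qCO2`, `qCO` (any may be NA when not measured), and `substrate`
#'   (`"CO"`, `"H2"` or `"CO2"`; names the yield/stoichiometry substrate).
#' @param params a [physioParams()] list.
#' @return The input with appended columns `qAce`, `yAcePerBiomass`,
#'   `yBiomassPerS`, `substratePerAcetate`, `cBalance`.
#' @export
steadyStateReport <- function(table, params = physioParams()) {
  need <- c("D", "biomass", "acetate", "substrate")
  if (!all(need %in% names(table)))
    mtxStop("invalid_input", "missing columns: %s",
            paste(setdiff(need, names(table)), collapse = ", "))
  n <- nrow(table)
  qAce <- yab <- ybs <- spa <- cb <- numeric(n)
  for (i in seq_len(n)) {
    qAce[i] <- specificAcetateRate(table$D[i], table$acetate[i],
                                   table$biomass[i], params)
    yab[i] <- yieldAcetatePerBiomass(table$acetate[i], table$biomass[i], params)
    qGas <- c(H2 = table$qH2[i], CO2 = table$qCO2[i], CO = table$qCO[i])
    qGas <- qGas[!is.na(qGas)]
    qs <- qGas[table$substrate[i]]
    ybs[i] <- if (!is.na(qs) && qs > 0)
      yieldBiomassPerSubstrate(table$D[i], unname(qs)) else NA_real_
    spa[i] <- if (!is.na(qs) && qs > 0 && qAce[i] > 0)
      substratePerAcetate(unname(qs), qAce[i]) else NA_real_
    cb[i] <- if (length(qGas) && any(qGas > 0))
      carbonBalance(qGas, qAce[i], table$D[i], params) else NA_real_
  }
  table$qAce <- qAce
  table$yAcePerBiomass <- yab
  table$yBiomassPerS <- ybs
  table$substratePerAcetate <- spa
  table$cBalance <- cb
  table
}

#' Read a steady-state table from TSV
#'
#' Expects a header with the [steadyStateReport()] column names.
#'
#' @param path TSV file.
#' @return A data.frame.
#' @export
readSteadyStates <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
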