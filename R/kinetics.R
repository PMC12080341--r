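## Sticky-end hybridization thermodynamics and bridge rate constants.
##
## The unbinding rate of a single DNA bridge and the binding rate of one
## free receptor with one free ligand under the adhesion disk are
##     k_off = alpha * kOnSol * rho0 * exp(dG0 / kBT)
##     k_on  = alpha * kOnSol * cEff,   cEff = [1 / (3 pi R^2 L)] in molar,
## i.e. the free sticky end of an unbound receptor is treated as uniformly
## distributed in the hemispherical shell of area 3 pi R^2 and thickness L.

## Unified oligonucleotide nearest-neighbor parameters, 1 M NaCl.
## dH in kcal/mol, dS in cal/(mol K); keys are the 5'->3' top-strand doublet.
.nnTable <- local({
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
          CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  ## complete by self-complementarity: XY == complement(YX) read 5'->3'
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  full <- expand.grid(a = names(comp), b = names(comp),
                      stringsAsFactors = FALSE)
  keys <- paste0(full$a, full$b)
  rc <- vapply(keys, function(k) {
    s <- strsplit(k, "")[[1]]
    paste0(comp[s[2]], comp[s[1]])
  }, character(1))
  H <- S <- setNames(numeric(length(keys)), keys)
  for (k in keys) {
    H[k] <- if (k %in% names(dH)) dH[[k]] else dH[[rc[[k]]]]
    S[k] <- if (k %in% names(dS)) dS[[k]] else dS[[rc[[k]]]]
  }
  ## duplex initiation with one terminal G.C or A.T pair
  list(dH = H, dS = S,
       initGC = c(dH = 0.1, dS = -2.8),
       initAT = c(dH = 2.3, dS = 4.1))
})

.checkSequence <- function(sequence) {
  if (is(sequence, "DNAString") || is(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)[1]
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a single non-empty DNA string")
  s <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!s %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d of sticky-end sequence",
                 s[bad[1]], bad[1]))
  if (length(s) < 2)
    stop("sticky end must have at least 2 nucleotides (no stack defined)")
  s
}

#' Nearest-neighbor thermodynamics of a sticky-end duplex
#'
#' Evaluates the hybridization enthalpy, entropy and free energy of the
#' perfect duplex formed by a sticky end and its complement, using the
#' unified oligonucleotide nearest-neighbor parameter set (stacking doublets
#' plus terminal initiation terms, tabulated at 1 M Na+) with the entropic
#' salt correction \eqn{\Delta S[Na^+] = \Delta S[1M] + 0.368 (N-1)
#' \ln[Na^+]} for \eqn{N} base pairs. Dangling-end and tethering
#' contributions are deliberately excluded: those kinetic effects are
#' absorbed by the dimensionless slowdown factor alpha of the rate model.
#'
#' @param sequence DNA string (character or \code{Biostrings::DNAString}),
#'   5' to 3'; its perfect complement is implied.
#' @param temperature temperature in kelvin (default 293.15).
#' @param sodium monovalent salt concentration in molar (default 0.1,
#'   i.e. 100 mM NaCl).
#' @return \code{nnThermodynamics}: list with \code{dH_kcal} (kcal/mol),
#'   \code{dS_cal} (cal/mol/K, salt-corrected), \code{dG_kcal} (kcal/mol at
#'   \code{temperature}) and \code{dG_kT} (same, in units of kBT).
#'   \code{nnFreeEnergy}: just \code{dG_kT}.
#' @examples
#' nnFreeEnergy("ACGTG")
#' @export
nnThermodynamics <- function(sequence, temperature = 293.15, sodium = 0.1) {
  s <- .checkSequence(sequence)
  if (temperature <= 0) stop("temperature must be positive (K)")
  if (sodium <= 0) stop("sodium concentration must be positive (M)")
  n <- length(s)
  doublets <- paste0(s[-n], s[-1])
  dH <- sum(.nnTable$dH[doublets])
  dS <- sum(.nnTable$dS[doublets])
  for (end in s[c(1, n)]) {
    init <- if (end %in% c("G", "C")) .nnTable$initGC else .nnTable$initAT
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  dS <- dS + 0.368 * (n - 1) * log(sodium)
  dG_kcal <- dH - temperature * dS / 1000
  list(dH_kcal = dH, dS_cal = dS, dG_kcal = dG_kcal,
       dG_kT = dG_kcal / (.Rgas * temperature))
}

#' @rdname nnThermodynamics
#' @export
nnFreeEnergy <- function(sequence, temperature = 293.15, sodium = 0.1) {
  nnThermodynamics(sequence, temperature, sodium)$dG_kT
}

#' Construct kinetic parameters for the bridge rate model
#'
#' @param deltaG0 standard hybridization free energy in kBT (negative =
#'   binding). Supply either this, a \code{sequence}, or a \code{kOff}.
#' @param sequence optional sticky-end sequence from which \code{deltaG0} is
#'   computed with \code{\link{nnFreeEnergy}}.
#' @param kOff optional unbinding rate (s^-1) from which \code{deltaG0} is
#'   back-computed via the rate model.
#' @param alpha dimensionless tethering slowdown factor in (0, 1].
#' @param kOnSol solution hybridization rate, M^-1 s^-1.
#' @param L spacer length, nm.
#' @param temperature kelvin.
#' @param sodium molar Na+ for the sequence route.
#' @return a \linkS4class{KineticParameters} object.
#' @export
kineticParameters <- function(deltaG0 = NULL, sequence = NULL, kOff = NULL,
                              alpha = 0.1, kOnSol = 1e6, L = 10,
                              temperature = 293.15, sodium = 0.1) {
  supplied <- c(!is.null(deltaG0), !is.null(sequence), !is.null(kOff))
  if (sum(supplied) != 1)
    stop("supply exactly one of deltaG0, sequence or kOff")
  if (!is.null(sequence))
    deltaG0 <- nnFreeEnergy(sequence, temperature, sodium)
  if (!is.null(kOff)) {
    if (kOff <= 0) stop("kOff must be positive")
    deltaG0 <- log(kOff / (alpha * kOnSol * 1))
  }
  new("KineticParameters", deltaG0 = deltaG0, alpha = alpha, kOnSol = kOnSol,
      L = L, rho0 = 1, temperature = temperature)
}

## Printed unbinding rates for the three sticky-end lengths studied (s^-1),
## with alpha = 0.1, kOnSol = 1e6 /M/s, L = 10 nm, T = 293.15 K.
.presetKOff <- c(l5 = 1.10, l6 = 0.174, l7 = 0.0084)

#' Named kinetic presets for sticky-end lengths 5, 6 and 7 nt
#'
#' Returns a \linkS4class{KineticParameters} object whose free energy is
#' back-computed from the reference unbinding rates 1.10, 0.174 and
#' 0.0084 s^-1 for presets "l5", "l6" and "l7", so the engine can be driven
#' without sequence input.
#'
#' @param name one of "l5", "l6", "l7".
#' @param alpha,kOnSol,L,temperature as in \code{\link{kineticParameters}}.
#' @export
kineticPreset <- function(name = c("l5", "l6", "l7"), alpha = 0.1,
                          kOnSol = 1e6, L = 10, temperature = 293.15) {
  name <- match.arg(name)
  kineticParameters(kOff = .presetKOff[[name]], alpha = alpha,
                    kOnSol = kOnSol, L = L, temperature = temperature)
}

#' Effective concentration of one free sticky end under the disk
#'
#' One free sticky end uniformly distributed in the hemispherical shell of
#' area 3 pi R^2 and thickness L has number density 1/(3 pi R^2 L) nm^-3;
#' this converts it to molar.
#'
#' @param R disk radius, nm.
#' @param L shell thickness (spacer length), nm.
#' @return molar concentration.
#' @export
effectiveConcentration <- function(R, L) {
  if (any(R <= 0) || any(L <= 0)) stop("R and L must be positive")
  (1 / (3 * pi * R^2 * L)) * 1e24 / .avogadro
}

#' Bridge unbinding rate
#'
#' \eqn{k_{off} = \alpha k_{on}^{sol} \rho_0 e^{\beta \Delta G_0}};
#' independent of disk radius and spacer length.
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @return s^-1.
#' @export
offRate <- function(params) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  params@alpha * params@kOnSol * params@rho0 * exp(params@deltaG0)
}

#' Per-pair bridge formation rate
#'
#' \eqn{k_{on} = \alpha k_{on}^{sol} c_{eff}} with \eqn{c_{eff}} the molar
#' concentration of a single free sticky end in the shell around the
#' hemisphere (\code{\link{effectiveConcentration}}); scales as 1/R^2.
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @param R disk radius, nm.
#' @return s^-1.
#' @export
onRatePerPair <- function(params, R) {
  stopifnot(is(params, "KineticParameters"))
  validObject(params)
  if (any(R <= 0)) stop("R must be positive")
  params@alpha * params@kOnSol * effectiveConcentration(R, params@L)
}

#' Bundle realized rate constants for a given disk radius
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @param R disk radius, nm.
#' @return a \linkS4class{RateConstants} object.
#' @export
rateConstants <- function(params, R) {
  new("RateConstants", kOnPair = onRatePerPair(params, R),
      kOff = offRate(params),
      cEff = effectiveConcentration(R, params@L), R = R)
}

#' Read a sticky-end sequence from plain text or FASTA
#'
#' Single-record FASTA (via Biostrings) or a bare one-line sequence file.
#'
#' @param path file path.
#' @return character sequence, 5' to 3'.
#' @export
readStickyEnd <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, ">")) {
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) != 1)
      stop("expected a single-record FASTA, found ", length(set), " records")
    as.character(set[[1]])
  } else {
    gsub("\\s", "", first)
  }
}

#' Full parameter echo for one kinetic condition
#'
#' JSON-ready list with the sticky-end length (if a sequence was given),
#' free energy in both kBT and kcal/mol, effective concentration and both
#' rate constants at radius \code{R}.
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @param R disk radius, nm.
#' @param sequence optional sequence for the echo.
#' @export
kineticsReport <- function(params, R, sequence = NULL) {
  rc <- rateConstants(params, R)
  out <- list(
    l = if (!is.null(sequence)) nchar(sequence) else NA_integer_,
    sequence = if (!is.null(sequence)) as.character(sequence) else NA_character_,
    deltaG0_kT = params@deltaG0,
    deltaG0_kcal_mol = params@deltaG0 * .Rgas * params@temperature,
    alpha = params@alpha, kOnSol_per_M_s = params@kOnSol,
    L_nm = params@L, temperature_K = params@temperature,
    cEff_M = rc@cEff, kOnPair_per_s = rc@kOnPair, kOff_per_s = rc@kOff,
    R_nm = R)
  out
}
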