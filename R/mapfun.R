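#' Mapping functions
#'
#' Convert recombination fractions to map distances and back.  Kosambi
#' (`d = 25 ln((1+2r)/(1-2r))`, allowing for moderate crossover
#' interference, the CRIMAP convention) is the package default; Haldane
#' (`d = -50 ln(1-2r)`, no interference) matches simulators with Poisson
#' crossovers.  Fractions are capped just below 1/2, where distance
#' diverges.
#'
#' @param r recombination fraction(s) in \[0, 0.5\].
#' @param d map distance(s) in cM.
#' @param mapfn `"kosambi"` or `"haldane"`.
#' @return distances in cM, or fractions.
#' @export
rf_to_cM <- function(r, mapfn = c("kosambi", "haldane")) {
  mapfn <- match.arg(mapfn)
  r <- pmin(pmax(r, 0), 0.5 - 1e-12)
  if (mapfn == "kosambi") 25 * log((1 + 2 * r) / (1 - 2 * r))
  else -50 * log(1 - 2 * r)
}

#' @rdname rf_to_cM
#' @export
cM_to_rf <- function(d, mapfn = c("kosambi", "haldane")) {
  mapfn <- match.arg(mapfn)
  if (mapfn == "kosambi") 0.5 * tanh(d / 50)
  else 0.5 * (1 - exp(-d / 50))
}
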