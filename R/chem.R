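# Monoisotopic atomic masses (CODATA/AME2020) for the elements the negative
# mode metabolite annotation needs, plus the electron mass: FTICR-level mass
# accuracy makes the ~0.55 mDa electron term non-negligible.
MONOISOTOPIC <- c(
  C  = 12,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.9737619984,
  S  = 31.9720711744,
  Cl = 34.96885268,
  Na = 22.9897692809,
  K  = 38.96370668,
  Br = 78.9183371
)
ELECTRON_MASS <- 0.000548579909

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-style formulas over C, H, N, O, P, S, Cl (plus Na/K/Br for
#' adduct arithmetic), e.g. `"C6H12O6"`.
#'
#' @param formula character scalar.
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C6H12O6")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(paste(toks, collapse = "")) ||
      nchar(paste(toks, collapse = "")) != nchar(formula))
    stop2("unparseable formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(ifelse(grepl("[0-9]+$", toks),
                         sub("^[A-Za-z]+", "", toks), "1"))
  bad <- setdiff(el, names(MONOISOTOPIC))
  if (length(bad))
    stop2("unsupported element(s) in ", formula, ": ",
          paste(bad, collapse = ", "))
  s <- tapply(n, el, sum)
  stats::setNames(as.integer(s), names(s))
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula character scalar molecular formula.
#' @return Mass in Da.
#' @export
#' @examples
#' formula_mass("C6H12O6")  # 180.0634
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(MONOISOTOPIC[names(counts)] * counts)
}

#' Negative-mode adduct rules
#'
#' Returns the adduct table used for MS1 annotation: the two physically
#' expected negative-mode adducts, deprotonation (`[M-H]-`) and chloride
#' attachment (`[M+Cl]-`), and optionally a set of implausible decoy adducts
#' used by the simplified decoy-adduct false discovery rate (a deliberately
#' simple stand-in for image-aware annotation scoring). Mass shifts include
#' the electron gained by the anion.
#'
#' @param decoys logical, include the decoy rules.
#' @return data.frame with columns `name`, `mass_shift` (Da), `decoy`.
#' @export
#' @examples
#' adduct_rules()
adduct_rules <- function(decoys = TRUE) {
  H <- MONOISOTOPIC[["H"]]; e <- ELECTRON_MASS
  rules <- data.frame(
    name = c("[M-H]-", "[M+Cl]-"),
    mass_shift = c(-H + e, MONOISOTOPIC[["Cl"]] + e),
    decoy = c(FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (decoys) {
    dec <- data.frame(
      name = c("[M+Br]-", "[M+Na-2H]-", "[M+K-2H]-"),
      mass_shift = c(MONOISOTOPIC[["Br"]] + e,
                     MONOISOTOPIC[["Na"]] - 2 * H + e,
                     MONOISOTOPIC[["K"]] - 2 * H + e),
      decoy = TRUE,
      stringsAsFactors = FALSE
    )
    rules <- rbind(rules, dec)
  }
  rules
}

#' Theoretical m/z of a formula under an adduct
#'
#' @param formula neutral molecular formula.
#' @param adduct adduct name matching a row of [adduct_rules()], or a
#'   single-row adduct data.frame.
#' @return m/z in Da (singly charged).
#' @export
#' @examples
#' adduct_mz("C6H12O6", "[M-H]-")
#' adduct_mz("C6H12O6", "[M+Cl]-")
adduct_mz <- function(formula, adduct) {
  if (is.character(adduct)) {
    rules <- adduct_rules(decoys = TRUE)
    i <- match(adduct, rules$name)
    if (is.na(i)) stop2("unknown adduct: ", adduct)
    shift <- rules$mass_shift[i]
  } else {
    shift <- adduct$mass_shift
  }
  formula_mass(formula) + shift
}

# signed ppm deviation of observed from theoretical
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
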