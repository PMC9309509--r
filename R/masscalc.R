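## Monoisotopic mass and adduct m/z arithmetic for confirming candidate BGC
## products against LC-MS observations.

## Masses of the most abundant (lightest, for these elements) isotope, in Da.
## Values to >= 6 decimal places from the standard isotope tables.
.MONOISOTOPIC_MASS <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  P  = 30.97376151,
  Na = 22.98976928,
  K  = 38.96370690,
  Cl = 34.96885271,
  F  = 18.99840320,
  Br = 78.91833760,
  I  = 126.90447300,
  Se = 79.91652180,
  Si = 27.97692650,
  B  = 11.00930550,
  Li = 7.01600450,
  Fe = 55.93494210
)

## Mass of the proton (H+), i.e. the hydrogen atom minus its electron.
.PROTON_MASS <- 1.007276

#' Parse a chemical formula string
#'
#' Parses a Hill-notation molecular formula such as \code{"C12H11N3O2"} into a
#' named integer vector of element counts. Parenthesised groups with a
#' trailing multiplier (e.g. \code{"(CH3)2"}) are expanded. Element symbols
#' must be among the supported set (C, H, N, O, S, P, Na, K, Cl, F, Br, I,
#' Se, Si, B, Li, Fe); anything else is rejected with an error at parse time.
#'
#' @param formula A single formula string, or an already-parsed named numeric
#'   vector (returned unchanged after validation). The empty string denotes
#'   the empty formula.
#' @return A named numeric vector of non-negative integer element counts with
#'   class \code{"ChemicalFormula"}. Elements are merged (each symbol appears
#'   once).
#' @examples
#' parseFormula("C12H11N3O2")
#' parseFormula("(CH3)2SO")
#' @export
parseFormula <- function(formula) {
  if (is.numeric(formula)) {
    counts <- formula
    unknown <- setdiff(names(counts), names(.MONOISOTOPIC_MASS))
    if (length(unknown))
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    if (any(counts < 0) || any(counts != round(counts)))
      stop("element counts must be non-negative integers")
    return(structure(counts, class = "ChemicalFormula"))
  }
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("'formula' must be a single character string")
  s <- gsub("[[:space:]]", "", formula)
  pos <- 1L
  n <- nchar(s)

  peek <- function() if (pos > n) "" else substr(s, pos, pos)
  # parse a group: sequence of (element|parenthesised group)[count]
  parseGroup <- function() {
    counts <- numeric(0)
    repeat {
      ch <- peek()
      if (ch == "" || ch == ")") break
      if (ch == "(") {
        pos <<- pos + 1L
        inner <- parseGroup()
        if (peek() != ")")
          stop("unbalanced parentheses in formula '", formula, "'")
        pos <<- pos + 1L
        mult <- parseCount()
        inner <- inner * mult
        counts <- mergeCounts(counts, inner)
      } else if (grepl("^[A-Z]$", ch)) {
        sym <- ch
        pos <<- pos + 1L
        if (grepl("^[a-z]$", peek())) {
          sym <- paste0(sym, peek())
          pos <<- pos + 1L
        }
        if (!sym %in% names(.MONOISOTOPIC_MASS))
          stop("unknown element symbol '", sym, "' in formula '", formula, "'")
        cnt <- parseCount()
        add <- stats::setNames(cnt, sym)
        counts <- mergeCounts(counts, add)
      } else {
        stop("unexpected character '", ch, "' in formula '", formula, "'")
      }
    }
    counts
  }
  parseCount <- function() {
    start <- pos
    while (grepl("^[0-9]$", peek())) pos <<- pos + 1L
    if (pos == start) 1 else as.numeric(substr(s, start, pos - 1L))
  }
  mergeCounts <- function(a, b) {
    for (sym in names(b)) {
      if (sym %in% names(a)) a[[sym]] <- a[[sym]] + b[[sym]]
      else a[sym] <- b[[sym]]
    }
    a
  }

  counts <- parseGroup()
  if (pos <= n)
    stop("unbalanced parentheses in formula '", formula, "'")
  structure(counts, class = "ChemicalFormula")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums, over every atom, the mass of the element's most abundant isotope.
#'
#' @param formula A formula string or a vector from [parseFormula()].
#' @return Monoisotopic mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopicMass("H2O")          # 18.010565
#' monoisotopicMass("C12H11N3O2")   # caerulomycin A, 229.085127
#' @export
monoisotopicMass <- function(formula) {
  counts <- parseFormula(formula)
  if (length(counts) == 0L) return(0)
  sum(unclass(counts) * .MONOISOTOPIC_MASS[names(counts)])
}

#' Parse an adduct specification
#'
#' Understands the usual bracket notation, e.g. \code{"[M+H]+"},
#' \code{"[M-H]-"}, \code{"[M+Na]+"}, \code{"[M+2H]2+"}, \code{"[2M+H]+"},
#' \code{"[M+H-H2O]+"}. The Unicode minus sign is accepted as \code{-}.
#'
#' The mass delta of a \code{+H}/\code{-H} term is the proton mass
#' (1.007276 Da); for every other gained or lost group the neutral
#' monoisotopic mass is used, i.e. the electron mass is neglected
#' (an error below 0.5 mDa for singly charged ions).
#'
#' @param adduct Adduct string.
#' @return A list with components \code{nmol} (molecular multiplier),
#'   \code{delta} (mass delta in Da) and \code{charge} (signed integer, never
#'   zero).
#' @export
parseAdduct <- function(adduct) {
  if (!is.character(adduct) || length(adduct) != 1L || is.na(adduct))
    stop("'adduct' must be a single character string")
  s <- gsub("[−–]", "-", gsub("[[:space:]]", "", adduct))
  m <- regmatches(s, regexec("^\\[(\\d*)M((?:[+-][A-Za-z0-9]+)*)\\](\\d*)([+-])$", s))[[1]]
  if (length(m) == 0L)
    stop("cannot parse adduct '", adduct, "'; expected e.g. \"[M+H]+\"")
  nmol <- if (m[2] == "") 1L else as.integer(m[2])
  zmag <- if (m[4] == "") 1L else as.integer(m[4])
  if (zmag == 0L) stop("adduct '", adduct, "' has zero charge")
  charge <- if (m[5] == "+") zmag else -zmag
  delta <- 0
  terms <- regmatches(m[3], gregexpr("[+-][A-Za-z0-9]+", m[3]))[[1]]
  for (term in terms) {
    sgn <- if (substr(term, 1, 1) == "+") 1 else -1
    body <- substr(term, 2, nchar(term))
    cm <- regmatches(body, regexec("^(\\d*)([A-Za-z0-9]+)$", body))[[1]]
    mult <- if (cm[2] == "") 1 else as.numeric(cm[2])
    grp <- cm[3]
    grpMass <- if (grp == "H") .PROTON_MASS else monoisotopicMass(grp)
    delta <- delta + sgn * mult * grpMass
  }
  list(nmol = nmol, delta = delta, charge = charge)
}

#' Theoretical m/z of an adduct ion
#'
#' Computes \eqn{m/z = (n M + \Delta) / |z|} for a neutral molecule of
#' monoisotopic mass \eqn{M} and an adduct specification giving the molecular
#' multiplier \eqn{n}, mass delta \eqn{\Delta} and charge \eqn{z}.
#'
#' @param formula Molecular formula (string or parsed vector).
#' @param adduct Adduct string, e.g. \code{"[M+H]+"} (the default).
#' @return The theoretical m/z in Th.
#' @examples
#' adductMz("C12H11N3O2", "[M+H]+")  # protonated caerulomycin A, 230.0924
#' adductMz("C25H35N3O", "[M+H]+")   # protonated undecylprodigiosin, 394.29
#' @export
adductMz <- function(formula, adduct = "[M+H]+") {
  spec <- parseAdduct(adduct)
  M <- monoisotopicMass(formula)
  (spec$nmol * M + spec$delta) / abs(spec$charge)
}

#' Match an observed m/z against candidate compounds
#'
#' For each candidate (name, formula, adduct) the theoretical m/z is computed
#' and compared with the observation; candidates within the ppm tolerance are
#' returned ranked by absolute ppm error.
#'
#' @param observedMz Observed m/z (single positive number).
#' @param candidates A data.frame with columns \code{name}, \code{formula}
#'   and optionally \code{adduct} (default \code{"[M+H]+"} where missing).
#' @param tolPpm Tolerance in parts per million (default 10).
#' @return A data.frame with columns \code{name}, \code{formula},
#'   \code{adduct}, \code{theoretical_mz} and \code{ppm_error} (signed,
#'   observed relative to theoretical), sorted by \code{abs(ppm_error)}.
#'   Zero rows when nothing matches.
#' @examples
#' matchObserved(230.0924,
#'   data.frame(name = "caerulomycin A", formula = "C12H11N3O2"))
#' @export
matchObserved <- function(observedMz, candidates, tolPpm = 10) {
  stopifnot(is.numeric(observedMz), length(observedMz) == 1L, observedMz > 0)
  if (!is.numeric(tolPpm) || tolPpm <= 0) stop("'tolPpm' must be > 0")
  empty <- data.frame(name = character(), formula = character(),
                      adduct = character(), theoretical_mz = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE)
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  if (!all(c("name", "formula") %in% names(candidates)))
    stop("'candidates' needs columns 'name' and 'formula'")
  adducts <- if ("adduct" %in% names(candidates)) as.character(candidates$adduct)
             else rep("[M+H]+", nrow(candidates))
  adducts[is.na(adducts) | adducts == ""] <- "[M+H]+"
  theo <- mapply(adductMz, as.character(candidates$formula), adducts)
  ppm <- (observedMz - theo) / theo * 1e6
  keep <- abs(ppm) <= tolPpm
  out <- data.frame(name = as.character(candidates$name)[keep],
                    formula = as.character(candidates$formula)[keep],
                    adduct = adducts[keep],
                    theoretical_mz = theo[keep],
                    ppm_error = ppm[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(abs(out$ppm_error)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
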