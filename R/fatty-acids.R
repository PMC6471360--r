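# Atomic masses (IUPAC, g/mol) used throughout so molar-mass arithmetic is
# bit-stable across platforms.
.atomic_mass <- c(H = 1.0079, C = 12.0107, O = 15.9994)

.mass_glycerol <- 3 * .atomic_mass[["C"]] + 8 * .atomic_mass[["H"]] +
  3 * .atomic_mass[["O"]]
.mass_water <- 2 * .atomic_mass[["H"]] + .atomic_mass[["O"]]

#' Molar mass of a free fatty acid from its formula
#'
#' A fatty acid with `n` carbons and `d` double bonds has the molecular
#' formula C\eqn{_n}H\eqn{_{2n-2d}}O\eqn{_2}.
#'
#' @param carbons number of carbon atoms (>= 2).
#' @param double_bonds number of C=C double bonds (>= 0, < carbons/2).
#' @return molar mass in g/mol.
#' @export
ffa_molar_mass <- function(carbons, double_bonds) {
  carbons * .atomic_mass[["C"]] +
    (2 * carbons - 2 * double_bonds) * .atomic_mass[["H"]] +
    2 * .atomic_mass[["O"]]
}

#' Construct a fatty acid
#'
#' @param code shorthand lipid code, e.g. `"C18:2 n-6"`.
#' @param label short letter label used in TAG species names, e.g. `"L"`.
#' @param carbons carbon-chain length (integer >= 2).
#' @param double_bonds number of double bonds (integer >= 0).
#' @param conjugated logical; whether the double bonds are conjugated.
#' @param molar_mass optional molar mass (g/mol).  When supplied it must agree
#'   with the formula mass of C\eqn{_n}H\eqn{_{2n-2d}}O\eqn{_2} to within
#'   1 g/mol; when omitted the formula mass is used.
#' @return an object of class `fatty_acid`.
#' @examples
#' linoleic <- fatty_acid("C18:2 n-6", "L", 18, 2)
#' linoleic$molar_mass
#' @export
fatty_acid <- function(code, label, carbons, double_bonds,
                       conjugated = FALSE, molar_mass = NULL) {
  stopifnot(is.character(code), length(code) == 1L,
            is.character(label), length(label) == 1L)
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  if (is.na(carbons) || carbons < 2L)
    stop("'carbons' must be an integer >= 2", call. = FALSE)
  if (is.na(double_bonds) || double_bonds < 0L ||
      double_bonds >= carbons / 2)
    stop("'double_bonds' must satisfy 0 <= double_bonds < carbons/2",
         call. = FALSE)
  formula_mass <- ffa_molar_mass(carbons, double_bonds)
  if (is.null(molar_mass)) {
    molar_mass <- formula_mass
  } else if (!is.numeric(molar_mass) || molar_mass <= 0 ||
             abs(molar_mass - formula_mass) > 1) {
    stop(sprintf(
      "molar_mass %.3f differs from the C%dH%dO2 formula mass %.3f by > 1 g/mol",
      molar_mass, carbons, 2 * carbons - 2 * double_bonds, formula_mass),
      call. = FALSE)
  }
  structure(
    list(code = code, label = label, carbons = carbons,
         double_bonds = double_bonds, conjugated = isTRUE(conjugated),
         molar_mass = molar_mass),
    class = "fatty_acid")
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat(sprintf("<fatty_acid> %s (%s): C%d:%d%s, %.2f g/mol\n",
              x$label, x$code, x$carbons, x$double_bonds,
              if (x$conjugated) " conjugated" else "", x$molar_mass))
  invisible(x)
}

#' Reference fatty acids
#'
#' The nine fatty acids needed to describe soybean oil (SBO), pomegranate
#' seed oil (PGO), their 1:1 physical blend (PHY) and the interesterified
#' oil (IO): palmitic (P), stearic (S), oleic (O), cis-vaccenic (V),
#' trans-linoleic (Lt), linoleic (L), gamma-linolenic (gLn), alpha-linolenic
#' (Ln) and conjugated linolenic / punicic acid (CLn).
#'
#' @return a named list of [fatty_acid] objects keyed by label.
#' @export
standard_fatty_acids <- function() {
  fas <- list(
    fatty_acid("C16:0",     "P",   16, 0),
    fatty_acid("C18:0",     "S",   18, 0),
    fatty_acid("C18:1 n-9", "O",   18, 1),
    fatty_acid("C18:1 n-7", "V",   18, 1),
    fatty_acid("C18:2t",    "Lt",  18, 2),
    fatty_acid("C18:2 n-6", "L",   18, 2),
    fatty_acid("C18:3 n-6", "gLn", 18, 3),
    fatty_acid("C18:3 n-3", "Ln",  18, 3),
    fatty_acid("C18:3 n-5", "CLn", 18, 3, conjugated = TRUE))
  names(fas) <- vapply(fas, `[[`, "", "label")
  fas
}

#' Construct an oil fatty-acid composition
#'
#' Area percentages from GC-FID of fatty-acid methyl esters.  Known entries
#' plus the unknown fraction must total 100 within a +/- 2 rounding tolerance.
#'
#' @param name oil name.
#' @param acids list of [fatty_acid] objects.
#' @param area_percent numeric vector of area percentages, same length as
#'   `acids`.
#' @param unknown_percent area percentage not attributed to a known acid.
#' @return an object of class `oil_composition`.
#' @export
oil_composition <- function(name, acids, area_percent, unknown_percent = 0) {
  stopifnot(is.list(acids), length(acids) == length(area_percent))
  if (!all(vapply(acids, inherits, TRUE, "fatty_acid")))
    stop("all elements of 'acids' must be fatty_acid objects", call. = FALSE)
  if (any(area_percent < 0) || unknown_percent < 0)
    stop("area percentages must be non-negative", call. = FALSE)
  total <- sum(area_percent) + unknown_percent
  if (total < 98 || total > 102)
    stop(sprintf("composition totals %.1f%%; expected 100 +/- 2", total),
         call. = FALSE)
  labels <- vapply(acids, `[[`, "", "label")
  names(acids) <- labels
  structure(
    list(name = name, acids = acids,
         area_percent = stats::setNames(as.numeric(area_percent), labels),
         unknown_percent = unknown_percent),
    class = "oil_composition")
}

#' @export
print.oil_composition <- function(x, ...) {
  cat(sprintf("<oil_composition> %s (%d fatty acids, %.1f%% unknown)\n",
              x$name, length(x$acids), x$unknown_percent))
  df <- data.frame(
    code = vapply(x$acids, `[[`, "", "code"),
    label = names(x$acids),
    area_percent = unname(x$area_percent))
  print(df, row.names = FALSE)
  invisible(x)
}

# GC-FID area % tables for the four study oils.  Dashes in the source table
# are absent acids and are omitted here.
.oil_tables <- list(
  SBO = list(p = c(P = 13.1, S = 3.8, O = 22.1, V = 2.8, Lt = 0.5, L = 49.5,
                   gLn = 0.6, Ln = 5.5), unknown = 2.0),
  PGO = list(p = c(P = 4.0, S = 2.6, O = 7.0, V = 1.1, Lt = 0.9, L = 8.5,
                   CLn = 74.7), unknown = 1.2),
  PHY = list(p = c(P = 9.8, S = 4.0, O = 18.1, V = 2.4, Lt = 0.6, L = 35.1,
                   gLn = 0.3, Ln = 3.4, CLn = 24.7), unknown = 1.8),
  IO  = list(p = c(P = 8.8, S = 3.7, O = 16.7, V = 2.7, Lt = 0.8, L = 32.9,
                   gLn = 0.3, Ln = 3.0, CLn = 29.2), unknown = 1.9))

#' Built-in fatty-acid compositions of the study oils
#'
#' GC-FID fatty-acid area percentages for soybean oil (`"SBO"`), pomegranate
#' seed oil (`"PGO"`), their 1:1 (w/w) physical blend (`"PHY"`) and the
#' enzymatically interesterified oil (`"IO"`).
#'
#' @param oil one of `"SBO"`, `"PGO"`, `"PHY"`, `"IO"`.
#' @return an [oil_composition].
#' @examples
#' oil_composition_fixture("PGO")
#' @export
oil_composition_fixture <- function(oil = c("SBO", "PGO", "PHY", "IO")) {
  oil <- match.arg(oil)
  tab <- .oil_tables[[oil]]
  fas <- standard_fatty_acids()
  oil_composition(oil, unname(fas[names(tab$p)]), unname(tab$p), tab$unknown)
}
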