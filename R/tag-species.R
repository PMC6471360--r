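#' Construct a triacylglycerol (TAG) species
#'
#' A TAG species is an unordered triple of acyl chains.  The total carbon
#' number CN, total double-bond count ND, partition number PN = CN - 2 ND and
#' the molar mass (three fatty acids esterified to glycerol, losing three
#' waters) are derived on construction.  The species label is independent of
#' the order in which the acyls are given.
#'
#' @param acyls list of exactly three [fatty_acid] objects (any order).
#' @return an object of class `tag_species` with fields `acyls`, `label`,
#'   `cn`, `nd`, `pn` and `molar_mass`.
#' @examples
#' fas <- standard_fatty_acids()
#' lll <- tag_species(list(fas$L, fas$L, fas$L))
#' lll$pn          # 42
#' lll$molar_mass  # ~879.4 g/mol
#' @export
tag_species <- function(acyls) {
  if (!is.list(acyls) || length(acyls) != 3L ||
      !all(vapply(acyls, inherits, TRUE, "fatty_acid")))
    stop("a TAG species requires exactly 3 fatty_acid acyls", call. = FALSE)
  # canonical order: descending abundance is unknowable here, so sort by
  # (carbons, double bonds, label) for a permutation-invariant label
  ord <- order(vapply(acyls, `[[`, 0L, "carbons"),
               vapply(acyls, `[[`, 0L, "double_bonds"),
               vapply(acyls, `[[`, "", "label"))
  acyls <- acyls[ord]
  cn <- sum(vapply(acyls, `[[`, 0L, "carbons"))
  nd <- sum(vapply(acyls, `[[`, 0L, "double_bonds"))
  structure(
    list(acyls = acyls,
         label = paste(vapply(acyls, `[[`, "", "label"), collapse = "-"),
         cn = cn, nd = nd, pn = cn - 2L * nd,
         molar_mass = sum(vapply(acyls, `[[`, 0, "molar_mass")) +
           .mass_glycerol - 3 * .mass_water),
    class = "tag_species")
}

#' @export
print.tag_species <- function(x, ...) {
  cat(sprintf("<tag_species> %s  CN=%d ND=%d PN=%d  %.2f g/mol\n",
              x$label, x$cn, x$nd, x$pn, x$molar_mass))
  invisible(x)
}

#' Partition number of a TAG species
#'
#' PN = CN - 2 ND, where CN is the total acyl carbon number and ND the total
#' number of double bonds.  On a reversed-phase C18 column TAG elution order
#' follows increasing PN, which is the basis of peak annotation.
#'
#' @param species a [tag_species].
#' @return integer partition number.
#' @examples
#' fas <- standard_fatty_acids()
#' partition_number(tag_species(list(fas$CLn, fas$CLn, fas$CLn)))  # 36
#' @export
partition_number <- function(species) {
  if (!inherits(species, "tag_species"))
    stop("'species' must be a tag_species", call. = FALSE)
  if (length(species$acyls) != 3L)
    stop("malformed tag_species: expected exactly 3 acyls", call. = FALSE)
  species$cn - 2L * species$nd
}

#' Molar mass of a TAG species
#'
#' Sum of the three fatty-acid masses plus glycerol minus three waters of
#' esterification.
#'
#' @param species a [tag_species].
#' @return molar mass in g/mol.
#' @export
tag_molar_mass <- function(species) {
  if (!inherits(species, "tag_species"))
    stop("'species' must be a tag_species", call. = FALSE)
  species$molar_mass
}

#' Mean molar mass of an oil from its fatty-acid composition
#'
#' GC area percentages of the known fatty acids are renormalized and treated
#' as acyl mole fractions (for C18-dominated oils FAME area % closely tracks
#' mole %).  The oil is then an average TAG: three average acyls esterified
#' to glycerol.
#'
#' @param comp an [oil_composition]; known acids must cover at least
#'   `min_coverage` of the total area.
#' @param min_coverage minimum known-acid coverage (fraction of total area).
#' @return mean molar mass in g/mol.
#' @examples
#' mean_oil_molar_mass(oil_composition_fixture("SBO"))
#' @export
mean_oil_molar_mass <- function(comp, min_coverage = 0.9) {
  stopifnot(inherits(comp, "oil_composition"))
  known <- sum(comp$area_percent)
  total <- known + comp$unknown_percent
  if (known / total < min_coverage)
    stop(sprintf(
      "known fatty acids cover only %.1f%% of area (%.1f%% unknown); need >= %.0f%%",
      100 * known / total, comp$unknown_percent, 100 * min_coverage),
      call. = FALSE)
  frac <- comp$area_percent / known
  mean_ffa <- sum(frac * vapply(comp$acids, `[[`, 0, "molar_mass"))
  3 * mean_ffa - 3 * .mass_water + .mass_glycerol
}

#' Enumerate plausible TAG species from a composition
#'
#' Forms every 3-multiset of the fatty acids whose renormalized mole
#' fraction reaches `min_abundance`, computes each PN, and estimates relative
#' abundance as the multinomial product of acyl fractions (a
#' random-distribution heuristic used only for ordering and tie-breaks).
#'
#' @param comp an [oil_composition].
#' @param min_abundance minimal acyl mole fraction, in (0, 1].
#' @return a data frame with columns `label`, `cn`, `nd`, `pn`,
#'   `est_abundance`, sorted by PN ascending then estimated abundance
#'   descending, with the [tag_species] objects in the list column `species`.
#' @examples
#' head(enumerate_plausible_species(oil_composition_fixture("PGO"), 0.05))
#' @export
enumerate_plausible_species <- function(comp, min_abundance = 0.05) {
  stopifnot(inherits(comp, "oil_composition"))
  if (!is.numeric(min_abundance) || min_abundance <= 0 || min_abundance > 1)
    stop("'min_abundance' must be in (0, 1]", call. = FALSE)
  if (length(comp$acids) == 0L)
    stop("empty composition", call. = FALSE)
  frac <- comp$area_percent / sum(comp$area_percent)
  keep <- which(frac >= min_abundance)
  if (length(keep) == 0L)
    stop("no fatty acid reaches min_abundance", call. = FALSE)
  acids <- comp$acids[keep]
  frac <- frac[keep]
  k <- length(acids)
  idx <- expand.grid(i = seq_len(k), j = seq_len(k), l = seq_len(k))
  idx <- idx[idx$i <= idx$j & idx$j <= idx$l, , drop = FALSE]
  species <- vector("list", nrow(idx))
  abundance <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    trip <- c(idx$i[r], idx$j[r], idx$l[r])
    species[[r]] <- tag_species(acids[trip])
    mult <- factorial(3) / prod(factorial(table(trip)))  # multiset multiplicity
    abundance[r] <- mult * prod(frac[trip])
  }
  out <- data.frame(
    label = vapply(species, `[[`, "", "label"),
    cn = vapply(species, `[[`, 0L, "cn"),
    nd = vapply(species, `[[`, 0L, "nd"),
    pn = vapply(species, `[[`, 0L, "pn"),
    est_abundance = abundance)
  ord <- order(out$pn, -out$est_abundance)
  out <- out[ord, , drop = FALSE]
  out$species <- I(species[ord])
  rownames(out) <- NULL
  out
}

#' Annotate chromatogram peaks by partition number
#'
#' Matches the peaks of a [peak_table] (sorted by retention time) to PN
#' groups of candidate TAG species in elution order: on reversed-phase C18,
#' PN increases with retention, so the first peak gets the lowest PN group
#' and so on.  Within a PN group the most abundant species names the peak.
#' Peaks beyond the available PN groups are labelled `"Unknown"`; PN groups
#' beyond the available peaks are reported in a warning.
#'
#' @param peaks a [peak_table].
#' @param species a list of [tag_species] or the data frame returned by
#'   [enumerate_plausible_species()] (row order within a PN group is kept as
#'   the abundance order).
#' @return the peak table with its `annotation` and a `pn` column filled in.
#' @export
annotate_peaks <- function(peaks, species) {
  stopifnot(inherits(peaks, "peak_table"))
  if (is.data.frame(species)) {
    labels <- species$label
    pns <- species$pn
  } else {
    if (!all(vapply(species, inherits, TRUE, "tag_species")))
      stop("'species' must be tag_species objects", call. = FALSE)
    labels <- vapply(species, `[[`, "", "label")
    pns <- vapply(species, `[[`, 0L, "pn")
  }
  if (is.unsorted(peaks$peaks$retention_min))
    stop("peaks must be sorted by retention time", call. = FALSE)
  groups <- sort(unique(pns))
  n_peak <- nrow(peaks$peaks)
  peaks$peaks$annotation <- "Unknown"
  peaks$peaks$pn <- NA_integer_
  n_match <- min(length(groups), n_peak)
  for (g in seq_len(n_match)) {
    members <- which(pns == groups[g])
    peaks$peaks$annotation[g] <- labels[members[1L]]  # input order = abundance
    peaks$peaks$pn[g] <- groups[g]
  }
  if (length(groups) > n_peak)
    warning(sprintf("unmatched PN groups (more groups than peaks): %s",
                    paste(groups[(n_peak + 1L):length(groups)],
                          collapse = ", ")), call. = FALSE)
  peaks
}
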