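test_that("partition number is CN - 2*ND and invariant to acyl order", {
  cases <- list(
    list(sp = tag("CLn", "CLn", "CLn"), cn = 54, nd = 9, pn = 36),
    list(sp = tag("P", "P", "P"),       cn = 48, nd = 0, pn = 48),
    list(sp = tag("CLn", "CLn", "O"),   cn = 54, nd = 7, pn = 40),
    list(sp = tag("L", "L", "L"),       cn = 54, nd = 6, pn = 42),
    list(sp = tag("CLn", "CLn", "L"),   cn = 54, nd = 8, pn = 38))
  for (cs in cases) {
    expect_identical(cs$sp$cn, as.integer(cs$cn))
    expect_identical(cs$sp$nd, as.integer(cs$nd))
    expect_identical(partition_number(cs$sp), as.integer(cs$pn))
  }
  # permutation invariance of PN and label
  perms <- list(c("CLn", "O", "CLn"), c("O", "CLn", "CLn"))
  for (p in perms) {
    sp <- tag(p[1], p[2], p[3])
    expect_identical(partition_number(sp), 40L)
    expect_identical(sp$label, tag("CLn", "CLn", "O")$label)
  }
  # PN parity equals CN parity
  for (cs in cases)
    expect_identical(cs$sp$pn %% 2L, cs$sp$cn %% 2L)
})

test_that("partition_number rejects malformed species", {
  expect_error(partition_number(fa$L), "tag_species")
  expect_error(tag_species(list(fa$L, fa$L)), "exactly 3")
})

test_that("fatty_acid validates its invariants", {
  expect_error(fatty_acid("C1:0", "X", 1, 0), "carbons")
  expect_error(fatty_acid("C18:9", "X", 18, 9), "double_bonds")
  # stated mass must agree with the formula mass within 1 g/mol
  expect_error(fatty_acid("C18:2 n-6", "L", 18, 2, molar_mass = 300),
               "formula mass")
  expect_silent(fatty_acid("C18:2 n-6", "L", 18, 2, molar_mass = 280.4))
})

test_that("TAG molar mass matches atomic-mass sums", {
  # triundecanoin, C36H68O6
  c11 <- fatty_acid("C11:0", "U", 11, 0)
  tri_u <- tag_species(list(c11, c11, c11))
  expect_equal(tag_molar_mass(tri_u), 596.9, tolerance = 0.1 / 596.9)
  # trilinoleoylglycerol, C57H98O6
  expect_equal(tag_molar_mass(tag("L", "L", "L")), 879.4,
               tolerance = 0.1 / 879.4)
  # formula identity: 3 FFA - 3 H2O + glycerol, for an arbitrary mix
  sp <- tag("P", "O", "Ln")
  h2o <- 2 * 1.0079 + 15.9994
  glycerol <- 3 * 12.0107 + 8 * 1.0079 + 3 * 15.9994
  expect_equal(tag_molar_mass(sp),
               fa$P$molar_mass + fa$O$molar_mass + fa$Ln$molar_mass -
                 3 * h2o + glycerol)
})

test_that("TAG molar mass is monotone in CN and ND", {
  mk <- function(n, d) {
    a <- fatty_acid("x", "x", n, d)
    tag_species(list(a, a, a))
  }
  # increasing CN at fixed ND
  expect_true(tag_molar_mass(mk(18, 2)) > tag_molar_mass(mk(16, 2)))
  # each double bond removes two hydrogens
  expect_lt(tag_molar_mass(mk(18, 3)), tag_molar_mass(mk(18, 2)))
  expect_equal(tag_molar_mass(mk(18, 2)) - tag_molar_mass(mk(18, 3)),
               6 * 1.0079)
})

test_that("mean oil molar mass is an acyl-fraction-weighted TAG mass", {
  # degenerate one-acid oil equals the mono-acid TAG
  pure_l <- oil_composition("pureL", list(fa$L), 100)
  expect_equal(mean_oil_molar_mass(pure_l), tag_molar_mass(tag("L", "L", "L")),
               tolerance = 1e-12)
  # 50/50 L/O blend is the mean of the two mono-acid TAG masses
  blend <- oil_composition("LO", list(fa$L, fa$O), c(50, 50))
  expect_equal(mean_oil_molar_mass(blend),
               (tag_molar_mass(tag("L", "L", "L")) +
                  tag_molar_mass(tag("O", "O", "O"))) / 2,
               tolerance = 0.1 / 879)
  # the SBO table against a spreadsheet-style weighted sum done longhand
  sbo <- oil_composition_fixture("SBO")
  area <- c(P = 13.1, S = 3.8, O = 22.1, V = 2.8, Lt = 0.5, L = 49.5,
            gLn = 0.6, Ln = 5.5)
  mass <- c(P = ffa_molar_mass(16, 0), S = ffa_molar_mass(18, 0),
            O = ffa_molar_mass(18, 1), V = ffa_molar_mass(18, 1),
            Lt = ffa_molar_mass(18, 2), L = ffa_molar_mass(18, 2),
            gLn = ffa_molar_mass(18, 3), Ln = ffa_molar_mass(18, 3))
  h2o <- 2 * 1.0079 + 15.9994
  glycerol <- 3 * 12.0107 + 8 * 1.0079 + 3 * 15.9994
  expected <- 3 * sum(area / sum(area) * mass) - 3 * h2o + glycerol
  expect_equal(mean_oil_molar_mass(sbo), expected, tolerance = 1e-12)
})

test_that("mean oil molar mass refuses low known-acid coverage", {
  sparse <- oil_composition("sparse", list(fa$L), 60, unknown_percent = 40)
  expect_error(mean_oil_molar_mass(sparse), "40.0% unknown")
})

test_that("species enumeration counts multisets and ranks PGO correctly", {
  # k acids above threshold -> C(k+2, 3) multisets
  for (k in 1:4) {
    comp <- oil_composition(
      "even", unname(fa[seq_len(k)]), rep(100 / k, k))
    expect_identical(nrow(enumerate_plausible_species(comp, 0.01)),
                     as.integer(choose(k + 2, 3)))
  }
  # single-acid oil: exactly one species
  one <- enumerate_plausible_species(
    oil_composition("pure", list(fa$CLn), 100), 0.5)
  expect_identical(one$label, "CLn-CLn-CLn")
  # PGO: lowest-PN group is led by the trilinolenoyl species
  pgo <- enumerate_plausible_species(oil_composition_fixture("PGO"), 0.05)
  expect_identical(pgo$pn[1], 36L)
  expect_identical(pgo$label[1], "CLn-CLn-CLn")
  # ordering: PN non-decreasing, abundance non-increasing within a group
  expect_true(!is.unsorted(pgo$pn))
  for (p in unique(pgo$pn))
    expect_true(!is.unsorted(-pgo$est_abundance[pgo$pn == p]))
})

test_that("peak annotation follows PN elution order", {
  species <- enumerate_plausible_species(oil_composition_fixture("PGO"), 0.05)
  n_groups <- length(unique(species$pn))
  tab <- flat_peak_table(rep(100, n_groups), rep("", n_groups))
  ann <- annotate_peaks(tab, species)
  expect_identical(ann$peaks$pn[1:3], sort(unique(species$pn))[1:3])
  expect_identical(ann$peaks$annotation[1], "CLn-CLn-CLn")
  # single peak, single species
  one <- annotate_peaks(flat_peak_table(5, ""), list(tag("L", "L", "L")))
  expect_identical(one$peaks$annotation, "L-L-L")
  # extra peaks beyond the PN groups stay Unknown
  many <- flat_peak_table(rep(1, n_groups + 2), rep("", n_groups + 2))
  ann2 <- annotate_peaks(many, species)
  expect_identical(ann2$peaks$annotation[n_groups + (1:2)],
                   c("Unknown", "Unknown"))
  # more groups than peaks: unmatched groups warned, not fatal
  expect_warning(annotate_peaks(flat_peak_table(1, ""), species),
                 "unmatched PN groups")
})
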