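test_that("formula parsing follows the element-count grammar", {
  expect_equal(unclass(parse_formula("C15H10O7"))[c("C", "H", "O")],
               c(C = 15L, H = 10L, O = 7L))
  expect_equal(length(parse_formula("")), 0L)
  expect_equal(unclass(parse_formula("C_12_H_22_O_11"))[c("C", "H", "O")],
               c(C = 12L, H = 22L, O = 11L))
  # repeated element mentions are summed; implicit count 1
  expect_equal(parse_formula("CH3CH3")[["C"]], 2L)
  expect_equal(parse_formula("CHCl")[["Cl"]], 1L)
  expect_error(parse_formula("C5Xx2"), "unknown element")
})

test_that("formula round-trips through the canonical Hill string", {
  for (f in c("C15H10O7", "C12H22O11", "C7H6N2O", "HCl", "")) {
    counts <- parse_formula(f)
    expect_identical(unclass(parse_formula(formula_string(counts))),
                     unclass(counts))
  }
  expect_identical(formula_string(parse_formula("O7C15H10")), "C15H10O7")
})

test_that("monoisotopic mass matches the elementwise oracle", {
  expect_identical(monoisotopic_mass(""), 0)
  expect_equal(monoisotopic_mass("C15H10O7"), 302.042653, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C21H24O7"), 388.152203, tolerance = 1e-6)
})

test_that("adduct m/z reproduces the printed library values", {
  expect_equal(round(adduct_mz("C15H10O7", "[M-H]-"), 4), 301.0354)
  expect_equal(round(adduct_mz("C19H20O6", "[M+COOH]-"), 4), 389.1242)
  expect_equal(round(adduct_mz("C21H24O7", "[M+Cl]-"), 4), 423.1216)
  expect_equal(round(adduct_mz("C12H22O11", "[M-H]-"), 4), 341.1089)
  expect_error(adduct_mz("C6H6", "[M+Na]+"), "supported")
})

test_that("deprotonation lowers and chloride adduction raises the m/z", {
  for (f in c("C6H12O6", "C19H20O6", "CH4")) {
    m <- monoisotopic_mass(f)
    expect_lt(adduct_mz(f, "[M-H]-"), m)
    expect_gt(adduct_mz(f, "[M+Cl]-"), m)
  }
})

test_that("ppm error uses (calc - exp)/calc and rejects bad input", {
  expect_identical(ppm_error(200, 200), 0)
  expect_equal(ppm_error(173.045547, 173.0449), 3.74, tolerance = 0.005)
  expect_equal(ppm_error(133.014247, 133.0139), 2.61, tolerance = 0.005)
  expect_error(ppm_error(0, 100), "positive")
})

test_that("the full packaged library reproduces at 4 decimals", {
  lib <- dbt_peak_library()
  expect_equal(nrow(lib), 40L)
  calc <- mapply(function(f, a) adduct_mz(f, a), lib$formula, lib$adduct)
  expect_equal(round(unname(calc), 4), lib$calculated_mz)
  # printed ppm errors are recovered for the deprotonated rows; the printed
  # errors of the three adduct rows follow a different (unstated) convention
  mh <- lib$adduct == "[M-H]-"
  err <- ppm_error(calc[mh], lib$experimental_mz[mh])
  expect_true(all(abs(err - lib$error_ppm[mh]) < 0.05))
  expect_true(all(abs(err) < 5))
})

test_that("peak annotation matches within tolerance and flags the rest", {
  lib <- dbt_peak_library()
  obs <- data.frame(peak_id = c("a", "b"), rt = c(42.1, 1.0),
                    mz = c(301.0349, 999.9))
  res <- annotate_peaks(obs, lib, tol_ppm = 5)
  hit <- res[res$peak_id == "a", ]
  expect_true(all(hit$matched))
  expect_true("Quercetin" %in% hit$name)
  expect_false(res$matched[res$peak_id == "b"])

  # tight tolerance excludes the same peak
  res01 <- annotate_peaks(obs[1, ], lib, tol_ppm = 0.1)
  expect_false(res01$matched[1])

  # duplicate-mass library entries are both reported, ordered by |ppm|
  dup <- data.frame(formula = c("C15H14O6", "C15H14O6"),
                    adduct = "[M-H]-", name = c("catechin", "epicatechin"))
  res2 <- annotate_peaks(data.frame(peak_id = 1, rt = 20, mz = 289.0720),
                         dup, tol_ppm = 5)
  expect_equal(nrow(res2), 2L)
  expect_true(all(diff(abs(res2$error_ppm)) >= 0))
  expect_error(annotate_peaks(obs, dup[0, ], 5), "empty")
})
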