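test_that("packaged profiles validate and encode the printed ratios", {
  for (nm in list_profiles()) {
    prof <- default_profile(nm)
    expect_length(validate_profile(prof), 0)
  }
  hu <- default_profile("human")
  mo <- default_profile("mouse")
  # basal-to-suprabasal drops, exact at the parameter level
  expect_equal(profile_mean(hu, "MECP2", "basal") /
                 profile_mean(hu, "MECP2", "suprabasal"), 16)
  expect_equal(profile_mean(hu, "XPC", "basal") /
                 profile_mean(hu, "XPC", "suprabasal"), 5)
  # cross-species basal ratios
  expect_equal(profile_mean(hu, "MECP2", "basal") /
                 profile_mean(mo, "MECP2", "basal"), 5)
  expect_equal(profile_mean(hu, "XPC", "basal") /
                 profile_mean(mo, "XPC", "basal"), 11)
  # basal positivity fractions behind the capture percentages
  expect_equal(profile_pos_frac(hu, "XPC", "basal"), 0.8824)
  expect_equal(profile_pos_frac(hu, "ITGB1", "basal"), 0.6706)
  expect_equal(profile_pos_frac(hu, "KRT15", "basal"), 0.6353)
  expect_equal(profile_pos_frac(hu, "EGFR", "basal"), 0.6235)
  # delaminating-cell proliferation probabilities
  expect_equal(hu$delamination$proliferation$MCM2, 0.40)
  expect_equal(hu$delamination$proliferation$Ki67, 0.20)
})

test_that("proliferation organization differs between human and mouse", {
  hu <- default_profile("human")
  mo <- default_profile("mouse")
  # mouse: proliferation restricted to the basal layer (exact zeros)
  for (ln in c("parabasal", "suprabasal"))
    for (m in c("MCM2", "PCNA", "Ki67"))
      expect_identical(profile_pos_frac(mo, m, ln), 0)
  # human: quiescent basal layer below the transit-amplifying parabasal
  expect_lt(profile_pos_frac(hu, "MCM2", "basal"),
            profile_pos_frac(hu, "MCM2", "parabasal"))
})

test_that("unknown profile names raise an error listing the options", {
  expect_error(default_profile("axolotl"), "available")
})

test_that("validate_profile reports violations without raising", {
  prof <- default_profile("human")
  prof$layers$basal$markers$XPC$pos_frac <- 1.2
  v <- validate_profile(prof)
  expect_true(any(grepl("XPC", v) & grepl("pos_frac", v)))
  prof2 <- default_profile("human")
  prof2$layers$parabasal <- NULL
  expect_true(any(grepl("missing layer", validate_profile(prof2))))
})

test_that("the uniform profile encodes unit fold-changes", {
  up <- uniform_profile()
  expect_length(validate_profile(up), 0)
  for (m in c("MECP2", "XPC", "MCM2"))
    expect_equal(profile_mean(up, m, "basal") /
                   profile_mean(up, m, "suprabasal"), 1)
})

test_that("marker panels enforce their structural invariants", {
  expect_error(marker_panel(c(A = "basal", A = "reference_protein",
                              K = "structural")), "unique")
  expect_error(marker_panel(c(A = "basal", K = "structural")),
               "reference_protein")
  expect_error(marker_panel(c(A = "basal", H = "reference_protein")),
               "structural")
  p <- default_panel()
  expect_length(validate_panel(p), 0)
  expect_identical(sum(p$role == "reference_protein"), 1L)
})
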