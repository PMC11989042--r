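test_that("identical seeds give bit-identical sections", {
  g <- section_geometry(width = 400)
  s1 <- synthesize_section(default_profile("human"), g, seed = 5)
  s2 <- synthesize_section(default_profile("human"), g, seed = 5)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$truth, s2$truth)
  s3 <- synthesize_section(default_profile("human"), g, seed = 6)
  expect_false(identical(s1$channels$DNA, s3$channels$DNA))
})

test_that("delaminating cell counts follow the encoded frequency", {
  # binomial oracle: n basal slots at p = frequency/100; pooled over
  # sections, the observed count must lie within 3 binomial SDs
  g <- small_geometry()
  p <- default_profile("human")$delamination$frequency / 100
  n_slots <- n_delam <- 0
  for (seed in 1:4) {
    s <- synthesize_section(default_profile("human"), g, seed)
    n_slots <- n_slots + sum(s$truth$layer == "basal")
    n_delam <- n_delam + sum(s$truth$delaminating)
  }
  expect_lt(abs(n_delam - n_slots * p), 3 * sqrt(n_slots * p * (1 - p)) + 1)
})

test_that("cell counts and layer proportions follow the geometry", {
  g <- small_geometry()
  s <- synthesize_section(default_profile("human"), g, seed = 2)
  # packing oracle: one basal row at the row spacing
  expect_equal(sum(s$truth$layer == "basal"),
               floor(g$width / g$spacing), tolerance = 0.1)
  tab <- table(s$truth$layer)
  # suprabasal band is the thickest and stroma is sparse
  expect_gt(tab[["suprabasal"]], tab[["parabasal"]])
  expect_gt(tab[["parabasal"]], tab[["basal"]])
  # every cell above the membrane in truth has a positive distance
  d <- stratiquant:::.membrane_at(s$membrane_truth, s$truth$x) - s$truth$y
  expect_true(all(d[s$truth$layer == "stromal"] < 0))
  expect_true(all(d[s$truth$layer != "stromal"] > 0))
})

test_that("rendered intensities reproduce the generative truth", {
  g <- small_geometry(width = 600)
  s <- synthesize_section(default_profile("human"), g, seed = 3)
  # mean over the true nuclear mask equals the drawn per-cell mean up to
  # camera noise (segmentation-free check of the renderer)
  H <- g$height; W <- g$width
  ch <- s$channels$MECP2
  tr <- s$truth[!s$truth$delaminating, ]
  rel <- vapply(seq_len(nrow(tr)), function(i) {
    idx <- stratiquant:::.disc_idx(tr$x[i], tr$y[i], tr$radius[i] - 0.5,
                                   H, W)
    mean(ch[idx]) / tr$mean_MECP2[i]
  }, numeric(1))
  expect_gt(mean(abs(rel - 1) < 0.1), 0.95)
  expect_equal(median(rel), 1, tolerance = 0.03)
})

test_that("sections round-trip through disk exactly", {
  g <- section_geometry(width = 300)
  s <- synthesize_section(default_profile("human"), g, seed = 4)
  dir <- file.path(tempdir(), "section_roundtrip")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- write_section(s, dir)
  expect_true(all(file.exists(paths)))
  s2 <- read_section(dir)
  expect_identical(lapply(s2$channels, unname),
                   lapply(s$channels, unname))
  expect_identical(names(s2$channels), names(s$channels))
  expect_equal(nrow(s2$truth), nrow(s$truth))
  meta <- jsonlite::read_json(file.path(dir, "channels.json"),
                              simplifyVector = TRUE)
  expect_identical(meta$channels, names(s$channels))
  expect_error(read_section(file.path(dir, "nope")), "missing")
})

test_that("a geometry too small for a basal row is rejected", {
  expect_error(section_geometry(width = 20), "width")
  g <- small_geometry()
  g$width <- 25L   # bypass the constructor check
  expect_error(synthesize_section(default_profile("human"), g, 1))
})

test_that("the PLA cohort simulator reproduces its design", {
  co <- simulate_pla_cohort(seed = 7)
  groups <- pla_progression_groups()
  expect_setequal(unique(co$group), groups$group)
  agg <- aggregate(count ~ group, co, mean)
  # group means track the encoded rates (between-sample variability of
  # cv 0.3 over 9-25 samples leaves the group mean within ~25%)
  for (i in seq_len(nrow(groups)))
    expect_equal(agg$count[agg$group == groups$group[i]], groups$rate[i],
                 tolerance = 0.25)
  expect_identical(simulate_pla_cohort(seed = 7), co)
})
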