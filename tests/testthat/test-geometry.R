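flat_epithelium <- function(y_boundary = 100, H = 200, W = 400,
                            value = 500, noise_sd = 2, seed = 1) {
  set.seed(seed)
  img <- matrix(0, H, W)
  img[seq_len(y_boundary + 1), ] <- value
  pmax(img + rnorm(H * W, sd = noise_sd), 0)
}

test_that("a flat epithelial boundary is recovered to sub-pixel accuracy", {
  mc <- estimate_membrane(flat_epithelium())
  expect_lt(sqrt(mean((as.numeric(mc) - 100)^2)), 1)
})

test_that("a sinusoidal boundary is recovered within 2 px RMS", {
  H <- 200; W <- 600
  set.seed(2)
  img <- matrix(0, H, W)
  truth <- 100 + 15 * sin(2 * pi * (0:(W - 1)) / 200)
  for (x in 0:(W - 1)) img[seq_len(round(truth[x + 1]) + 1), x + 1] <- 500
  img <- pmax(img + rnorm(H * W, sd = 2), 0)
  mc <- estimate_membrane(img)
  expect_lt(sqrt(mean((as.numeric(mc) - truth)^2)), 2)
})

test_that("an all-epithelium image (no stroma) is rejected", {
  expect_error(estimate_membrane(matrix(500, 100, 200)), "stroma")
})

test_that("layer assignment respects signed distances and tie-breaks", {
  membrane <- structure(rep(100, 50), class = "membrane_curve")
  cells <- stratiquant:::.as_cell_table(
    data.frame(cell_id = 1:4, x = c(10, 20, 30, 40),
               y = c(120, 100, 95, 40), area = 50), pixel_size = 0.5)
  out <- assign_layers(cells, membrane, layer_params())
  expect_identical(out$layer, c("stromal",   # d = -10 px
                                "basal",     # d = 0: boundary is epithelial
                                "basal",     # d = 2.5 um
                                "suprabasal"))
  expect_equal(out$dist_um, c(-10, 0, 2.5, 30))
  # partition: every cell gets exactly one layer
  expect_false(anyNA(out$layer))
})

test_that("distances are invariant to horizontal translation", {
  g <- small_geometry(width = 600)
  s <- synthesize_section(default_profile("human"), g, seed = 5)
  labels <- segment_nuclei(s$channels$DNA)
  cells <- extract_cell_table(labels, s$channels["MECP2"],
                              pixel_size = g$pixel_size)
  mc <- estimate_membrane(s$channels$KRT14)
  a <- assign_layers(cells, mc, layer_params())
  shift <- 37L
  cells2 <- cells
  cells2$x <- cells$x + shift
  mc2 <- structure(c(rep(mc[1], shift), as.numeric(mc)),
                   class = "membrane_curve")
  b <- assign_layers(stratiquant:::.as_cell_table(cells2, g$pixel_size),
                     mc2, layer_params())
  expect_equal(b$dist_um, a$dist_um)
  expect_identical(b$layer, a$layer)
})

test_that("delamination requires membrane contact AND displacement", {
  # synthetic label field: one basal cell in the plane, one suprabasal
  # cell without contact, one displaced cell with a membrane stalk
  H <- 120; W <- 200
  membrane <- structure(rep(90, W), class = "membrane_curve")
  labels <- matrix(0L, H, W)
  mkdisc <- function(labels, xc, yc, r, id) {
    for (x in (xc - r):(xc + r)) for (y in (yc - r):(yc + r))
      if ((x - xc)^2 + (y - yc)^2 <= r^2) labels[y + 1, x + 1] <- id
    labels
  }
  for (k in 1:9) labels <- mkdisc(labels, 15 * k, 85, 4, k)  # basal row
  labels <- mkdisc(labels, 100, 40, 4, 10L)                  # suprabasal
  labels <- mkdisc(labels, 60, 72, 4, 11L)                   # displaced
  labels[74:91, 60:61] <- 11L                                # stalk
  channels <- list(DNA = matrix(100, H, W) * (labels > 0))
  cells <- extract_cell_table(as_label_map(labels), channels,
                              pixel_size = 0.5)
  cells <- assign_layers(cells, membrane, layer_params())
  out <- detect_delaminating(cells, as_label_map(labels), membrane,
                             layer_params())
  expect_false(any(out$delaminating[1:9]))   # in the basal plane
  expect_false(isTRUE(out$delaminating[10])) # no membrane connection
  expect_true(out$delaminating[11])          # contact + displacement
})

test_that("layer parameters reject non-positive values", {
  expect_error(layer_params(basal_depth = 0))
  expect_error(layer_params(touch_tol = -1))
})
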