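toy_cells <- function(df, pixel_size = 0.5)
  stratiquant:::.as_cell_table(df, pixel_size)

test_that("reference-protein normalization matches element-wise division", {
  cells <- toy_cells(data.frame(cell_id = 1:5,
                                MECP2 = c(10, 20, 30, 40, 50),
                                H1 = c(2, 4, 5, 8, 10)))
  out <- normalize_reference_protein(cells, "MECP2")
  expect_equal(out$norm_h1_MECP2, c(5, 5, 6, 5, 5))
  # marker = reference: all ones
  out2 <- normalize_reference_protein(cells, "H1")
  expect_equal(out2$norm_h1_H1, rep(1, 5))
  # global gain cancels
  cells2 <- cells; cells2$MECP2 <- 3 * cells2$MECP2; cells2$H1 <- 3 * cells2$H1
  expect_equal(normalize_reference_protein(cells2, "MECP2")$norm_h1_MECP2,
               out$norm_h1_MECP2)
  expect_error(normalize_reference_protein(cells, "MECP2", "H2"),
               "reference")
  cells$H1[2] <- 0
  expect_warning(out3 <- normalize_reference_protein(cells, "MECP2"),
                 "dropped")
  expect_identical(nrow(out3), 4L)
})

test_that("stromal normalization maps the stromal median to one", {
  cells <- toy_cells(data.frame(
    cell_id = 1:24, MECP2 = c(rep(c(2, 4, 6), 7), 8, 8, 8),
    layer = c(rep("stromal", 21), rep("basal", 3))))
  out <- normalize_to_stroma(cells, "MECP2")
  expect_equal(out$norm_stroma_MECP2[22:24], c(2, 2, 2))  # 8 / median 4
  expect_equal(median(out$norm_stroma_MECP2[out$layer == "stromal"]), 1)
  cells2 <- cells; cells2$MECP2 <- 10 * cells2$MECP2
  expect_equal(normalize_to_stroma(cells2, "MECP2")$norm_stroma_MECP2,
               out$norm_stroma_MECP2)
  few <- cells[c(1:5, 22:24), ]
  expect_error(normalize_to_stroma(toy_cells(few), "MECP2"), "20")
})

test_that("mixture gates separate well-split modes almost perfectly", {
  set.seed(1)
  v <- c(rlnorm(500, log(20), 0.3), rlnorm(500, log(400), 0.3))
  truth <- rep(c(FALSE, TRUE), each = 500)
  gate <- place_gate(v)
  expect_identical(gate$method, "mixture")
  expect_lt(mean(apply_gate(v, gate) != truth), 0.02)
  # log-shift equivariance: scaling values scales the threshold
  gate10 <- place_gate(v * 10)
  expect_equal(gate10$threshold, 10 * gate$threshold, tolerance = 1e-6)
})

test_that("degenerate gate fits fall back to Otsu with a tag", {
  set.seed(2)
  v <- rlnorm(300, log(100), 0.05)  # unimodal, tight
  expect_warning(gate <- place_gate(v), "Otsu|otsu")
  expect_identical(gate$method, "otsu")
  expect_error(place_gate(rep(5, 100)), "identical")
  expect_error(place_gate(rlnorm(20)), "50")
})

test_that("capture percentages equal a brute-force recount", {
  set.seed(3)
  n <- 120
  cells <- toy_cells(data.frame(
    cell_id = 1:n,
    XPC = exp(rnorm(n, 5, 1)), ITGB1 = exp(rnorm(n, 5, 1)),
    layer = sample(c("basal", "suprabasal"), n, replace = TRUE)))
  gates <- list(XPC = place_gate(cells$XPC),
                ITGB1 = place_gate(cells$ITGB1))
  cs <- capture_stats(cells, gates, markers = c("XPC", "ITGB1"))
  for (m in c("XPC", "ITGB1")) {   # loop oracle
    npos <- 0; nb <- 0
    for (i in seq_len(n)) if (cells$layer[i] == "basal") {
      nb <- nb + 1
      if (cells[[m]][i] > gates[[m]]$threshold) npos <- npos + 1
    }
    row <- cs$capture[cs$capture$marker == m, ]
    expect_identical(row$n_positive, as.integer(npos))
    expect_equal(row$percent, 100 * npos / nb)
  }
})

test_that("85 basal cells with 75 positive print as 88.24%", {
  cells <- toy_cells(data.frame(
    cell_id = 1:100,
    XPC = c(rep(1000, 75), rep(1, 25)),
    layer = c(rep("basal", 85), rep("suprabasal", 15))))
  gates <- list(XPC = list(threshold = 100, method = "manual"))
  class(gates$XPC) <- "gate"
  cs <- capture_stats(cells, gates, markers = "XPC")
  expect_equal(round(cs$capture$percent, 2), 88.24)
  # all basal positive -> 100%
  cells$XPC[1:85] <- 1000
  cs2 <- capture_stats(cells, gates, markers = "XPC")
  expect_equal(cs2$capture$percent, 100)
  cells$layer <- "suprabasal"
  expect_error(capture_stats(cells, gates, markers = "XPC"), "basal")
})

test_that("fold changes match hand computation and identity cases", {
  cells <- toy_cells(data.frame(
    cell_id = 1:6, M = c(10, 20, 30, 2, 4, 6),
    layer = rep(c("basal", "suprabasal"), each = 3)))
  fc <- fold_change(cells, "M", a = "basal", b = "suprabasal", seed = 1)
  expect_equal(fc$mean_ratio, 20 / 4)
  expect_equal(fc$median_ratio, 20 / 4)
  same <- toy_cells(data.frame(cell_id = 1:6, M = rep(c(1, 2, 3), 2),
                               layer = rep(c("a", "b"), each = 3)))
  expect_equal(fold_change(same, "M", a = "a", b = "b",
                           seed = 1)$mean_ratio, 1)
  expect_error(fold_change(cells, "M", a = "basal", b = "missing"),
               "empty")
  # bootstrap CI is seeded and reproducible
  fc2 <- fold_change(cells, "M", a = "basal", b = "suprabasal", seed = 1)
  expect_identical(fc$ci, fc2$ci)
})

test_that("delamination statistics handle counts, 100% and N/A", {
  cells <- toy_cells(data.frame(
    cell_id = 1:10, MCM2 = c(rep(1000, 2), rep(1, 8)),
    layer = "parabasal",
    delaminating = c(rep(TRUE, 5), rep(FALSE, 5))))
  gates <- list(MCM2 = structure(list(threshold = 100, method = "manual"),
                                 class = "gate"))
  ds <- delamination_stats(cells, gates)
  expect_identical(ds$n_delaminating, 5L)
  expect_equal(ds$percent_positive$percent[
    ds$percent_positive$marker == "MCM2"], 40)       # 2 of 5
  expect_true(is.na(ds$percent_positive$percent[
    ds$percent_positive$marker == "PHH3"]))          # channel absent
  cells$MCM2[1:5] <- 1000
  expect_equal(delamination_stats(cells, gates)$percent_positive$percent[1],
               100)
  cells$delaminating <- FALSE
  ds0 <- delamination_stats(cells, gates)
  expect_identical(ds0$n_delaminating, 0L)
  expect_true(all(is.na(ds0$percent_positive$percent)))
})

test_that("basal clustering separates an 8-fold FTH1 split", {
  set.seed(9)
  n <- 200
  hi <- rep(c(TRUE, FALSE), each = n / 2)
  cells <- toy_cells(data.frame(
    cell_id = 1:n,
    FTH1 = exp(rnorm(n, log(ifelse(hi, 800, 100)), 0.33)),
    MECP2 = exp(rnorm(n, log(1300), 0.33)),
    TP63 = exp(rnorm(n, log(800), 0.33)),
    layer = "basal"))
  cl <- cluster_basal(cells, c("FTH1", "MECP2", "TP63"), k = 2, seed = 1)
  expect_gte(mclust::adjustedRandIndex(cl$labels, hi), 0.8)
  # the summary identifies the FTH1-high population
  expect_gt(max(cl$medians[, "FTH1"]) / min(cl$medians[, "FTH1"]), 3)
  cl1 <- cluster_basal(cells, "FTH1", k = 1, seed = 1)
  expect_identical(unique(cl1$labels), 1L)
  expect_error(cluster_basal(cells, "FTH1", k = 0), "k")
  expect_error(cluster_basal(cells[1:30, ], "FTH1", k = 2), "at least")
})

test_that("pairwise t-tests star unadjusted p-values at alpha", {
  set.seed(5)
  vals <- c(rnorm(20, 0), rnorm(20, 3), rnorm(20, 0.1))
  grp <- rep(c("ref", "far", "near"), each = 20)
  tt <- pairwise_t_vs_ref(vals, grp, ref = "ref")
  expect_true(tt$significant[tt$group == "far"])
  expect_false(tt$significant[tt$group == "near"])
  expect_true(all(tt$p_holm >= tt$p_value, na.rm = TRUE))
})
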