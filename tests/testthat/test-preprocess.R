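test_that("GC baseline correction subtracts the per-bin background median", {
  ann <- toy_annotation(n_genes = 1, n_exons = 1, probes_per_exon = 1,
                        n_bg = 3)
  # background {1,2,3} (median 2) in the probe's GC bin, probe value 5
  v <- matrix(c(5, 1, 2, 3), 4, 4)
  m <- toy_matrix(ann, v)
  out <- gc_baseline_correct(m, ann, min_bin = 3)
  expect_equal(unname(out$values["g1_e1_p1", ]), rep(3, 4))
  # corrected background values are centered too
  expect_equal(unname(out$values["bg2", ]), rep(0, 4))
})

test_that("GC correction is the identity when all bin medians are zero", {
  ann <- toy_annotation(n_bg = 5)
  v <- matrix(rnorm(nrow(ann) * 4), nrow(ann), 4)
  v[ann$is_background, ] <- rep(c(-1, -1, 0, 1, 1), 4)  # median 0 per array
  m <- toy_matrix(ann, v)
  out <- gc_baseline_correct(m, ann, min_bin = 5)
  expect_equal(out$values, m$values)
})

test_that("small GC bins fall back to the global background median", {
  # gene probe in bin 15 with no background probes there; global bg
  # median 1, probe value 4 -> corrected 3
  ann <- toy_annotation(n_genes = 1, n_exons = 1, probes_per_exon = 1,
                        n_bg = 3, gc_gene = 15L, gc_bg = 10L)
  m <- toy_matrix(ann, matrix(c(4, 0, 1, 2), 4, 4))
  out <- gc_baseline_correct(m, ann, min_bin = 3)
  expect_equal(unname(out$values["g1_e1_p1", ]), rep(3, 4))
  # and an annotation without background probes is a hard error
  no_bg <- probe_annotation(as.data.frame(ann)[!ann$is_background, ])
  m2 <- toy_matrix(no_bg, matrix(1, nrow(no_bg), 4))
  expect_error(gc_baseline_correct(m2, no_bg), "no background probes")
})

test_that("GC correction absorbs per-bin constant shifts per array", {
  set.seed(8)
  ann <- toy_annotation(n_genes = 3, n_exons = 2, probes_per_exon = 2,
                        n_bg = 12)
  ann$gc_count <- rep(c(10L, 11L), length.out = nrow(ann))
  v <- matrix(rnorm(nrow(ann) * 4, 5), nrow(ann), 4)
  m <- toy_matrix(ann, v)
  shifted <- v
  for (j in 1:4) {
    for (b in c(10L, 11L)) {
      shifted[ann$gc_count == b, j] <-
        shifted[ann$gc_count == b, j] + rnorm(1, sd = 3)
    }
  }
  m2 <- toy_matrix(ann, shifted)
  expect_equal(gc_baseline_correct(m, ann, min_bin = 2)$values,
               gc_baseline_correct(m2, ann, min_bin = 2)$values)
})

test_that("quantile normalization matches the hand-computed rank means", {
  ann <- toy_annotation(n_genes = 1, n_exons = 1, probes_per_exon = 2,
                        n_bg = 0)
  ann <- probe_annotation(as.data.frame(ann))
  v <- matrix(c(1, 3, 4, 2), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  m <- probe_matrix(v, c(s1 = "A", s2 = "B"))
  out <- quantile_normalize(m)
  expect_equal(unname(out$values[, "s1"]), c(1.5, 3.5))
  expect_equal(unname(out$values[, "s2"]), c(3.5, 1.5))
})

test_that("ties receive the mean of the reference values at tied ranks", {
  v <- matrix(c(2, 2, 1, 3), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  m <- probe_matrix(v, c(s1 = "A", s2 = "B"))
  out <- quantile_normalize(m)
  # reference distribution is (1.5, 2.5); both tied entries get its mean
  expect_equal(unname(out$values[, "s1"]), c(2, 2))
  expect_equal(unname(out$values[, "s2"]), c(1.5, 2.5))
})

test_that("after quantile normalization all columns share one distribution", {
  set.seed(21)
  for (i in 1:5) {
    v <- matrix(rnorm(200 * 6, sd = runif(1, 0.5, 3)), 200, 6,
                dimnames = list(sprintf("p%03d", 1:200),
                                sprintf("s%d", 1:6)))
    m <- probe_matrix(v, setNames(rep(c("A", "B"), each = 3),
                                  colnames(v)))
    out <- quantile_normalize(m)
    ref <- unname(sort(out$values[, 1]))
    for (j in 2:6) expect_equal(unname(sort(out$values[, j])), ref,
                                tolerance = 1e-12)
  }
  # identical columns are a fixed point
  v2 <- matrix(rep(rnorm(50), 4), 50, 4,
               dimnames = list(sprintf("p%02d", 1:50), sprintf("s%d", 1:4)))
  m2 <- probe_matrix(v2, setNames(rep(c("A", "B"), each = 2),
                                  colnames(v2)))
  expect_equal(quantile_normalize(m2)$values, v2)
})

test_that("a single-sample matrix is returned unchanged with a warning", {
  v <- matrix(rnorm(5), 5, 1, dimnames = list(letters[1:5], "s1"))
  m <- structure(list(values = v, conditions = c(s1 = "A")),
                 class = "probe_matrix")
  expect_warning(out <- quantile_normalize(m), "single-sample")
  expect_equal(out$values, v)
})

test_that("probe summarization takes per-unit medians at both levels", {
  ann <- toy_annotation(n_genes = 1, n_exons = 1, probes_per_exon = 3,
                        n_bg = 1)
  v <- matrix(0, nrow(ann), 4)
  v[1:3, 1] <- c(1, 2, 9)   # odd count -> 2
  v[1:3, 2] <- c(1, 3, 3)
  m <- toy_matrix(ann, v)
  gs <- summarize_probes(m, ann, "gene")
  expect_equal(gs$values["g1", 1], 2)
  expect_equal(gs$values["g1", 2], 3)

  # even-count median is the midpoint
  ann2 <- toy_annotation(n_genes = 1, n_exons = 1, probes_per_exon = 2,
                         n_bg = 1)
  m2 <- toy_matrix(ann2, matrix(c(1, 3, 0), 3, 4))
  expect_equal(summarize_probes(m2, ann2, "gene")$values["g1", 1], 2)
})

test_that("summarization matches a brute-force sort-and-pick oracle", {
  set.seed(31)
  ann <- toy_annotation(n_genes = 1, n_exons = 2, probes_per_exon = 3,
                        n_bg = 1)
  v <- matrix(rnorm(nrow(ann) * 4), nrow(ann), 4)
  m <- toy_matrix(ann, v)
  gs <- summarize_probes(m, ann, "gene")
  oracle <- function(x) {  # independent median: sort and pick/average
    s <- sort(x); n <- length(s)
    if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  for (j in 1:4) expect_equal(gs$values["g1", j], oracle(v[1:6, j]))
})

test_that("gene summary equals the median over the pooled exon probe sets", {
  set.seed(32)
  sim <- simulate_experiment(sim_params(n_genes = 6, seed = 3))
  gs <- summarize_probes(sim$matrix, sim$annotation, "gene")
  ann <- sim$annotation
  for (g in rownames(gs$values)) {
    probes <- ann$probe_id[!ann$is_background & ann$gene_id == g]
    pooled <- apply(sim$matrix$values[probes, , drop = FALSE], 2, median)
    expect_equal(unname(gs$values[g, ]), unname(pooled))
  }
})

test_that("units with zero probes in the matrix are excluded with a message", {
  ann <- toy_annotation(n_genes = 2, n_exons = 1, probes_per_exon = 1,
                        n_bg = 1)
  v <- matrix(1, 2, 4,
              dimnames = list(c("g1_e1_p1", "bg1"), NULL))
  samples <- c("A1", "A2", "B1", "B2")
  colnames(v) <- samples
  m <- probe_matrix(v, setNames(rep(c("A", "B"), each = 2), samples))
  expect_message(gs <- summarize_probes(m, ann, "gene"), "zero probes")
  expect_equal(rownames(gs$values), "g1")
})

test_that("presence thresholds interpolate the background order statistics", {
  # background values pooled over the condition: {0,1,2,3} -> 75th
  # percentile 2.25; a probe at 2.5 is above, one at 2.25 is not
  ann <- toy_annotation(n_genes = 2, n_exons = 1, probes_per_exon = 1,
                        n_bg = 2)
  v <- matrix(0, 4, 4, dimnames = list(ann$probe_id,
                                       c("A1", "A2", "B1", "B2")))
  v[c("bg1", "bg2"), c("A1", "A2")] <- c(0, 2, 1, 3)
  v[c("bg1", "bg2"), c("B1", "B2")] <- c(0, 2, 1, 3)
  v["g1_e1_p1", ] <- 2.5
  v["g2_e1_p1", ] <- 2.25
  m <- probe_matrix(v, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  pc <- presence_call(m, ann, min_bin = 1)
  expect_true(pc$present_A[pc$gene_id == "g1"])
  expect_false(pc$present_A[pc$gene_id == "g2"])   # strict >
  expect_equal(pc$frac_A[pc$gene_id == "g1"], 1)
})

test_that("presence needs a strict majority of probe values above threshold", {
  ann <- toy_annotation(n_genes = 1, n_exons = 2, probes_per_exon = 1,
                        n_bg = 2)
  v <- matrix(0, 4, 4, dimnames = list(ann$probe_id,
                                       c("A1", "A2", "B1", "B2")))
  v[c("bg1", "bg2"), ] <- 0   # threshold 0 in every bin
  # 2 probes x 2 samples per condition = 4 values; exactly 2 above -> absent
  v["g1_e1_p1", c("A1", "A2")] <- c(1, 1)
  v["g1_e2_p1", c("A1", "A2")] <- c(-1, -1)
  # 3 of 4 above -> present
  v["g1_e1_p1", c("B1", "B2")] <- c(1, 1)
  v["g1_e2_p1", c("B1", "B2")] <- c(1, -1)
  m <- probe_matrix(v, c(A1 = "A", A2 = "A", B1 = "B", B2 = "B"))
  pc <- presence_call(m, ann, min_bin = 1)
  expect_equal(pc$frac_A, 0.5)
  expect_false(pc$present_A)
  expect_equal(pc$frac_B, 0.75)
  expect_true(pc$present_B)
  expect_true(pc$present_any)
})
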