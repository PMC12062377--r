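sheet <- fixture_sheet()

test_that("median-of-ratios size factors match closed forms", {
  m <- matrix(c(10, 20, 30, 10, 20, 30, 10, 20, 30, 10, 20, 30), ncol = 4)
  expect_equal(unname(size_factors(m)), rep(1, 4))

  m2 <- cbind(A = c(10, 20, 30), B = c(20, 40, 60))
  sf <- size_factors(m2)
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

  # scale equivariance of factor ratios (the overall scale of
  # median-of-ratios factors is set by the geometric mean)
  m3 <- m2; m3[, "A"] <- m3[, "A"] * 5
  sf3 <- size_factors(m3)
  expect_equal(unname((sf3["A"] / sf3["B"]) / (sf["A"] / sf["B"])), 5)

  expect_error(size_factors(cbind(c(0, 5), c(3, 0))), "pseudocount")
})

test_that("Wald fold-changes reproduce exact ratio cases", {
  cnt <- rbind(h1 = c(100, 100, 400, 400),
               h2 = c(200, 200, 200, 200),
               h3 = c(50, 50, 50, 50))
  colnames(cnt) <- sheet$sample_id
  res <- nb_wald_test(cnt, sheet, sf = rep(1, 4), dispersion = 0.01)
  expect_equal(res$log2fc_raw[res$key == "h1"], 2, tolerance = 1e-6)
  expect_equal(res$log2fc_raw[res$key == "h2"], 0, tolerance = 1e-6)
  expect_equal(res$log2fc_raw[res$key == "h3"], 0, tolerance = 1e-6)
  expect_true(all(res$p >= 0 & res$p <= 1))
})

test_that("zero-condition rows get pseudocount fold-changes and flags", {
  cnt <- rbind(ref = c(100, 100, 100, 100),
               z = c(60, 40, 0, 0),
               dead = c(0, 0, 0, 0))
  colnames(cnt) <- sheet$sample_id
  res <- nb_wald_test(cnt, sheet, sf = rep(1, 4), dispersion = 0.01)
  expect_identical(res$status, c("ok", "zero_jumping", "all_zero"))
  expect_equal(res$log2fc_raw[2], log2(1 / 51), tolerance = 1e-9)
  expect_true(is.na(res$p[2]))
})

test_that("WT normalization is a shift and the reference lands at zero", {
  cnt <- rbind(ref = c(100, 100, 250, 250),
               a = c(100, 100, 800, 800),
               b = c(100, 100, 100, 100))
  colnames(cnt) <- sheet$sample_id
  res <- nb_wald_test(cnt, sheet, sf = rep(1, 4), dispersion = 0.01)
  out <- normalize_to_reference(res, "ref")
  expect_equal(out$log2fc_wt[out$key == "ref"], 0)
  expect_equal(out$log2fc_wt, out$log2fc_raw - res$log2fc_raw[1])
  # shift invariance of the normalized values
  res2 <- res; res2$log2fc_raw <- res2$log2fc_raw + 1.7
  out2 <- normalize_to_reference(res2, "ref")
  expect_equal(out2$log2fc_wt, out$log2fc_wt)
  expect_error(normalize_to_reference(res, "missing"), "absent")
})

test_that("jumper classes follow the threshold rules", {
  res <- data.frame(
    key = c("", "hi", "lo", "non", "weak", "nonlow"),
    log2fc_wt = c(0, 3.1, -2.5, -2.6, 1.0, -2.5),
    p = c(0.5, 1e-8, 1e-8, NA, 1e-8, NA),
    stringsAsFactors = FALSE)
  cnt <- rbind(c(500, 500, 500, 500),
               c(100, 100, 900, 900),
               c(300, 300, 10, 10),
               c(40, 20, 0, 0),    # plasmid 60 > 50, zero jumping -> NON
               c(100, 100, 200, 200),
               c(30, 10, 0, 0))    # plasmid 40 fails the >50 floor
  rownames(cnt) <- res$key
  colnames(cnt) <- sheet$sample_id
  out <- classify_jumpers(res, cnt, sheet)
  expect_identical(out$class,
                   c("REFERENCE", "HIGH", "LOW", "NON", "UNCLASSIFIED",
                     "UNCLASSIFIED"))
})

test_that("raising jumping counts never lowers the fold-change", {
  base <- c(120, 80)
  prev <- -Inf
  for (j in c(0, 5, 20, 80, 320, 1280)) {
    cnt <- rbind(ref = c(100, 100, 100, 100),
                 h = c(base, j, j))
    colnames(cnt) <- sheet$sample_id
    res <- nb_wald_test(cnt, sheet, sf = rep(1, 4), dispersion = 0.02)
    lfc <- res$log2fc_raw[res$key == "h"]
    expect_gte(lfc, prev)
    prev <- lfc
  }
})

test_that("replicate QC flags decorrelated libraries", {
  # heterogeneous haplotype frequencies, as in a founder-skewed library
  ref <- fixture_reference_280()
  set.seed(7)
  H <- 300
  w <- rexp(H)
  truth <- data.frame(key = sprintf("%d:A>G", seq_len(H) + 9),
                      n_variants = 1L, nm = 1L, a_h = 0, p_h = w / sum(w),
                      class = "NEUTRAL", stringsAsFactors = FALSE)
  cfg_deep <- sim_config(ref, seed = 71L, depth = 1e5, dispersion = 0.01)
  cfg_shallow <- sim_config(ref, seed = 72L, depth = 1e3, dispersion = 0.01)
  deep <- simulate_counts(truth, cfg_deep)
  shallow <- simulate_counts(truth, cfg_shallow)

  qc_deep <- replicate_qc(deep, sheet)
  qc_shallow <- replicate_qc(shallow, sheet)
  expect_identical(nrow(qc_deep), 2L)
  expect_true(all(qc_deep$spearman > 0.9))
  # correlation improves with depth (same means, independent replicates)
  expect_true(all(qc_deep$spearman > qc_shallow$spearman))

  ident <- deep; ident[, "plasmid_rep2"] <- ident[, "plasmid_rep1"]
  qc_id <- replicate_qc(ident, sheet)
  expect_equal(qc_id$pearson[qc_id$condition == "plasmid"], 1)
  expect_equal(qc_id$spearman[qc_id$condition == "plasmid"], 1)

  set.seed(3)
  perm <- deep; perm[, "jump_rep2"] <- sample(perm[, "jump_rep2"])
  qc_p <- replicate_qc(perm, sheet)
  expect_lt(abs(qc_p$spearman[qc_p$condition == "jumping"]), 0.25)
  expect_true(qc_p$flagged[qc_p$condition == "jumping"])
})

test_that("dispersion estimates recover a constant simulated dispersion", {
  ref <- fixture_reference_280()
  set.seed(11)
  H <- 2000
  truth <- data.frame(key = sprintf("%d:A>G", seq_len(H) + 9),
                      n_variants = 1L, nm = 1L, a_h = 0,
                      p_h = rep(1 / H, H), class = "NEUTRAL",
                      stringsAsFactors = FALSE)
  cfg <- sim_config(ref, seed = 12L, depth = 2e5, dispersion = 0.05)
  cnt <- simulate_counts(truth, cfg)
  ds <- estimate_dispersion(cnt, sheet)
  expect_lt(abs(median(ds$used) - 0.05), 0.03)
})
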