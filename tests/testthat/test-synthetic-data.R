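# one larger library shared across the spectrum checks
ref280 <- fixture_reference_280()
cfg_big <- sim_config(ref280, mu = 0.01, indel_fraction = 0.07,
                      transition_fraction = 0.6, n_clones = 10000L,
                      founder_count = 2L, founder_fraction = 0.35,
                      protected_prefix = 0L, seed = 314L)
mut_big <- mutagenize(cfg_big)

test_that("zero mutation rate yields clones identical to the reference", {
  cfg <- sim_config(ref280, mu = 0, founder_count = 0L, seed = 1L,
                    n_clones = 20L)
  mut <- mutagenize(cfg)
  expect_true(all(vapply(mut$clones, nrow, 1L) == 0L))
  expect_true(all(mut$sequences == ref280$sequence))
})

test_that("mutation burden matches the binomial expectation", {
  # founders excluded from the event-rate check
  founder_tok <- variant_tokens(mut_big$founders)
  n_events <- vapply(mut_big$clones, function(v)
    sum(!(variant_tokens(v) %in% founder_tok)), numeric(1))
  expected <- 280 * 0.01
  se <- sqrt(expected / length(n_events))  # Poisson-scale SE of the mean
  expect_lt(abs(mean(n_events) - expected), 3 * se + 0.02)
})

test_that("default configuration yields 1-6 mutations per element", {
  cfg <- sim_config(synthetic_alu_reference(), seed = 5L, n_clones = 2000L)
  mut <- mutagenize(cfg)
  m <- mean(vapply(mut$clones, nrow, 1L))
  expect_gte(m, 1); expect_lte(m, 6)
})

test_that("protected 5' prefix is never mutated", {
  cfg <- sim_config(ref280, mu = 0.03, protected_prefix = 5L,
                    founder_count = 0L, seed = 17L, n_clones = 500L)
  mut <- mutagenize(cfg)
  pos <- unlist(lapply(mut$clones, function(v) v$pos))
  expect_true(all(pos >= 5L))
})

test_that("transition fraction and founder carriage match the config", {
  snv <- do.call(rbind, mut_big$clones)
  founder_tok <- variant_tokens(mut_big$founders)
  snv <- snv[!(variant_tokens(snv) %in% founder_tok), , drop = FALSE]
  snv <- snv[snv$ref != "" & snv$alt != "", , drop = FALSE]
  tr <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- snv$alt == unname(tr[snv$ref])
  expect_gt(nrow(snv), 1e4)
  se <- sqrt(0.6 * 0.4 / nrow(snv))
  expect_lt(abs(mean(is_ts) - 0.6), 3 * se)

  carry <- vapply(mut_big$clones, function(v)
    founder_tok[1] %in% variant_tokens(v), logical(1))
  se_f <- sqrt(0.35 * 0.65 / length(carry))
  expect_lt(abs(mean(carry) - 0.35), 3 * se_f)
})

test_that("implausible mutation rates are rejected", {
  expect_error(sim_config(ref280, mu = 0.6, seed = 1L), "implausible")
})

test_that("activity is additive with region-dependent effects", {
  effects <- c("10:A>G" = 2, "20:C>T" = -1)
  v2 <- variant_df(c(10L, 20L), c("A", "C"), c("G", "T"))
  expect_equal(assign_activity(v2, effects), 1)
  expect_equal(assign_activity(variant_df(), effects), 0)
  expect_error(assign_activity(variant_df(5L, "A", "C"), effects),
               "no effect")

  # effect magnitude concentrates on SRP-hitting clones
  cfg <- sim_config(ref280, seed = 23L, n_clones = 1000L,
                    founder_count = 0L,
                    effect_in_region = c(mean = 2, sd = 0.5),
                    effect_out_region = c(mean = 0, sd = 0.2))
  mut <- mutagenize(cfg)
  eff <- draw_variant_effects(mut$clones, cfg)
  a <- vapply(mut$clones, assign_activity, numeric(1), effects = eff)
  hits_srp <- vapply(mut$clones, function(v)
    any(in_intervals(v$pos, list(ref280$srp_left, ref280$srp_right))),
    logical(1))
  expect_gt(mean(abs(a[hits_srp])), mean(abs(a[!hits_srp])))
})

test_that("variant positions outside the reference are rejected", {
  cfg <- sim_config(ref280, seed = 1L)
  expect_error(draw_variant_effects(variant_df(400L, "A", "G"), cfg),
               "outside the reference")
})

test_that("selection model: neutral activity leaves frequencies unchanged", {
  truth <- data.frame(key = c("", "9:A>G"), n_variants = c(0L, 1L),
                      nm = c(0L, 1L), a_h = c(0, 0), p_h = c(0.3, 0.7),
                      class = "NEUTRAL", stringsAsFactors = FALSE)
  cfg <- sim_config(ref280, seed = 3L, depth = 2e6, dispersion = 0)
  cnt <- simulate_counts(truth, cfg)
  jf <- cnt[, "jump_rep1"] / sum(cnt[, "jump_rep1"])
  expect_equal(unname(jf), truth$p_h, tolerance = 0.01)
})

test_that("selection model matches the closed form q ~ p * 2^a", {
  truth <- data.frame(key = c("", "9:A>G"), n_variants = c(0L, 1L),
                      nm = c(0L, 1L), a_h = c(0, 1), p_h = c(0.5, 0.5),
                      class = "NEUTRAL", stringsAsFactors = FALSE)
  cfg <- sim_config(ref280, seed = 4L, depth = 2e6, dispersion = 0)
  cnt <- simulate_counts(truth, cfg)
  jf <- cnt[, "jump_rep2"] / sum(cnt[, "jump_rep2"])
  expect_equal(unname(jf), c(1 / 3, 2 / 3), tolerance = 0.01)
  # default layout: two plasmid + two jumping replicate columns
  expect_identical(colnames(cnt), c("plasmid_rep1", "plasmid_rep2",
                                    "jump_rep1", "jump_rep2"))
})

test_that("regressing observed enrichment on true activity gives slope 1", {
  set.seed(71)
  H <- 400
  truth <- data.frame(key = c("", sprintf("%d:A>G", seq_len(H - 1) + 9)),
                      n_variants = 1L, nm = 1L,
                      a_h = c(0, rnorm(H - 1, 0, 1.2)),
                      p_h = rep(1 / H, H), class = "NEUTRAL",
                      stringsAsFactors = FALSE)
  cfg <- sim_config(ref280, seed = 8L, depth = 1e6, dispersion = 0.01)
  cnt <- simulate_counts(truth, cfg)
  pf <- rowMeans(cnt[, 1:2]) / sum(rowMeans(cnt[, 1:2]))
  jf <- rowMeans(cnt[, 3:4]) / sum(rowMeans(cnt[, 3:4]))
  fit <- lm(log2(jf / pf) ~ truth$a_h)
  expect_lt(abs(coef(fit)[2] - 1), 0.05)
})

test_that("emitted alignments validate and round-trip the variant lists", {
  small <- fixture_sim_small()
  recs <- emit_alignments(small$sim$clones, small$ref)
  # SAM validity: M + I lengths equal sequence length; NM = edited bases
  for (i in seq_len(nrow(recs))) {
    cg <- parse_cigar(recs$cigar[i])
    expect_identical(sum(cg$len[cg$op %in% c("M", "I")]),
                     nchar(recs$seq[i]))
    hap <- call_variants(recs[i, ], small$ref)
    expect_identical(hap$key, variant_key(small$sim$clones[[i]]))
  }
})

test_that("identical configs give byte-identical outputs", {
  ref <- synthetic_alu_reference()
  cfg <- sim_config(ref, seed = 77L, n_clones = 100L, depth = 2e3)
  s1 <- simulate_mpja(cfg)
  s2 <- simulate_mpja(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$effects, s2$effects)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write.table(s1$table, f1, sep = "\t"); write.table(s2$table, f2, sep = "\t")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("artifact injection reproduces configured rates and stays consistent", {
  refA <- synthetic_alu_reference("A", seed = 1001L)
  refB <- synthetic_alu_reference("B", seed = 1002L)
  refs <- list(A = refA, B = refB)
  cfgA <- sim_config(refA, seed = 31L, n_clones = 5000L, hop_rate = 0.022,
                     short_frag_rate = 0.05)
  cfgB <- sim_config(refB, seed = 32L, n_clones = 5000L)
  mutA <- mutagenize(cfgA); mutB <- mutagenize(cfgB)
  libs <- list(A = emit_alignments(mutA$clones, refA, "sA"),
               B = emit_alignments(mutB$clones, refB, "sB"))

  # zero rates leave records untouched
  cfg0 <- sim_config(refA, seed = 31L, hop_rate = 0, short_frag_rate = 0)
  out0 <- inject_artifacts(libs, refs, cfg0)
  expect_identical(out0$A[, names(libs$A)], libs$A)

  expect_error(inject_artifacts(libs["A"], refs, cfgA), "two libraries")

  out <- inject_artifacts(libs, refs, cfgA)
  hopped <- mean(out$A$origin_lib != "A")
  se <- sqrt(0.022 * 0.978 / nrow(out$A))
  expect_lt(abs(hopped - 0.022), 3 * se)

  short <- out$A[vapply(seq_len(nrow(out$A)), function(i) {
    cg <- parse_cigar(out$A$cigar[i])
    sum(cg$len[cg$op %in% c("M", "D")]) < 200L
  }, logical(1)), ]
  expect_gt(nrow(short), 0)
  for (i in seq_len(min(nrow(short), 50))) {
    hap <- call_variants(short[i, ], refs[[short$ref_id[i]]])
    expect_lt(hap$aligned_length, 200L)  # tags re-validate after truncation
  }
})
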