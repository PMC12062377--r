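sheet <- fixture_sheet()

# small deterministic table builder: haplotypes with given keys and counts
mk_table <- function(keys, p1, p2, j1, j2) {
  data.frame(reference_id = "R", key = keys, nm = 0L,
             aligned_length = 280L, sequence = "X",
             plasmid_rep1 = p1, plasmid_rep2 = p2,
             jump_rep1 = j1, jump_rep2 = j2, stringsAsFactors = FALSE)
}

test_that("design dimensions and membership match a brute-force build", {
  tab <- mk_table(c("", "10:A>G", "10:A>G;20:C>T", "20:C>T"),
                  c(10, 20, 30, 40), c(11, 21, 31, 41),
                  c(5, 6, 7, 8), c(9, 10, 11, 12))
  des <- build_design(tab, sheet, min_carriers = 1L)
  expect_identical(length(des$y), 8L)  # 4 haplotypes x 2 replicates
  expect_identical(sort(des$tokens), c("10:A>G", "20:C>T"))
  # brute-force membership from the variant lists
  N_oracle <- t(vapply(tab$key, function(k) {
    tok <- variant_tokens(parse_variant_key(k))
    as.integer(des$tokens %in% tok)
  }, integer(length(des$tokens))))
  dimnames(N_oracle) <- dimnames(des$N_hap)
  expect_identical(des$N_hap, N_oracle)
  # each design row carries exactly one nonzero plasmid covariate
  expect_true(all(rowSums(des$plasmid != 0) == 1))

  # carrier threshold empties N
  des3 <- build_design(tab, sheet, min_carriers = 3L)
  expect_identical(length(des3$tokens), 0L)
})

test_that("OLS coefficients match a normal-equations oracle", {
  tab <- mk_table(c("", "10:A>G", "10:A>G;20:C>T", "20:C>T", "30:G>T"),
                  c(10, 20, 30, 40, 50), c(11, 21, 31, 41, 51),
                  c(5, 60, 7, 80, 9), c(9, 10, 110, 12, 13))
  des <- build_design(tab, sheet, min_carriers = 1L)
  fit <- fit_variant_model(des)
  X <- cbind(1, des$plasmid, des$N)
  beta <- solve(t(X) %*% X, t(X) %*% des$y)
  expect_equal(unname(fit$effects$coefficient),
               unname(beta[-(1:3), 1]), tolerance = 1e-8)
  expect_equal(unname(fit$plasmid_slopes),
               unname(beta[2:3, 1]), tolerance = 1e-8)
})

test_that("identity response gives unit plasmid slopes and zero intercept", {
  set.seed(20)
  p1 <- rpois(40, 100); p2 <- rpois(40, 100)
  tab <- mk_table(rep("", 40) , p1, p2, p1, p2)
  tab$key <- ""  # no variants at all
  des <- build_design(tab, sheet, min_carriers = 1L)
  fit <- fit_variant_model(des)
  expect_equal(unname(fit$plasmid_slopes), c(1, 1), tolerance = 1e-8)
  expect_equal(unname(fit$intercept), 0, tolerance = 1e-7)
})

test_that("duplicate variant columns are dropped and reported as aliased", {
  # two variants always co-occurring -> identical N columns
  tab <- mk_table(c("", "10:A>G;20:C>T", "10:A>G;20:C>T", "30:G>T"),
                  c(10, 20, 30, 40), c(11, 21, 31, 41),
                  c(5, 6, 7, 8), c(9, 10, 11, 12))
  des <- build_design(tab, sheet, min_carriers = 1L)
  fit <- fit_variant_model(des)
  expect_identical(length(fit$aliased), 1L)
  expect_true(fit$aliased %in% c("10:A>G", "20:C>T"))
})

test_that("causal variant effects are recovered from simulation", {
  ref <- synthetic_alu_reference()
  chars <- strsplit(ref$sequence, "")[[1]]
  tr <- c(A = "G", G = "A", C = "T", T = "C")
  causal <- 25L
  hs <- data.frame(pos = causal, ref = chars[causal + 1],
                   alt = unname(tr[chars[causal + 1]]), prob = 0.03)
  cfg <- sim_config(ref, seed = 41L, n_clones = 2000L, founder_count = 0L,
                    effect_in_region = c(mean = 0, sd = 0),
                    effect_out_region = c(mean = 0, sd = 0),
                    depth = 1e5, dispersion = 0.01, hotspots = hs,
                    effect_overrides = data.frame(pos = causal, effect = 2))
  sim <- simulate_mpja(cfg)
  fl <- filter_haplotypes(sim$table, sheet)
  des <- build_design(fl$table, sheet, min_carriers = 3L)
  fit <- fit_variant_model(des)
  tok <- sprintf("%d:%s>%s", causal, hs$ref, hs$alt)
  row <- fit$effects[fit$effects$variant == tok, ]
  expect_gt(row$carriers, 20)
  expect_lt(abs(row$coefficient - 2), 2 * row$se)
})

test_that("window profile counts, flags and localizes effects", {
  # 280-base reference -> 276 windows
  tab <- mk_table(c("", "10:A>G", "10:A>G;20:C>T", "20:C>T"),
                  c(10, 20, 30, 40), c(11, 21, 31, 41),
                  c(5, 6, 7, 8), c(9, 10, 11, 12))
  des <- build_design(tab, sheet, min_carriers = 1L)
  wp <- window_profile(des, 280L)
  expect_identical(nrow(wp), 276L)
  expect_identical(wp$center, wp$start + 2L)
  # windows with no variants are flagged undefined
  empty_w <- wp[wp$n_variants == 0, ]
  expect_true(all(is.na(empty_w$coefficient)))
  covered <- wp[wp$start == 8, ]  # window [8,13) holds position 10
  expect_identical(covered$n_variants, 1L)
  expect_false(is.na(covered$coefficient))
})

test_that("coefficients are invariant to row order and replicate swap", {
  tab <- mk_table(c("", "10:A>G", "10:A>G;20:C>T", "20:C>T", "30:G>T"),
                  c(10, 20, 30, 40, 50), c(11, 21, 31, 41, 51),
                  c(5, 60, 7, 80, 9), c(9, 10, 110, 12, 13))
  f1 <- fit_variant_model(build_design(tab, sheet, min_carriers = 1L))
  tab_rev <- tab[rev(seq_len(nrow(tab))), ]
  f2 <- fit_variant_model(build_design(tab_rev, sheet, min_carriers = 1L))
  expect_equal(f1$effects$coefficient, f2$effects$coefficient,
               tolerance = 1e-9)
  # swap replicate labels (and implicitly the covariate columns)
  tab_sw <- tab
  tab_sw[, c("plasmid_rep1", "plasmid_rep2")] <-
    tab[, c("plasmid_rep2", "plasmid_rep1")]
  tab_sw[, c("jump_rep1", "jump_rep2")] <-
    tab[, c("jump_rep2", "jump_rep1")]
  f3 <- fit_variant_model(build_design(tab_sw, sheet, min_carriers = 1L))
  expect_equal(f1$effects$coefficient, f3$effects$coefficient,
               tolerance = 1e-9)
})
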