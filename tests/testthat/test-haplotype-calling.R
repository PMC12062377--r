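small <- fixture_sim_small(seed = 55L, n_clones = 300L)

test_that("caller equivalence: MD route matches direct comparison", {
  # clones at elevated mutation rate with SNVs and 1-bp indels
  cfg <- sim_config(small$ref, seed = 61L, mu = 0.02, indel_fraction = 0.1,
                    n_clones = 1000L, founder_count = 1L)
  mut <- mutagenize(cfg)
  recs <- emit_alignments(mut$clones, small$ref)
  agree <- vapply(seq_len(nrow(recs)), function(i) {
    a <- call_variants(recs[i, ], small$ref)
    b <- call_variants_by_comparison(recs[i, ], small$ref)
    identical(a$key, b$key)
  }, logical(1))
  expect_true(all(agree))
})

test_that("aggregation matches a brute-force dictionary of sequences", {
  recs <- emit_alignments(small$sim$clones, small$ref, sample_id = "s1")
  called <- call_records(recs, small$ref)
  tab <- aggregate_haplotypes(called)
  # oracle: group raw reads by exact sequence identity
  oracle <- table(recs$seq)
  expect_identical(nrow(tab), length(oracle))
  m <- match(tab$sequence, names(oracle))
  expect_false(anyNA(m))
  expect_identical(tab$s1, as.integer(oracle[m]))
  expect_identical(sum(tab$s1), nrow(recs))  # counts conserved
})

test_that("trivial aggregations behave", {
  rec <- emit_alignments(list(variant_df(), variant_df()), small$ref, "s1")
  tab <- aggregate_haplotypes(call_records(rec, small$ref))
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$s1, 2L)
  empty <- aggregate_haplotypes(call_records(rec[0, ], small$ref), "s1")
  expect_identical(nrow(empty), 0L)
})

test_that("filters apply sequentially and match a hand-enumerated oracle", {
  sheet <- fixture_sheet()
  base <- small$sim$table[1, ]
  mk <- function(key, nm, len, p1, p2, j1, j2, seqs = "X") {
    r <- base
    r$key <- key; r$nm <- nm; r$aligned_length <- len; r$sequence <- seqs
    r$plasmid_rep1 <- p1; r$plasmid_rep2 <- p2
    r$jump_rep1 <- j1; r$jump_rep2 <- j2
    r
  }
  tab <- rbind(
    mk("", 0L, 280L, 30, 30, 20, 20, "S1"),          # survives, jumping
    mk("1:A>G", 5L, 280L, 40, 20, 4, 4, "S2"),       # survives, not jumping
    mk("2:A>G", 11L, 280L, 50, 50, 50, 50, "S3"),    # nm cap
    mk("3:A>G", 5L, 150L, 50, 50, 50, 50, "S4"),     # short fragment
    mk("4:A>G", 0L, 280L, 1, 0, 50, 50, "S5"),       # plasmid total <= 2
    mk("5:A>G", 5L, 280L, 60, 0, 0, 0, "S6"))        # survives, zero jumping
  fl <- filter_haplotypes(tab, sheet)
  expect_identical(sort(fl$table$key), sort(c("", "1:A>G", "5:A>G")))
  expect_identical(fl$report$short_fragment, 1L)
  expect_identical(fl$report$mismatch_cap, 1L)
  expect_identical(fl$report$low_plasmid, 1L)
  expect_identical(fl$report$retained, 3L)
  expect_identical(fl$report$input,
                   fl$report$retained + fl$report$short_fragment +
                     fl$report$mismatch_cap + fl$report$index_hopping +
                     fl$report$low_plasmid)
  # jumping detection threshold: > 10 pooled jumping reads
  expect_identical(fl$table$jumping_detected[fl$table$key == ""], TRUE)
  expect_identical(fl$table$jumping_detected[fl$table$key == "1:A>G"], FALSE)
  expect_identical(fl$table$jumping_detected[fl$table$key == "5:A>G"], FALSE)

  # idempotence
  fl2 <- filter_haplotypes(fl$table, sheet)
  expect_identical(fl2$table[names(fl$table)], fl$table)
  expect_identical(fl2$report$retained, fl$report$retained)

  # empty input
  fl0 <- filter_haplotypes(tab[0, ], sheet)
  expect_identical(fl0$report$retained, 0L)
  expect_identical(fl0$report$mismatch_cap, 0L)
})

test_that("index-hopping screen removes exact cross-library collisions", {
  tabA <- small$sim$table
  tabB <- tabA[2:3, ]
  tabB$reference_id <- "other"
  # both copies of an unresolvable native-vs-native collision are dropped
  scr <- screen_index_hopping(list(A = tabA, B = tabB),
                              library_refs = c(A = tabA$reference_id[1],
                                               B = "other"))
  expect_identical(unname(scr$removed["A"]), 2L)
  expect_identical(unname(scr$removed["B"]), 2L)
  expect_false(any(scr$tables$A$sequence %in% tabB$sequence))

  # a hopped row (aligned to the foreign reference) is removed only from
  # the contaminated library; the native copy survives
  hop <- tabA[5, ]
  tabC <- rbind(tabB, hop)
  scr2 <- screen_index_hopping(list(A = tabA, B = tabC),
                               library_refs = c(A = tabA$reference_id[1],
                                                B = "other"))
  expect_identical(unname(scr2$removed["B"]), 3L)
  expect_true(tabA$sequence[5] %in% scr2$tables$A$sequence)
})

test_that("built-in aligner reproduces tags and edit distances", {
  ref <- small$ref
  id <- align_fragment(ref$sequence, ref)
  expect_identical(id$cigar, sprintf("%dM", ref$length))
  expect_identical(id$nm, 0L)

  chars <- strsplit(ref$sequence, "")[[1]]
  one <- chars; one[100] <- setdiff(c("A", "C", "G", "T"), one[100])[1]
  r1 <- align_fragment(paste(one, collapse = ""), ref)
  expect_identical(r1$nm, 1L)

  expect_error(align_fragment("ACGN", ref), "A/C/G/T")

  # NM equals the Levenshtein oracle for interior mutations
  set.seed(91)
  for (i in 1:60) {
    v <- chars
    subs <- sample(10:(ref$length - 10), sample(1:6, 1))
    for (p in subs) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    if (runif(1) < 0.5) v <- v[-sample(10:(ref$length - 10), 1)]
    frag <- paste(v, collapse = "")
    rec <- align_fragment(frag, ref)
    expect_identical(rec$nm,
                     as.integer(utils::adist(frag, ref$sequence)))
    # the emitted record is internally consistent
    hap <- call_variants(rec, ref)
    expect_identical(hap$nm, rec$nm)
  }
})
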