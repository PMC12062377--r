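# Shared fixtures: small deterministic references and configs built in code.

# 280-bp reference with a fixed stream (hand-checkable length arithmetic)
fixture_reference_280 <- function() {
  set.seed(8844L)
  s <- paste(sample(c("A", "C", "G", "T"), 280, replace = TRUE),
             collapse = "")
  alu_reference("AluFix280", s, srp_left = c(15L, 55L),
                srp_right = c(160L, 200L))
}

# tiny 10-base reference used in the worked tag examples
fixture_reference_tiny <- function() {
  alu_reference("tiny", "ACGTACGTAC", srp_left = c(0L, 3L),
                srp_right = c(5L, 8L), core = c(0L, 10L))
}

fixture_sheet <- function() default_sample_sheet(2L)

# a small mutant library shared by calling tests
fixture_sim_small <- function(seed = 99L, n_clones = 150L) {
  ref <- synthetic_alu_reference()
  cfg <- sim_config(ref, seed = seed, n_clones = n_clones, depth = 5e3,
                    dispersion = 0.01)
  list(ref = ref, cfg = cfg, sim = simulate_mpja(cfg))
}

# plain-R Levenshtein oracle (full dynamic program, independent of the
# compiled implementation)
r_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, rep(0L, m))
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j] + (ca[i] != cb[j]),
                        prev[j + 1] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[m + 1]
}

# brute-force hypergeometric upper tail by direct enumeration of the pmf
enum_hyper_upper <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}
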