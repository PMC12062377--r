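#' Simulation configuration for a synthetic MPJA library
#'
#' Defines the generative model used throughout the test suite: an
#' error-prone PCR clone library over one Alu reference, an additive
#' log2-scale activity model concentrated in the SRP binding regions, and
#' negative-binomial sequencing counts under activity-dependent selection.
#'
#' The defaults encode the assay conditions the pipeline is designed for:
#' mutation rate `mu = 8/1000` per base (midpoint of the 1-16 mutations/kb
#' range typical of error-prone PCR kits, giving roughly 1-6 mutations per
#' ~300 bp element), SNV-dominated spectra with a transition bias, a
#' never-mutated 5' prefix of 5 bases (the mutagenesis primer footprint),
#' founder variants fixed early in amplification, two sequencing replicates
#' per condition, ~2.2% index hopping and a small sub-200-bp fragment rate.
#'
#' @param reference An [alu_reference()].
#' @param mu Per-base mutation probability per clone.
#' @param transition_fraction Fraction of SNV events that are transitions.
#' @param indel_fraction Fraction of mutation events that are 1-bp indels
#'   (split evenly between insertion and deletion).
#' @param n_clones Number of clones drawn from the mutagenized pool.
#' @param founder_count Number of variants fixed early in the PCR.
#' @param founder_fraction Fraction of clones carrying each founder variant.
#' @param protected_prefix Number of 5' bases never mutated.
#' @param effect_in_region,effect_out_region Named vectors `c(mean=, sd=)`:
#'   normal distributions of per-variant activity effects (log2 units) for
#'   positions inside / outside the SRP intervals.
#' @param abundance_sd Log-scale standard deviation of per-clone abundance
#'   weights (lognormal). Error-prone PCR libraries are strongly skewed in
#'   count representation (amplification jackpots on top of the founder
#'   effect); 0 gives equal clone abundances.
#' @param depth Expected total reads per sample.
#' @param dispersion Negative-binomial dispersion `phi`
#'   (variance `m + phi * m^2`); 0 gives Poisson counts.
#' @param hop_rate Fraction of records replaced by reads from another
#'   library (index hopping).
#' @param short_frag_rate Fraction of records truncated below 200 aligned
#'   bases.
#' @param n_replicates Sequencing replicates per condition.
#' @param seed Integer RNG seed (mandatory; every stage derives a child
#'   stream from it).
#' @param hotspots Optional `data.frame(pos, ref, alt, prob)` of variants
#'   with elevated per-clone carriage probability (positional mutability
#'   bias of error-prone PCR).
#' @param effect_overrides Optional `data.frame(pos, effect)`: fixed activity
#'   effect for every variant at the listed positions (used to plant known
#'   causal variants in recovery experiments).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(reference,
                       mu = 0.008,
                       transition_fraction = 0.6,
                       indel_fraction = 0.07,
                       n_clones = 2000L,
                       founder_count = 2L,
                       founder_fraction = 0.35,
                       protected_prefix = 5L,
                       effect_in_region = c(mean = 0, sd = 2),
                       effect_out_region = c(mean = 0, sd = 0.25),
                       abundance_sd = 1,
                       depth = 1e5,
                       dispersion = 0.01,
                       hop_rate = 0.022,
                       short_frag_rate = 0.01,
                       n_replicates = 2L,
                       seed,
                       hotspots = NULL,
                       effect_overrides = NULL) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  stopifnot(inherits(reference, "alu_reference"))
  cfg <- list(reference = reference, mu = mu,
              transition_fraction = transition_fraction,
              indel_fraction = indel_fraction,
              n_clones = as.integer(n_clones),
              founder_count = as.integer(founder_count),
              founder_fraction = founder_fraction,
              protected_prefix = as.integer(protected_prefix),
              effect_in_region = effect_in_region,
              effect_out_region = effect_out_region,
              abundance_sd = abundance_sd,
              depth = depth, dispersion = dispersion,
              hop_rate = hop_rate, short_frag_rate = short_frag_rate,
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed),
              hotspots = hotspots, effect_overrides = effect_overrides)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
    if (mu * reference$length > reference$length / 2)
      stop("implausible configuration: expected mutations exceed half the element")
    for (f in c("transition_fraction", "indel_fraction", "founder_fraction",
                "hop_rate", "short_frag_rate"))
      if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
    if (depth <= 0) stop("depth must be positive")
    if (abundance_sd < 0) stop("abundance_sd must be >= 0")
    if (dispersion < 0) stop("dispersion must be >= 0")
    if (n_replicates < 1) stop("n_replicates must be >= 1")
    if (n_clones < 1) stop("n_clones must be >= 1")
  })
  invisible(cfg)
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

draw_alt <- function(ref_base, is_transition) {
  if (is_transition) return(TRANSITION[[ref_base]])
  others <- setdiff(c("A", "C", "G", "T"), c(ref_base, TRANSITION[[ref_base]]))
  sample(others, 1L)
}

#' Draw an error-prone PCR clone library
#'
#' Mutation events are i.i.d. per base with probability `mu` outside the
#' protected 5' prefix; each event is a 1-bp indel with probability
#' `indel_fraction`, otherwise an SNV with a transition bias. Founder
#' variants (drawn once) and hotspot variants are layered on top with their
#' own per-clone carriage probabilities. Variant lists are canonical
#' (position-sorted, indels left-anchored).
#'
#' @param config A [sim_config()].
#' @return List with `clones` (list of canonical variant data frames),
#'   `sequences` (mutant sequence per clone), `founders` (the founder
#'   variant table).
#' @export
mutagenize <- function(config) {
  validate_sim_config(config)
  local_rng(config$seed + 1L)
  ref <- config$reference
  chars <- strsplit(ref$sequence, "")[[1]]
  allowed <- seq.int(config$protected_prefix, ref$length - 1L)

  draw_variant_at <- function(p) {
    r <- runif(1)
    if (r < config$indel_fraction) {
      if (runif(1) < 0.5) {
        variant_df(p, chars[p + 1L], "")                    # deletion
      } else {
        variant_df(p, "", sample(c("A", "C", "G", "T"), 1L))  # insertion
      }
    } else {
      variant_df(p, chars[p + 1L],
                 draw_alt(chars[p + 1L],
                          runif(1) < config$transition_fraction))
    }
  }

  founders <- variant_df()
  if (config$founder_count > 0) {
    fpos <- sample(allowed, config$founder_count)
    founders <- do.call(rbind, lapply(fpos, function(p)
      variant_df(p, chars[p + 1L],
                 draw_alt(chars[p + 1L],
                          runif(1) < config$transition_fraction))))
  }
  hs <- config$hotspots

  clones <- vector("list", config$n_clones)
  for (i in seq_len(config$n_clones)) {
    v <- variant_df()
    if (nrow(founders))
      v <- founders[runif(nrow(founders)) < config$founder_fraction, ,
                    drop = FALSE]
    if (!is.null(hs) && nrow(hs)) {
      carry <- hs[runif(nrow(hs)) < hs$prob, c("pos", "ref", "alt"),
                  drop = FALSE]
      v <- rbind(v, carry)
    }
    hits <- allowed[runif(length(allowed)) < config$mu]
    hits <- setdiff(hits, v$pos)
    if (length(hits))
      v <- rbind(v, do.call(rbind, lapply(hits, draw_variant_at)))
    # at most one substituting/deleting event per position (founders and
    # hotspots take precedence over random events)
    nonins <- variant_kind(v) != "INS"
    dup <- nonins & duplicated(ifelse(nonins, v$pos, NA_integer_),
                               incomparables = NA)
    v <- v[!dup, , drop = FALSE]
    v <- canonicalize_variants(v, ref$sequence)
    # canonicalization may shift an indel into the protected prefix; such
    # events are discarded (the prefix is primer-derived and never varies)
    clones[[i]] <- v[v$pos >= config$protected_prefix, , drop = FALSE]
  }
  sequences <- vapply(clones, function(v) apply_variants(ref$sequence, v),
                      character(1))
  list(clones = clones, sequences = sequences, founders = founders)
}

#' Variant tokens of a variant table
#' @param variants Variant data frame.
#' @return Character vector `"pos:ref>alt"`, one per row.
#' @export
variant_tokens <- function(variants) {
  if (nrow(variants) == 0) return(character())
  sprintf("%d:%s>%s", variants$pos, variants$ref, variants$alt)
}

#' Draw per-variant activity effects
#'
#' Each distinct variant gets one effect, drawn from the in-region
#' distribution when its position lies in either SRP interval and from the
#' out-of-region distribution otherwise; `effect_overrides` pins the effect
#' of every variant at the listed positions.
#'
#' @param variant_list List of variant data frames (one per clone) or a
#'   single variant data frame pooling all distinct variants.
#' @param config A [sim_config()].
#' @return Named numeric vector of effects keyed by `"pos:ref>alt"`.
#' @export
draw_variant_effects <- function(variant_list, config) {
  local_rng(config$seed + 2L)
  if (is.data.frame(variant_list)) variant_list <- list(variant_list)
  all_v <- do.call(rbind, variant_list)
  if (is.null(all_v) || nrow(all_v) == 0) return(setNames(numeric(), character()))
  if (any(all_v$pos < 0 | all_v$pos > config$reference$length))
    stop("variant position outside the reference")
  tok <- variant_tokens(all_v)
  keep <- !duplicated(tok)
  all_v <- all_v[keep, , drop = FALSE]
  tok <- tok[keep]
  o <- order(tok)  # draw in a stable order so effects are reproducible
  all_v <- all_v[o, , drop = FALSE]; tok <- tok[o]
  in_srp <- in_intervals(all_v$pos,
                         list(config$reference$srp_left,
                              config$reference$srp_right))
  eff <- ifelse(in_srp,
                rnorm(nrow(all_v), config$effect_in_region[["mean"]],
                      config$effect_in_region[["sd"]]),
                rnorm(nrow(all_v), config$effect_out_region[["mean"]],
                      config$effect_out_region[["sd"]]))
  if (!is.null(config$effect_overrides)) {
    ov <- config$effect_overrides
    hit <- match(all_v$pos, ov$pos)
    eff[!is.na(hit)] <- ov$effect[hit[!is.na(hit)]]
  }
  setNames(eff, tok)
}

#' Additive activity of a haplotype
#'
#' @param variants Canonical variant data frame of one haplotype.
#' @param effects Named effect vector from [draw_variant_effects()].
#' @return The haplotype activity `a_h` in log2 units (0 for the reference).
#' @export
assign_activity <- function(variants, effects) {
  if (nrow(variants) == 0) return(0)
  tok <- variant_tokens(variants)
  miss <- setdiff(tok, names(effects))
  if (length(miss)) stop("no effect drawn for variant(s): ",
                         paste(miss, collapse = ", "))
  sum(effects[tok])
}

#' Ground-truth table of a simulated library
#'
#' Collapses clones into distinct haplotypes with true plasmid frequency
#' `p_h` (lognormal per-clone abundance weights summed over identical
#' clones, emulating PCR amplification skew), true activity `a_h` and a
#' true class label (`HIGH` if `a_h > 2`, `LOW` if `a_h < -2`,
#' `REFERENCE`, else `NEUTRAL`).
#'
#' @param clones Clone list from [mutagenize()].
#' @param effects Effect vector from [draw_variant_effects()].
#' @param config A [sim_config()].
#' @return Data frame (`key`, `n_variants`, `nm`, `a_h`, `p_h`, `class`)
#'   plus a `variants` attribute: named list of variant tables by key.
#' @export
build_truth <- function(clones, effects, config) {
  local_rng(config$seed + 5L)
  keys <- vapply(clones, variant_key, character(1))
  w <- if (config$abundance_sd > 0)
    exp(rnorm(length(clones), 0, config$abundance_sd)) else rep(1, length(clones))
  ukeys <- sort(unique(keys))
  # rowsum with explicit levels: the reference key "" is not indexable by name
  wsum <- as.numeric(rowsum(w, factor(keys, levels = ukeys)))
  vmap <- clones[match(ukeys, keys)]
  names(vmap) <- ukeys
  a_h <- vapply(vmap, assign_activity, numeric(1), effects = effects)
  truth <- data.frame(
    key = ukeys,
    n_variants = vapply(vmap, nrow, integer(1)),
    nm = vapply(vmap, variant_nm, integer(1)),
    a_h = a_h,
    p_h = as.numeric(wsum) / sum(w),
    stringsAsFactors = FALSE)
  truth$class <- ifelse(truth$key == "", "REFERENCE",
                        ifelse(truth$a_h > 2, "HIGH",
                               ifelse(truth$a_h < -2, "LOW", "NEUTRAL")))
  attr(truth, "variants") <- vmap
  truth
}

#' Simulate plasmid and jumping sequencing counts
#'
#' Plasmid counts are NB with mean `depth * p_h`; jumping counts are NB with
#' mean `depth * q_h` where `q_h` is proportional to `p_h * 2^(a_h)`
#' (activity-dependent selection), normalized to sum to one. Replicates are
#' independent; variance is `m + phi m^2`.
#'
#' @param truth Ground-truth table from [build_truth()].
#' @param config A [sim_config()].
#' @return Integer matrix, rows = haplotype keys, columns
#'   `plasmid_rep1..n, jump_rep1..n`.
#' @export
simulate_counts <- function(truth, config) {
  local_rng(config$seed + 3L)
  stopifnot(abs(sum(truth$p_h) - 1) < 1e-8)
  q <- truth$p_h * 2^truth$a_h
  q <- q / sum(q)
  nr <- config$n_replicates
  draw <- function(mean_vec) {
    if (config$dispersion > 0)
      rnbinom(length(mean_vec), mu = mean_vec, size = 1 / config$dispersion)
    else rpois(length(mean_vec), mean_vec)
  }
  cols <- c(sprintf("plasmid_rep%d", seq_len(nr)),
            sprintf("jump_rep%d", seq_len(nr)))
  out <- matrix(0L, nrow(truth), 2L * nr, dimnames = list(truth$key, cols))
  for (r in seq_len(nr)) {
    out[, r] <- draw(config$depth * truth$p_h)
    out[, nr + r] <- draw(config$depth * q)
  }
  out
}

#' Emit SAM-style alignment records for clones
#'
#' One record per clone, carrying POS/CIGAR/MD/NM consistent with its
#' variant list; the round trip through [call_variants()] recovers the exact
#' canonical variant list.
#'
#' @param clones List of canonical variant data frames.
#' @param reference An [alu_reference()].
#' @param sample_id Sample label stored on the records.
#' @param qname_prefix Prefix for read names.
#' @return Alignment-record data frame (0-based `pos`).
#' @export
emit_alignments <- function(clones, reference, sample_id = "sample1",
                            qname_prefix = "clone") {
  rows <- lapply(seq_along(clones), function(i) {
    tg <- build_alignment_tags(clones[[i]], reference)
    data.frame(qname = sprintf("%s_%05d", qname_prefix, i),
               ref_id = reference$id, pos = tg$pos, cigar = tg$cigar,
               md = tg$md, nm = tg$nm, seq = tg$seq,
               sample_id = sample_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expand a count matrix into per-sample alignment records
#'
#' Used for small end-to-end runs where the SAM route is exercised: each
#' haplotype contributes `count` identical records per sample.
#'
#' @param truth Ground-truth table (carries the variant lists).
#' @param counts Count matrix from [simulate_counts()].
#' @param reference An [alu_reference()].
#' @return Named list of record data frames, one per sample column.
#' @export
counts_to_records <- function(truth, counts, reference) {
  vmap <- attr(truth, "variants")
  out <- list()
  for (smp in colnames(counts)) {
    idx <- rep(seq_len(nrow(counts)), counts[, smp])
    if (length(idx) == 0) {
      out[[smp]] <- emit_alignments(list(), reference, smp)
      next
    }
    recs <- lapply(unique(idx), function(i) {
      tg <- build_alignment_tags(vmap[[i]], reference)
      n <- sum(idx == i)
      data.frame(qname = sprintf("%s_h%05d_r%05d", smp, i, seq_len(n)),
                 ref_id = reference$id, pos = tg$pos, cigar = tg$cigar,
                 md = tg$md, nm = tg$nm, seq = tg$seq, sample_id = smp,
                 stringsAsFactors = FALSE)
    })
    out[[smp]] <- do.call(rbind, recs)
  }
  out
}

#' Inject index-hopping and short-fragment artifacts
#'
#' Replaces about `hop_rate` of each library's records with records drawn
#' from a different library (the hopped record keeps its own reference and
#' tags but adopts the contaminated library's sample label), and truncates
#' about `short_frag_rate` of records below 200 aligned bases with
#' CIGAR/MD/NM rebuilt consistently. Origins are recorded in an
#' `origin_lib` column for ground-truth checks.
#'
#' @param libs Named list of record data frames, one per library.
#' @param references Named list of [alu_reference()] by reference id.
#' @param config A [sim_config()] (supplies `hop_rate`, `short_frag_rate`,
#'   `seed`).
#' @return Named list of record data frames with artifacts applied.
#' @export
inject_artifacts <- function(libs, references, config) {
  local_rng(config$seed + 4L)
  if (config$hop_rate > 0 && length(libs) < 2)
    stop("index hopping requires at least two libraries")
  for (nm in names(libs)) libs[[nm]]$origin_lib <- nm
  out <- libs
  if (config$hop_rate > 0) {
    for (nm in names(libs)) {
      n <- nrow(out[[nm]])
      hop <- which(runif(n) < config$hop_rate)
      if (length(hop) == 0) next
      donors <- setdiff(names(libs), nm)
      for (i in hop) {
        d <- if (length(donors) == 1) donors else sample(donors, 1L)
        j <- sample.int(nrow(libs[[d]]), 1L)
        rec <- libs[[d]][j, , drop = FALSE]
        rec$sample_id <- out[[nm]]$sample_id[i]
        rec$origin_lib <- d
        rec$qname <- paste0(out[[nm]]$qname[i], "_hop")
        out[[nm]][i, ] <- rec
      }
    }
  }
  if (config$short_frag_rate > 0) {
    for (nm in names(out)) {
      n <- nrow(out[[nm]])
      cut <- which(runif(n) < config$short_frag_rate)
      for (i in cut) {
        rec <- out[[nm]][i, , drop = FALSE]
        ref <- references[[rec$ref_id]]
        hap <- call_variants(rec, ref)
        t_len <- sample(120:199, 1L)
        tg <- build_alignment_tags(hap$variants, ref, span = c(0L, t_len))
        out[[nm]]$pos[i] <- tg$pos
        out[[nm]]$cigar[i] <- tg$cigar
        out[[nm]]$md[i] <- tg$md
        out[[nm]]$nm[i] <- tg$nm
        out[[nm]]$seq[i] <- tg$seq
      }
    }
  }
  out
}

#' One-shot synthetic MPJA dataset
#'
#' Runs mutagenesis, effect assignment, ground truth and count simulation
#' for one reference. Deterministic given the config (child seeds are
#' derived from `config$seed` per stage).
#'
#' @param config A [sim_config()].
#' @return List: `config`, `reference`, `clones`, `effects`, `truth`,
#'   `counts`, `table` (a haplotype count table in the caller's output
#'   format, built from the ground truth).
#' @export
simulate_mpja <- function(config) {
  mut <- mutagenize(config)
  effects <- draw_variant_effects(mut$clones, config)
  truth <- build_truth(mut$clones, effects, config)
  counts <- simulate_counts(truth, config)
  list(config = config, reference = config$reference, clones = mut$clones,
       founders = mut$founders, effects = effects, truth = truth,
       counts = counts,
       table = truth_to_table(truth, counts, config$reference))
}

#' Haplotype count table from ground truth
#'
#' Bypasses the SAM route for large simulations: builds the same table
#' structure [aggregate_haplotypes()] would produce from alignment records.
#'
#' @param truth Ground-truth table.
#' @param counts Count matrix.
#' @param reference An [alu_reference()].
#' @return Haplotype table data frame.
#' @export
truth_to_table <- function(truth, counts, reference) {
  vmap <- attr(truth, "variants")
  # positional indexing: the reference haplotype's key is "" and empty
  # names cannot be used for list lookup
  seqs <- vapply(seq_len(nrow(truth)), function(i)
    apply_variants(reference$sequence, vmap[[i]]), character(1))
  out <- data.frame(reference_id = reference$id, key = truth$key,
                    nm = truth$nm, aligned_length = reference$length,
                    sequence = unname(seqs), stringsAsFactors = FALSE)
  cbind(out, as.data.frame(counts, row.names = NULL))
}

#' Synthetic genomic AluS-like element set
#'
#' Generates diverged copies of a reference element as a stand-in for a
#' genomic AluS collection (substitutions at a per-element divergence drawn
#' uniformly from `divergence`, plus occasional 1-bp indels). Elements are
#' labelled `g0001...`; this is synthetic data, not genome sequence.
#'
#' @param reference An [alu_reference()].
#' @param n Number of elements.
#' @param divergence Range of per-base substitution probability.
#' @param indel_prob Per-base 1-bp indel probability.
#' @param seed RNG seed.
#' @return Named character vector of sequences.
#' @export
simulate_genomic_alus <- function(reference, n = 100,
                                  divergence = c(0.02, 0.10),
                                  indel_prob = 0.001, seed = 1L) {
  local_rng(seed)
  chars <- strsplit(reference$sequence, "")[[1]]
  L <- length(chars)
  out <- character(n)
  for (i in seq_len(n)) {
    d <- runif(1, divergence[1], divergence[2])
    s <- chars
    subs <- which(runif(L) < d)
    for (p in subs) s[p] <- draw_alt(chars[p], runif(1) < 0.5)
    dels <- which(runif(L) < indel_prob)
    if (length(dels)) s[dels] <- ""
    out[i] <- paste(s, collapse = "")
  }
  setNames(out, sprintf("g%04d", seq_len(n)))
}
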