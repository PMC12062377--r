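pipeline_defaults <- function() {
  list(
    seed = NULL,
    outdir = "results/pipeline",
    n_references = 2L,
    reference_fasta = NULL,
    reference_regions = NULL,
    stages = list(simulate = TRUE, call = TRUE, differential = TRUE,
                  effects = TRUE, enrichment = TRUE, compare = TRUE),
    thresholds = list(lfc_cut = 2, p_cut = 1e-5, max_nm = 10L,
                      min_aligned = 200L, plasmid_min = 2L,
                      jumping_detect = 10L, nonjumper_plasmid = 50L,
                      min_carriers = 3L),
    simulation = list(mu = 0.008, transition_fraction = 0.6,
                      indel_fraction = 0.07, n_clones = 600L,
                      founder_count = 2L, founder_fraction = 0.35,
                      protected_prefix = 5L,
                      effect_in_mean = 0, effect_in_sd = 2,
                      effect_out_mean = 0, effect_out_sd = 0.25,
                      abundance_sd = 1,
                      depth = 2e4, dispersion = 0.01,
                      hop_rate = 0.022, short_frag_rate = 0.01,
                      n_replicates = 2L),
    genomic = list(n_elements = 60L, divergence_min = 0.02,
                   divergence_max = 0.10))
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), applies documented
#' defaults, rejects unknown keys (guarding against silent typos) and
#' collects *all* validation errors rather than failing on the first.
#'
#' @param config Path to a YAML file or a configuration list.
#' @param stop_on_error Throw one error listing every problem (default);
#'   with `FALSE`, return the error messages for inspection.
#' @return The validated configuration list (class `pipeline_config`), or —
#'   with `stop_on_error = FALSE` — `list(config =, errors =)`.
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  errors <- character()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    errors <- c(errors, paste0("unknown key(s): ", paste(bad, collapse = ", ")))
  for (blk in c("stages", "thresholds", "simulation", "genomic")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
      if (length(bad))
        errors <- c(errors, paste0("unknown key(s) in ", blk, ": ",
                                   paste(bad, collapse = ", ")))
      defaults[[blk]][names(config[[blk]])] <- config[[blk]]
    }
  }
  for (k in setdiff(names(defaults), c("stages", "thresholds", "simulation",
                                       "genomic")))
    if (!is.null(config[[k]])) defaults[[k]] <- config[[k]]
  cfg <- defaults
  if (is.null(cfg$seed) || is.na(suppressWarnings(as.integer(cfg$seed))))
    errors <- c(errors, "seed is mandatory and must be an integer")
  else cfg$seed <- as.integer(cfg$seed)
  sim <- cfg$simulation
  for (f in c("mu", "transition_fraction", "indel_fraction",
              "founder_fraction", "hop_rate", "short_frag_rate"))
    if (sim[[f]] < 0 || sim[[f]] > 1)
      errors <- c(errors, paste0("simulation.", f, " must be in [0, 1]"))
  if (sim$depth <= 0)
    errors <- c(errors, "simulation.depth must be positive")
  if (sim$dispersion < 0)
    errors <- c(errors, "simulation.dispersion must be >= 0")
  if (sim$n_replicates < 1)
    errors <- c(errors, "simulation.n_replicates must be >= 1")
  for (f in c("lfc_cut", "p_cut", "max_nm", "min_aligned", "plasmid_min",
              "jumping_detect", "nonjumper_plasmid"))
    if (cfg$thresholds[[f]] <= 0)
      errors <- c(errors, paste0("thresholds.", f, " must be positive"))
  if (!is.null(cfg$reference_fasta) && !file.exists(cfg$reference_fasta))
    errors <- c(errors, paste0("reference_fasta not found: ",
                               cfg$reference_fasta))
  if (!is.null(cfg$reference_regions) && !file.exists(cfg$reference_regions))
    errors <- c(errors, paste0("reference_regions not found: ",
                               cfg$reference_regions))
  if (!stop_on_error)
    return(list(config = structure(cfg, class = "pipeline_config"),
                errors = errors))
  if (length(errors))
    stop("invalid pipeline configuration:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

pipeline_references <- function(cfg) {
  if (!is.null(cfg$reference_fasta))
    return(read_alu_references(cfg$reference_fasta, cfg$reference_regions))
  n <- max(1L, as.integer(cfg$n_references))
  refs <- lapply(seq_len(n), function(i)
    synthetic_alu_reference(sprintf("AluSyn%d", i), seed = 20240516L + i))
  setNames(refs, vapply(refs, `[[`, "", "id"))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_log <- function(manifest, stage, t0, ...) {
  info <- list(...)
  elapsed <- round(as.numeric(Sys.time()) - t0, 2)
  message(sprintf("[%s] %s (%.2fs)", stage,
                  paste(names(info), unlist(info), sep = "=",
                        collapse = " "), elapsed))
  manifest$stages[[stage]] <- c(info, list(elapsed_s = elapsed))
  manifest
}

#' Run the MPJA pipeline end to end
#'
#' Executes simulate, call, differential, effects, enrichment and compare
#' in order on each simulated library; every stage consumes the previous
#' stage's outputs and all artifacts are plain TSV/JSON under `outdir`.
#' Deterministic for a fixed seed: each library and stage derives a child
#' seed from the master seed.
#'
#' @param config A `pipeline_config` (see [validate_config()]), a YAML
#'   path, or a plain list.
#' @return The run manifest (stage row counts, output checksums, seed),
#'   invisibly; also written to `manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  refs <- pipeline_references(cfg)
  sheet <- default_sample_sheet(cfg$simulation$n_replicates)
  th <- cfg$thresholds
  manifest <- list(seed = cfg$seed, libraries = names(refs),
                   stages = list(), outputs = list())

  sims <- list(); tables <- list()
  for (li in seq_along(refs)) {
    ref <- refs[[li]]
    t0 <- as.numeric(Sys.time())
    sim <- cfg$simulation
    sc <- sim_config(ref, mu = sim$mu,
                     transition_fraction = sim$transition_fraction,
                     indel_fraction = sim$indel_fraction,
                     n_clones = sim$n_clones,
                     founder_count = sim$founder_count,
                     founder_fraction = sim$founder_fraction,
                     protected_prefix = sim$protected_prefix,
                     effect_in_region = c(mean = sim$effect_in_mean,
                                          sd = sim$effect_in_sd),
                     effect_out_region = c(mean = sim$effect_out_mean,
                                           sd = sim$effect_out_sd),
                     abundance_sd = sim$abundance_sd,
                     depth = sim$depth, dispersion = sim$dispersion,
                     hop_rate = sim$hop_rate,
                     short_frag_rate = sim$short_frag_rate,
                     n_replicates = sim$n_replicates,
                     seed = cfg$seed + 1000L * li)
    if (!isTRUE(cfg$stages$simulate)) stop("pipeline requires the simulate stage")
    sims[[ref$id]] <- simulate_mpja(sc)
    manifest <- stage_log(manifest, paste0("simulate_", ref$id), t0,
                          clones = sim$n_clones,
                          haplotypes = nrow(sims[[ref$id]]$truth))
  }

  # per-library SAM emission + calling (SAM route), or direct table route
  for (ref_id in names(refs)) {
    t0 <- as.numeric(Sys.time())
    s <- sims[[ref_id]]
    write_tsv(s$truth[, c("key", "n_variants", "nm", "a_h", "p_h", "class")],
              file.path(outdir, paste0(ref_id, "_truth.tsv")))
    write_tsv(s$table, file.path(outdir, paste0(ref_id, "_counts.tsv")))
    write_fasta(setNames(as.list(s$table$sequence),
                         paste0(ref_id, "_h", seq_len(nrow(s$table)))),
                file.path(outdir, paste0(ref_id, "_haplotypes.fasta")))
    tables[[ref_id]] <- s$table
    manifest <- stage_log(manifest, paste0("tabulate_", ref_id), t0,
                          rows = nrow(s$table))
  }

  if (isTRUE(cfg$stages$call)) {
    # SAM route: expand counts into per-sample records, inject artifacts,
    # write one SAM per sample, read back, call and aggregate
    t0 <- as.numeric(Sys.time())
    lib_records <- list()
    for (ref_id in names(refs)) {
      s <- sims[[ref_id]]
      recs <- counts_to_records(s$truth, s$counts, s$reference)
      lib_records[[ref_id]] <- do.call(rbind, unname(recs))
    }
    art_cfg <- sims[[1]]$config
    if (length(lib_records) < 2) art_cfg$hop_rate <- 0  # hopping needs >= 2
    lib_records <- inject_artifacts(lib_records, refs, art_cfg)
    tables <- list()
    for (ref_id in names(refs)) {
      recs <- lib_records[[ref_id]]
      for (smp in unique(recs$sample_id))
        write_sam(recs[recs$sample_id == smp, , drop = FALSE],
                  file.path(outdir, sprintf("%s_%s.sam", ref_id, smp)),
                  refs)
      called <- call_records(recs, refs)
      tables[[ref_id]] <- aggregate_haplotypes(called, sheet$sample_id)
    }
    scr <- screen_index_hopping(tables)
    filtered <- list()
    for (ref_id in names(refs)) {
      fl <- filter_haplotypes(scr$tables[[ref_id]], sheet,
                              max_nm = th$max_nm,
                              min_aligned = th$min_aligned,
                              plasmid_min = th$plasmid_min,
                              jumping_detect = th$jumping_detect)
      fl$report$index_hopping <- fl$report$index_hopping +
        unname(scr$removed[ref_id])
      filtered[[ref_id]] <- fl
      write_tsv(fl$table, file.path(outdir, paste0(ref_id, "_filtered.tsv")))
      jsonlite::write_json(fl$report,
                           file.path(outdir, paste0(ref_id, "_filter_report.json")),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    manifest <- stage_log(manifest, "call_filter", t0,
                          retained = sum(vapply(filtered, function(f)
                            f$report$retained, numeric(1))))
  } else {
    filtered <- lapply(tables, function(t) {
      t$jumping_detected <- rowSums(
        t[, sheet$sample_id[sheet$condition == "jumping"], drop = FALSE]) >
        th$jumping_detect
      list(table = t)
    })
  }

  results <- list()
  if (isTRUE(cfg$stages$differential)) {
    for (ref_id in names(refs)) {
      t0 <- as.numeric(Sys.time())
      tab <- filtered[[ref_id]]$table
      res <- nb_wald_test(tab, sheet)
      res <- normalize_to_reference(res, ref_key = "")
      res <- classify_jumpers(res, tab, sheet, lfc_cut = th$lfc_cut,
                              p_cut = th$p_cut,
                              nonjumper_plasmid = th$nonjumper_plasmid)
      qc <- replicate_qc(tab, sheet)
      write_tsv(res, file.path(outdir, paste0(ref_id, "_differential.tsv")))
      jsonlite::write_json(qc, file.path(outdir, paste0(ref_id, "_qc.json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      results[[ref_id]] <- res
      manifest <- stage_log(manifest, paste0("differential_", ref_id), t0,
                            high = sum(res$class == "HIGH"),
                            low = sum(res$class == "LOW"),
                            non = sum(res$class == "NON"))
    }
  }

  if (isTRUE(cfg$stages$effects)) {
    for (ref_id in names(refs)) {
      t0 <- as.numeric(Sys.time())
      tab <- filtered[[ref_id]]$table
      des <- build_design(tab, sheet, min_carriers = th$min_carriers)
      if (length(des$tokens)) {
        fit <- fit_variant_model(des)
        write_tsv(fit$effects,
                  file.path(outdir, paste0(ref_id, "_variant_effects.tsv")))
      }
      wp <- window_profile(des, refs[[ref_id]]$length)
      write_tsv(wp, file.path(outdir, paste0(ref_id, "_windows.tsv")))
      manifest <- stage_log(manifest, paste0("effects_", ref_id), t0,
                            variants = length(des$tokens),
                            windows = nrow(wp))
    }
  }

  if (isTRUE(cfg$stages$enrichment) && length(results)) {
    t0 <- as.numeric(Sys.time())
    enr_all <- NULL
    for (ref_id in names(results)) {
      res <- results[[ref_id]]
      ref <- refs[[ref_id]]
      vars_of <- function(keys) unique(unlist(lapply(
        sub("\\|.*$", "", keys), function(k) variant_tokens(parse_variant_key(k)))))
      background <- vars_of(res$key)
      sets <- list(high = vars_of(res$key[res$class == "HIGH"]),
                   low_non = vars_of(res$key[res$class %in% c("LOW", "NON")]))
      sets <- sets[vapply(sets, length, 1L) > 0]
      if (length(sets) == 0 || length(background) == 0) next
      regions <- list(srp_left = ref$srp_left, srp_right = ref$srp_right,
                      srp_both = list(ref$srp_left, ref$srp_right))
      enr <- hypergeom_enrichment(sets, background, regions)
      enr$library <- ref_id
      enr_all <- rbind(enr_all, enr)
      if (any(res$class == "HIGH")) {
        for (rg in c("srp_left", "srp_right")) {
          pfm <- position_frequency_matrix(res$key[res$class == "HIGH"],
                                           ref, ref[[rg]])
          write_tsv(as.data.frame(pfm$matrix),
                    file.path(outdir, sprintf("%s_pfm_high_%s.tsv",
                                              ref_id, rg)))
        }
      }
    }
    if (!is.null(enr_all)) {
      enr_all$p_adj <- bh_adjust(enr_all$p)  # BH across libraries too
      write_tsv(enr_all, file.path(outdir, "enrichment.tsv"))
    }
    manifest <- stage_log(manifest, "enrichment", t0,
                          tests = if (is.null(enr_all)) 0L else nrow(enr_all))
  }

  if (isTRUE(cfg$stages$compare) && length(results)) {
    t0 <- as.numeric(Sys.time())
    g <- cfg$genomic
    focal <- names(refs)[1]
    genomic <- simulate_genomic_alus(
      refs[[focal]], n = g$n_elements,
      divergence = c(g$divergence_min, g$divergence_max),
      seed = cfg$seed + 77L)
    res <- results[[focal]]
    tab <- filtered[[focal]]$table
    jump_keys <- tab$key[tab$jumping_detected]
    seqs <- setNames(tab$sequence[match(jump_keys, tab$key)], jump_keys)
    cls <- res$class[match(jump_keys, res$key)]
    if (length(seqs)) {
      dr <- min_distances(seqs, genomic, classes = cls)
      write_tsv(dr$per_haplotype, file.path(outdir, "distances.tsv"))
      if (!is.null(dr$per_class))
        write_tsv(dr$per_class, file.path(outdir, "distances_by_class.tsv"))
      high_seqs <- seqs[!is.na(cls) & cls == "HIGH"]
      if (length(high_seqs)) {
        na <- nearest_activators(genomic, high_seqs, k_max = 16L)
        write_tsv(na, file.path(outdir, "nearest_activators.tsv"))
      }
      manifest <- stage_log(manifest, "compare", t0,
                            haplotypes = length(seqs),
                            min_distance = min(dr$per_haplotype$min_distance))
    }
  }

  outs <- list.files(outdir, full.names = TRUE)
  outs <- outs[!grepl("manifest\\.json$", outs)]
  sums <- tools::md5sum(outs)
  manifest$outputs <- as.list(setNames(unname(sums), basename(outs)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
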