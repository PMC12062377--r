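#' Sample sheet constructor
#'
#' @param sample_id Sample identifiers matching count-table columns.
#' @param condition `"plasmid"` or `"jumping"` per sample.
#' @param replicate Integer replicate index per sample.
#' @return Validated sample-sheet data frame.
#' @export
sample_sheet <- function(sample_id, condition, replicate) {
  if (!all(condition %in% c("plasmid", "jumping")))
    stop("condition must be 'plasmid' or 'jumping'")
  data.frame(sample_id = as.character(sample_id),
             condition = condition, replicate = as.integer(replicate),
             stringsAsFactors = FALSE)
}

#' Default sample sheet for simulator column names
#' @param n_replicates Replicates per condition.
#' @return A [sample_sheet()] for `plasmid_rep*` / `jump_rep*` columns.
#' @export
default_sample_sheet <- function(n_replicates = 2L) {
  sample_sheet(
    c(sprintf("plasmid_rep%d", seq_len(n_replicates)),
      sprintf("jump_rep%d", seq_len(n_replicates))),
    rep(c("plasmid", "jumping"), each = n_replicates),
    rep(seq_len(n_replicates), 2L))
}

#' Call haplotypes for a set of alignment records
#'
#' Applies [call_variants()] to every record. Rows not spanning the full
#' reference keep their variant key but gain a `|start-end` span suffix so
#' truncated fragments remain distinct haplotypes.
#'
#' @param records Alignment-record data frame (see [read_sam()]).
#' @param references Named list of [alu_reference()] by reference id.
#' @return Data frame: `qname`, `sample_id`, `reference_id`, `key`, `nm`,
#'   `aligned_length`, `sequence`.
#' @export
call_records <- function(records, references) {
  if (inherits(references, "alu_reference"))
    references <- setNames(list(references), references$id)
  # identical alignments yield identical haplotypes: call each distinct
  # (reference, pos, cigar, md, seq) tuple once
  sig <- paste(records$ref_id, records$pos, records$cigar, records$md,
               records$seq, sep = "\r")
  first <- which(!duplicated(sig))
  uk <- character(length(first)); unm <- integer(length(first))
  ual <- integer(length(first))
  for (u in seq_along(first)) {
    i <- first[u]
    ref <- references[[records$ref_id[i]]]
    if (is.null(ref)) stop("unknown reference id: ", records$ref_id[i])
    hap <- call_variants(records[i, , drop = FALSE], ref)
    k <- hap$key
    if (hap$pos > 0L || hap$aligned_length < ref$length)
      k <- sprintf("%s|%d-%d", k, hap$pos, hap$pos + hap$aligned_length)
    uk[u] <- k; unm[u] <- hap$nm; ual[u] <- hap$aligned_length
  }
  m <- match(sig, sig[first])
  data.frame(qname = records$qname, sample_id = records$sample_id,
             reference_id = records$ref_id, key = uk[m], nm = unm[m],
             aligned_length = ual[m], sequence = records$seq,
             stringsAsFactors = FALSE)
}

#' Aggregate called records into a haplotype count table
#'
#' One row per distinct `(reference_id, key)`, counts partitioned by sample.
#' Total read counts are conserved.
#'
#' @param called Output of [call_records()].
#' @param samples Character vector of sample ids defining the count columns
#'   (defaults to the samples observed).
#' @return Haplotype table: `reference_id`, `key`, `nm`, `aligned_length`,
#'   `sequence`, one integer column per sample.
#' @export
aggregate_haplotypes <- function(called, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(called$sample_id))
  base_cols <- c("reference_id", "key", "nm", "aligned_length", "sequence")
  if (nrow(called) == 0) {
    out <- data.frame(reference_id = character(), key = character(),
                      nm = integer(), aligned_length = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
    for (s in samples) out[[s]] <- integer()
    return(out)
  }
  grp <- paste(called$reference_id, called$key, sep = "\r")
  first <- !duplicated(grp)
  out <- called[first, base_cols, drop = FALSE]
  rownames(out) <- NULL
  gidx <- match(grp, grp[first])
  for (s in samples) {
    cnt <- tabulate(gidx[called$sample_id == s], nbins = sum(first))
    out[[s]] <- as.integer(cnt)
  }
  out
}

#' Filter a haplotype table with the study's QC rules
#'
#' Rules are applied in a fixed order and the removals per rule recorded:
#' 1. aligned length `>= min_aligned` (sub-200-bp fragments missing the
#'    right arm are dropped);
#' 2. edit-distance cap `nm <= max_nm` (at most 10 nucleotide changes);
#' 3. index-hopping screen: rows whose full sequence exactly matches a
#'    haplotype observed in a different library;
#' 4. plasmid support: total plasmid count `> plasmid_min` required for a
#'    row to enter the analysis. Rows are additionally flagged
#'    `jumping_detected` when the total jumping count `> jumping_detect`;
#'    zero-jumping rows are retained so non-jumpers can be called.
#'
#' @param table Haplotype table (from [aggregate_haplotypes()] or
#'   [truth_to_table()]).
#' @param sheet A [sample_sheet()] naming the count columns.
#' @param max_nm Edit-distance cap (default 10).
#' @param min_aligned Aligned-length floor in bases (default 200).
#' @param plasmid_min Plasmid total must exceed this (default 2).
#' @param jumping_detect Jumping total must exceed this to flag the row as
#'   detected in the jumping library (default 10, applied to pooled
#'   replicates).
#' @param foreign_sequences Character vector of full sequences observed in
#'   other libraries (the hop screen); `NULL` disables the screen.
#' @return List: `table` (surviving rows, with `jumping_detected` flag) and
#'   `report` (named removal counts, in application order).
#' @export
filter_haplotypes <- function(table, sheet,
                              max_nm = 10L, min_aligned = 200L,
                              plasmid_min = 2L, jumping_detect = 10L,
                              foreign_sequences = NULL) {
  miss <- setdiff(sheet$sample_id, names(table))
  if (length(miss))
    stop("table lacks sample columns: ", paste(miss, collapse = ", "))
  if (!all(c("plasmid", "jumping") %in% sheet$condition))
    stop("sample sheet must annotate both plasmid and jumping conditions")
  n0 <- nrow(table)
  report <- c(input = n0, short_fragment = 0L, mismatch_cap = 0L,
              index_hopping = 0L, low_plasmid = 0L, retained = 0L)

  keep <- table$aligned_length >= min_aligned
  report["short_fragment"] <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  keep <- table$nm <= max_nm
  report["mismatch_cap"] <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  if (!is.null(foreign_sequences) && length(foreign_sequences)) {
    keep <- !(table$sequence %in% foreign_sequences)
    report["index_hopping"] <- sum(!keep)
    table <- table[keep, , drop = FALSE]
  }

  pcols <- sheet$sample_id[sheet$condition == "plasmid"]
  jcols <- sheet$sample_id[sheet$condition == "jumping"]
  ptot <- rowSums(table[, pcols, drop = FALSE])
  keep <- ptot > plasmid_min
  report["low_plasmid"] <- sum(!keep)
  table <- table[keep, , drop = FALSE]

  table$jumping_detected <-
    rowSums(table[, jcols, drop = FALSE]) > jumping_detect
  report["retained"] <- nrow(table)
  rownames(table) <- NULL
  list(table = table, report = as.list(report))
}

#' Cross-library index-hopping screen
#'
#' Hopped reads surface in a library as haplotypes that belong to a
#' different library: they align to that library's reference, and their
#' full sequence exactly matches a haplotype natively observed there. A row
#' is removed from library X when (a) it is aligned to a reference other
#' than X's own, or (b) its sequence exactly matches a *native* haplotype
#' of another library. Under (b) the collision is unresolvable, so the row
#' is dropped wherever it appears.
#'
#' @param tables Named list of haplotype tables, one per library.
#' @param library_refs Named character vector: each library's own reference
#'   id (defaults to the list names, the pipeline's convention).
#' @return List with `tables` (screened) and `removed` (rows removed per
#'   library).
#' @export
screen_index_hopping <- function(tables, library_refs = names(tables)) {
  if (is.null(names(library_refs))) names(library_refs) <- names(tables)
  native <- lapply(names(tables), function(nm) {
    t <- tables[[nm]]
    t$sequence[t$reference_id == library_refs[[nm]]]
  })
  names(native) <- names(tables)
  removed <- setNames(integer(length(tables)), names(tables))
  out <- tables
  for (nm in names(tables)) {
    t <- tables[[nm]]
    foreign_native <- unlist(native[setdiff(names(tables), nm)],
                             use.names = FALSE)
    drop <- t$reference_id != library_refs[[nm]] |
      t$sequence %in% foreign_native
    removed[nm] <- sum(drop)
    out[[nm]] <- t[!drop, , drop = FALSE]
    rownames(out[[nm]]) <- NULL
  }
  list(tables = out, removed = removed)
}

#' Align a raw fragment to a reference
#'
#' Built-in substitute for an external aligner when raw full-length
#' fragments are supplied: glocal alignment (fragment end to end, reference
#' overhangs free) with unit mismatch and gap costs, emitting a consistent
#' POS/CIGAR/MD/NM record.
#'
#' @param fragment DNA string (A/C/G/T).
#' @param reference An [alu_reference()].
#' @param qname,sample_id Record labels.
#' @return One-row alignment-record data frame.
#' @export
align_fragment <- function(fragment, reference, qname = "frag",
                           sample_id = "sample1") {
  fragment <- toupper(fragment)
  if (!grepl("^[ACGT]+$", fragment))
    stop("fragment must be a non-empty A/C/G/T string")
  aln <- glocal_align_cpp(fragment, reference$sequence)
  ops <- strsplit(aln$ops, "")[[1]]
  chars <- strsplit(reference$sequence, "")[[1]]
  fchar <- strsplit(fragment, "")[[1]]
  rp <- aln$start; qp <- 0L
  md <- character(); run <- 0L; nm <- 0L; last_del <- FALSE
  for (op in ops) {
    if (op == "M") {
      rp <- rp + 1L; qp <- qp + 1L
      if (chars[rp] == fchar[qp]) run <- run + 1L
      else {
        md <- c(md, as.character(run), chars[rp]); run <- 0L; nm <- nm + 1L
      }
      last_del <- FALSE
    } else if (op == "D") {
      if (!last_del) { md <- c(md, as.character(run), "^"); run <- 0L }
      rp <- rp + 1L
      md[length(md)] <- paste0(md[length(md)], chars[rp])
      nm <- nm + 1L; last_del <- TRUE
    } else {  # I
      qp <- qp + 1L; nm <- nm + 1L; last_del <- FALSE
    }
  }
  md <- c(md, as.character(run))
  rle_ops <- rle(ops)
  data.frame(qname = qname, ref_id = reference$id, pos = aln$start,
             cigar = cigar_string(rle_ops$values, rle_ops$lengths),
             md = paste(md, collapse = ""), nm = nm, seq = fragment,
             sample_id = sample_id, stringsAsFactors = FALSE)
}
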