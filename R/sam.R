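#' Parse a CIGAR string
#'
#' @param cigar CIGAR string over operations M, I, D, S.
#' @return `data.frame(op, len)` in order.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !grepl("^([0-9]+[MIDS])+$", cigar))
    stop("malformed CIGAR: ", cigar)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDS]", cigar))[[1]]
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

cigar_string <- function(ops, lens) {
  keep <- lens > 0
  ops <- ops[keep]; lens <- lens[keep]
  if (length(ops) == 0) return("")
  # merge adjacent identical ops
  grp <- cumsum(c(TRUE, ops[-1] != ops[-length(ops)]))
  paste0(tapply(lens, grp, sum), ops[!duplicated(grp)], collapse = "")
}

#' Parse a SAM MD tag
#'
#' The MD grammar is `[0-9]+(([A-Z]|\^[A-Z]+)[0-9]+)*`: match lengths
#' alternating with single mismatched reference bases or `^`-prefixed deleted
#' reference runs.
#'
#' @param md MD tag string (without the `MD:Z:` prefix).
#' @return `data.frame(type, len, bases)` with `type` in
#'   `match`/`mismatch`/`deletion`; `bases` holds the reference base(s) for
#'   non-match tokens.
#' @export
parse_md <- function(md) {
  if (is.na(md) || !grepl("^[0-9]+((\\^[ACGTN]+|[ACGTN])[0-9]+)*$", md)) {
    # longest prefix that is a valid parse state, including a trailing
    # non-number token; the next character is the offender
    ok <- regmatches(md, regexpr(
      "^[0-9]+(([ACGTN]|\\^[ACGTN]+)[0-9]+)*([ACGTN]|\\^[ACGTN]*)?", md))
    off <- if (length(ok)) nchar(ok) + 1L else 1L
    stop(sprintf("malformed MD tag at offset %d: %s", off, md))
  }
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[ACGTN]+|[ACGTN]", md))[[1]]
  type <- ifelse(grepl("^[0-9]+$", toks), "match",
                 ifelse(startsWith(toks, "^"), "deletion", "mismatch"))
  bases <- ifelse(type == "match", "", sub("^\\^", "", toks))
  len <- ifelse(type == "match", suppressWarnings(as.integer(toks)),
                nchar(bases))
  data.frame(type = type, len = as.integer(len), bases = bases,
             stringsAsFactors = FALSE)
}

#' Build alignment tags for a variant set
#'
#' Computes POS/CIGAR/MD/NM and the read sequence for a clone defined by a
#' canonical variant table against a reference, optionally restricted to a
#' reference span (used for truncated-fragment artifacts).
#'
#' @param variants Canonical variant data frame.
#' @param reference An [alu_reference()] (or a plain sequence string).
#' @param span `c(start, end)` 0-based half-open aligned reference window.
#' @return List with `pos` (0-based), `cigar`, `md`, `nm`, `seq`,
#'   `aligned_length`.
#' @export
build_alignment_tags <- function(variants, reference, span = NULL) {
  ref_seq <- if (inherits(reference, "alu_reference")) reference$sequence
             else reference
  L <- nchar(ref_seq)
  if (is.null(span)) span <- c(0L, L)
  chars <- strsplit(ref_seq, "")[[1]]
  v <- variants[variants$pos >= span[1] & variants$pos < span[2], ,
                drop = FALSE]
  if (nrow(v)) {
    kinds <- variant_kind(v)
    if (anyDuplicated(v$pos[kinds != "INS"]))
      stop("overlapping variants: multiple edits at one reference position")
  }
  kind <- if (nrow(v)) variant_kind(v) else character()
  snv_at <- setNames(v$alt[kind == "SNV"], v$pos[kind == "SNV"])
  del_at <- v$pos[kind == "DEL"]
  ins_at <- split(v$alt[kind == "INS"], v$pos[kind == "INS"])

  ops <- character(); lens <- integer()
  md <- character(); run <- 0L; nm <- 0L
  push <- function(op, len) {
    ops <<- c(ops, op); lens <<- c(lens, len)
  }
  flush_md <- function() { md <<- c(md, as.character(run)); run <<- 0L }
  last_del <- FALSE
  for (p in seq.int(span[1], span[2] - 1L)) {
    pc <- as.character(p)
    if (!is.null(ins_at[[pc]])) {
      bases <- paste(ins_at[[pc]], collapse = "")
      push("I", nchar(bases)); nm <- nm + nchar(bases)
      last_del <- FALSE
    }
    if (p %in% del_at) {
      if (!last_del) { flush_md(); md <- c(md, "^") }
      md[length(md)] <- paste0(md[length(md)], chars[p + 1L])
      push("D", 1L); nm <- nm + 1L
      last_del <- TRUE
    } else if (!is.na(snv_at[pc])) {
      flush_md(); md <- c(md, chars[p + 1L])
      push("M", 1L); run <- 0L; nm <- nm + 1L
      last_del <- FALSE
    } else {
      push("M", 1L); run <- run + 1L
      last_del <- FALSE
    }
  }
  # trailing insertion at the span end
  pc <- as.character(span[2])
  if (span[2] == L && !is.null(ins_at[[pc]])) {
    bases <- paste(ins_at[[pc]], collapse = "")
    push("I", nchar(bases)); nm <- nm + nchar(bases)
  }
  flush_md()
  seqs <- apply_variants(ref_seq, v, span = span)
  list(pos = span[1], cigar = cigar_string(ops, lens),
       md = paste(md, collapse = ""), nm = nm, seq = seqs,
       aligned_length = span[2] - span[1])
}

#' Call variants from an alignment record (CIGAR/MD route)
#'
#' Reconstructs the variant set of a read from its POS, CIGAR and MD tag,
#' reading alternate alleles off the read sequence. The result is
#' canonicalized (sorted, indels left-anchored) and validated against NM.
#'
#' @param record A one-row alignment record data frame (fields `pos` 0-based,
#'   `cigar`, `md`, `nm`, `seq`, `ref_id`).
#' @param reference An [alu_reference()] matching `record$ref_id` (or plain
#'   sequence string used for canonicalization).
#' @return A list (`haplotype`): `variants`, `key`, `nm`, `pos`,
#'   `aligned_length`, `seq`.
#' @export
call_variants <- function(record, reference) {
  ref_seq <- if (inherits(reference, "alu_reference")) reference$sequence
             else reference
  cg <- parse_cigar(record$cigar)
  mdt <- parse_md(record$md)
  seqc <- strsplit(record$seq, "")[[1]]
  if (sum(cg$len[cg$op %in% c("M", "I", "S")]) != length(seqc))
    stop("CIGAR does not match sequence length")
  if (sum(mdt$len[mdt$type != "deletion"]) != sum(cg$len[cg$op == "M"]))
    stop("MD/CIGAR disagreement: MD covers ", sum(mdt$len[mdt$type != "deletion"]),
         " M bases, CIGAR has ", sum(cg$len[cg$op == "M"]))

  # expand MD over M columns: NA = match, base = mismatched reference base
  md_cols <- character(0)
  del_queue <- character(0)
  for (i in seq_len(nrow(mdt))) {
    if (mdt$type[i] == "match") {
      md_cols <- c(md_cols, rep(NA_character_, mdt$len[i]))
    } else if (mdt$type[i] == "mismatch") {
      md_cols <- c(md_cols, mdt$bases[i])
    } else {
      # deletions: consumed in CIGAR order; store flattened run
      md_cols <- c(md_cols, strsplit(mdt$bases[i], "")[[1]])
    }
  }
  md_is_del <- logical(0)
  j <- 1L
  for (i in seq_len(nrow(mdt))) {
    n <- if (mdt$type[i] == "deletion") nchar(mdt$bases[i]) else mdt$len[i]
    md_is_del <- c(md_is_del, rep(mdt$type[i] == "deletion", n))
  }

  pos <- as.integer(record$pos)  # 0-based
  rp <- pos; qp <- 0L; mi <- 1L
  out_pos <- integer(); out_ref <- character(); out_alt <- character()
  for (k in seq_len(nrow(cg))) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op == "S") {
      qp <- qp + len
    } else if (op == "I") {
      out_pos <- c(out_pos, rep(rp, len))
      out_ref <- c(out_ref, rep("", len))
      out_alt <- c(out_alt, seqc[qp + seq_len(len)])
      qp <- qp + len
    } else if (op == "D") {
      for (d in seq_len(len)) {
        if (mi > length(md_cols) || !md_is_del[mi])
          stop("MD/CIGAR disagreement: deletion not present in MD")
        out_pos <- c(out_pos, rp); out_ref <- c(out_ref, md_cols[mi])
        out_alt <- c(out_alt, "")
        rp <- rp + 1L; mi <- mi + 1L
      }
    } else {  # M
      for (d in seq_len(len)) {
        if (mi > length(md_cols) || md_is_del[mi])
          stop("MD/CIGAR disagreement: match column marked as deletion in MD")
        if (!is.na(md_cols[mi])) {
          if (md_cols[mi] == seqc[qp + 1L])
            stop("MD mismatch base equals read base at reference position ", rp)
          out_pos <- c(out_pos, rp); out_ref <- c(out_ref, md_cols[mi])
          out_alt <- c(out_alt, seqc[qp + 1L])
        }
        rp <- rp + 1L; qp <- qp + 1L; mi <- mi + 1L
      }
    }
  }
  variants <- canonicalize_variants(
    variant_df(out_pos, out_ref, out_alt), ref_seq)
  nm <- variant_nm(variants)
  if (!is.null(record$nm) && !is.na(record$nm) && nm != as.integer(record$nm))
    stop(sprintf("NM disagreement: tag says %s, variants imply %d",
                 record$nm, nm))
  aligned <- sum(cg$len[cg$op %in% c("M", "D")])
  list(variants = variants, key = variant_key(variants), nm = nm,
       pos = pos, aligned_length = aligned, seq = record$seq)
}

#' Call variants by direct read-vs-reference column comparison
#'
#' Independent of the MD tag: walks the CIGAR columns and compares the read
#' sequence against the reference sequence directly. Used as the second
#' route of the caller-equivalence check.
#'
#' @inheritParams call_variants
#' @return Same structure as [call_variants()].
#' @export
call_variants_by_comparison <- function(record, reference) {
  ref_seq <- if (inherits(reference, "alu_reference")) reference$sequence
             else reference
  chars <- strsplit(ref_seq, "")[[1]]
  cg <- parse_cigar(record$cigar)
  seqc <- strsplit(record$seq, "")[[1]]
  rp <- as.integer(record$pos); qp <- 0L
  out_pos <- integer(); out_ref <- character(); out_alt <- character()
  for (k in seq_len(nrow(cg))) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op == "S") qp <- qp + len
    else if (op == "I") {
      out_pos <- c(out_pos, rep(rp, len)); out_ref <- c(out_ref, rep("", len))
      out_alt <- c(out_alt, seqc[qp + seq_len(len)]); qp <- qp + len
    } else if (op == "D") {
      out_pos <- c(out_pos, rp + seq_len(len) - 1L)
      out_ref <- c(out_ref, chars[rp + seq_len(len)])
      out_alt <- c(out_alt, rep("", len)); rp <- rp + len
    } else {
      for (d in seq_len(len)) {
        if (chars[rp + 1L] != seqc[qp + 1L]) {
          out_pos <- c(out_pos, rp); out_ref <- c(out_ref, chars[rp + 1L])
          out_alt <- c(out_alt, seqc[qp + 1L])
        }
        rp <- rp + 1L; qp <- qp + 1L
      }
    }
  }
  variants <- canonicalize_variants(
    variant_df(out_pos, out_ref, out_alt), ref_seq)
  aligned <- sum(cg$len[cg$op %in% c("M", "D")])
  list(variants = variants, key = variant_key(variants),
       nm = variant_nm(variants), pos = as.integer(record$pos),
       aligned_length = aligned, seq = record$seq)
}

#' Write alignment records to a SAM file
#'
#' Internal coordinates are 0-based; POS is converted to 1-based on output.
#'
#' @param records Data frame with columns `qname`, `ref_id`, `pos` (0-based),
#'   `cigar`, `md`, `nm`, `seq`, and optionally `sample_id` (stored in the
#'   `RG:Z:` tag).
#' @param path Output path.
#' @param references Named list of [alu_reference()] (for `@SQ` headers).
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, references) {
  if (inherits(references, "alu_reference"))
    references <- setNames(list(references), references$id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (r in references)
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", r$id, r$length), con)
  rg <- if ("sample_id" %in% names(records))
    sprintf("\tRG:Z:%s", records$sample_id) else ""
  lines <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d\tMD:Z:%s%s",
                   records$qname, records$ref_id, records$pos + 1L,
                   records$cigar, records$seq, records$nm, records$md, rg)
  writeLines(lines, con)
  invisible(path)
}

#' Read alignment records from a SAM file
#'
#' Minimal text reader for the single-end records this pipeline emits and
#' consumes; extracts POS (converted to 0-based), CIGAR, SEQ and the MD/NM/RG
#' tags.
#'
#' @param path SAM file path.
#' @return Data frame of records (`qname`, `ref_id`, `pos`, `cigar`, `md`,
#'   `nm`, `seq`, `sample_id`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0)
    return(data.frame(qname = character(), ref_id = character(),
                      pos = integer(), cigar = character(), md = character(),
                      nm = integer(), seq = character(),
                      sample_id = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  tag <- function(fields, prefix) {
    hit <- fields[startsWith(fields, prefix)]
    if (length(hit)) sub(prefix, "", hit[1], fixed = TRUE) else NA_character_
  }
  data.frame(
    qname = vapply(f, `[`, "", 1L),
    ref_id = vapply(f, `[`, "", 3L),
    pos = as.integer(vapply(f, `[`, "", 4L)) - 1L,
    cigar = vapply(f, `[`, "", 6L),
    md = vapply(f, function(x) tag(x[-(1:11)], "MD:Z:"), ""),
    nm = as.integer(vapply(f, function(x) tag(x[-(1:11)], "NM:i:"), "")),
    seq = vapply(f, `[`, "", 10L),
    sample_id = vapply(f, function(x) tag(x[-(1:11)], "RG:Z:"), ""),
    stringsAsFactors = FALSE)
}
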