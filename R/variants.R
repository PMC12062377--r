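#' Variant tables
#'
#' Variants are stored as a data frame with columns `pos` (0-based reference
#' coordinate), `ref` and `alt`. The three kinds are encoded as:
#' SNV `ref = "A", alt = "G"`; 1-bp insertion before `pos` `ref = "",
#' alt = "G"`; 1-bp deletion `ref = "G", alt = ""`. The canonical string key
#' is `"pos:ref>alt"` joined by `";"`, the empty string for the reference
#' haplotype.
#'
#' @param pos Integer 0-based positions.
#' @param ref,alt Character reference / alternate alleles (see encoding).
#' @return A `data.frame(pos, ref, alt)`.
#' @export
variant_df <- function(pos = integer(), ref = character(), alt = character()) {
  df <- data.frame(pos = as.integer(pos), ref = as.character(ref),
                   alt = as.character(alt), stringsAsFactors = FALSE)
  kind <- variant_kind(df)
  if (any(kind == "SNV" & (nchar(df$ref) != 1L | df$ref == df$alt)))
    stop("SNV must have single-base ref != alt")
  df
}

variant_kind <- function(variants) {
  ifelse(variants$ref == "", "INS", ifelse(variants$alt == "", "DEL", "SNV"))
}

#' @rdname variant_df
#' @param variants A variant data frame.
#' @export
variant_key <- function(variants) {
  if (is.null(variants) || nrow(variants) == 0) return("")
  v <- sort_variants(variants)
  paste(sprintf("%d:%s>%s", v$pos, v$ref, v$alt), collapse = ";")
}

#' @rdname variant_df
#' @param key A canonical haplotype key string.
#' @export
parse_variant_key <- function(key) {
  if (is.na(key) || key == "") return(variant_df())
  parts <- strsplit(key, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+):([ACGT]*)>([ACGT]*)$", parts))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed variant key token: ", parts[bad][1])
  variant_df(pos = as.integer(vapply(m, `[`, "", 2L)),
             ref = vapply(m, `[`, "", 3L),
             alt = vapply(m, `[`, "", 4L))
}

# Deterministic ordering: position, then kind (INS before DEL before SNV at
# the same position so insertions precede edits of the base they precede),
# then alleles.
sort_variants <- function(variants) {
  kind_rank <- c(INS = 0L, DEL = 1L, SNV = 1L)[variant_kind(variants)]
  variants[order(variants$pos, kind_rank, variants$ref, variants$alt), ,
           drop = FALSE]
}

#' Left-anchor indels and sort a variant table
#'
#' Indel placement inside homopolymer runs is aligner-dependent; keys must be
#' stable, so 1-bp insertions and deletions are shifted to the leftmost
#' equivalent position before keying. Deletions sharing one homopolymer run
#' are packed into the run's leftmost slots.
#'
#' @param variants Variant data frame.
#' @param ref_seq Reference sequence string.
#' @return Canonical (sorted, left-anchored, de-duplicated) variant table.
#' @export
canonicalize_variants <- function(variants, ref_seq) {
  if (nrow(variants) == 0) return(variants)
  chars <- strsplit(ref_seq, "")[[1]]
  kind <- variant_kind(variants)
  # a shift may not cross a position edited by another variant: homopolymer
  # equivalence only holds over unmodified reference bases
  shift_left <- function(p, base, blocked) {
    # chars[p] is the base at 0-based position p - 1
    while (p > 0L && chars[p] == base && !((p - 1L) %in% blocked))
      p <- p - 1L
    p
  }
  for (i in which(kind != "SNV")) {
    base <- if (kind[i] == "DEL") variants$ref[i] else variants$alt[i]
    # deletions of the same base slide through each other (they share a
    # homopolymer run and are packed below); everything else blocks
    blocked <- if (kind[i] == "DEL")
      variants$pos[kind == "SNV" | (kind == "DEL" & variants$ref != base)]
    else variants$pos[kind != "INS"]
    variants$pos[i] <- shift_left(variants$pos[i], base, blocked)
  }
  # pack deletions that collapsed onto the same run start
  del <- which(variant_kind(variants) == "DEL")
  if (length(del) > 1) {
    keyrun <- paste(variants$pos[del], variants$ref[del])
    for (grp in split(del, keyrun)) {
      if (length(grp) > 1) {
        p0 <- variants$pos[grp[1]]
        variants$pos[grp] <- p0 + seq_along(grp) - 1L
      }
    }
  }
  v <- sort_variants(variants)
  v[!duplicated(paste(v$pos, v$ref, v$alt)), , drop = FALSE]
}

#' Apply variants to a reference sequence
#'
#' Reconstructs the mutant (read) sequence from the reference and a variant
#' table, optionally over a restricted reference span.
#'
#' @param ref_seq Reference sequence string.
#' @param variants Variant data frame (positions within the span).
#' @param span Optional `c(start, end)` 0-based half-open window; variants
#'   outside it are ignored.
#' @return The mutant sequence string.
#' @export
apply_variants <- function(ref_seq, variants, span = NULL) {
  chars <- strsplit(ref_seq, "")[[1]]
  L <- length(chars)
  if (is.null(span)) span <- c(0L, L)
  keep <- chars[seq.int(span[1] + 1L, span[2])]
  ins <- rep("", length(keep) + 1L)
  if (nrow(variants)) {
    kind <- variant_kind(variants)
    for (i in seq_len(nrow(variants))) {
      p <- variants$pos[i]
      if (p < span[1] || p >= span[2] + (kind[i] == "INS")) next
      j <- p - span[1] + 1L
      if (kind[i] == "SNV") {
        if (keep[j] != variants$ref[i])
          stop(sprintf("SNV ref mismatch at position %d", p))
        keep[j] <- variants$alt[i]
      } else if (kind[i] == "DEL") {
        if (keep[j] != variants$ref[i])
          stop(sprintf("DEL ref mismatch at position %d", p))
        keep[j] <- NA_character_
      } else {
        ins[j] <- paste0(ins[j], variants$alt[i])
      }
    }
  }
  out <- character(2L * length(keep) + 1L)
  out[seq(1, by = 2, length.out = length(keep) + 1L)] <- ins
  body <- ifelse(is.na(keep), "", keep)
  out[seq(2, by = 2, length.out = length(keep))] <- body
  paste(out, collapse = "")
}

#' Number of edited bases implied by a variant table
#' @param variants Variant data frame.
#' @return Integer: SNVs + inserted bases + deleted bases.
#' @export
variant_nm <- function(variants) {
  # every row is a single-base edit under this encoding
  nrow(variants)
}
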