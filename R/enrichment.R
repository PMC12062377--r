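#' Hypergeometric enrichment of class variants in region sets
#'
#' Distinct variants (position, ref, alt tuples pooled across haplotypes)
#' form the universe: `N` background variants of which `K` fall in the
#' region; a class contributes `n` variants of which `k` fall in the
#' region. The one-sided upper-tail p-value is `P(X >= k)` under the
#' hypergeometric null, and Benjamini-Hochberg adjustment is applied across
#' all (class x region) tests.
#'
#' @param class_sets Named list of character vectors of variant tokens
#'   (`"pos:ref>alt"`), one per class; each must be a subset of
#'   `background`.
#' @param background Character vector of all variant tokens.
#' @param regions Named list of interval sets; each element is a single
#'   `c(start, end)` or a list of such intervals (e.g.
#'   `list(srp_left = ..., srp_right = ..., srp_both = list(...))`).
#' @return `data.frame(class, region, N, K, n, k, p, p_adj)`.
#' @export
hypergeom_enrichment <- function(class_sets, background, regions) {
  background <- unique(background)
  N <- length(background)
  if (N == 0) stop("empty background variant set")
  bg_pos <- as.integer(sub(":.*$", "", background))
  out <- NULL
  for (cl in names(class_sets)) {
    set <- unique(class_sets[[cl]])
    if (!all(set %in% background))
      stop("class '", cl, "' contains variants outside the background")
    set_pos <- as.integer(sub(":.*$", "", set))
    for (rg in names(regions)) {
      iv <- regions[[rg]]
      K <- sum(in_intervals(bg_pos, iv))
      k <- sum(in_intervals(set_pos, iv))
      n <- length(set)
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      out <- rbind(out, data.frame(class = cl, region = rg, N = N, K = K,
                                   n = n, k = k, p = p,
                                   stringsAsFactors = FALSE))
    }
  }
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Position frequency matrix over a region
#'
#' Per region column, the frequency of each nucleotide across the class's
#' haplotype sequences (reference base where a haplotype has no variant).
#' Deleted positions reduce the column support; insertions do not create
#' columns. Suitable input for logo rendering.
#'
#' @param keys Character vector of haplotype keys of one class (span
#'   suffixes are ignored; full-length haplotypes expected).
#' @param reference An [alu_reference()].
#' @param region `c(start, end)` 0-based half-open interval within the
#'   reference.
#' @param weights Optional non-negative weight per haplotype (e.g. read
#'   counts); default unweighted.
#' @return List of class `pfm`: `matrix` (4 x width, rows A/C/G/T, columns
#'   sum to 1 over supported columns), `support` (weight behind each
#'   column), `region`, `positions` (0-based).
#' @export
position_frequency_matrix <- function(keys, reference, region,
                                      weights = NULL) {
  if (length(keys) == 0) stop("empty haplotype class")
  region <- as.integer(region)
  if (region[1] < 0 || region[2] > reference$length || region[1] >= region[2])
    stop("region outside the reference")
  if (is.null(weights)) weights <- rep(1, length(keys))
  stopifnot(length(weights) == length(keys), all(weights >= 0))
  width <- region[2] - region[1]
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, 4, width,
                   dimnames = list(bases, as.character(seq.int(region[1],
                                                               region[2] - 1L))))
  support <- rep(0, width)
  ref_chars <- strsplit(reference$sequence, "")[[1]]
  for (i in seq_along(keys)) {
    v <- parse_variant_key(sub("\\|.*$", "", keys[i]))
    col_base <- ref_chars[seq.int(region[1] + 1L, region[2])]
    if (nrow(v)) {
      kind <- variant_kind(v)
      inside <- v$pos >= region[1] & v$pos < region[2]
      for (j in which(inside & kind == "SNV"))
        col_base[v$pos[j] - region[1] + 1L] <- v$alt[j]
      for (j in which(inside & kind == "DEL"))
        col_base[v$pos[j] - region[1] + 1L] <- NA_character_
    }
    ok <- !is.na(col_base)
    support[ok] <- support[ok] + weights[i]
    idx <- cbind(match(col_base[ok], bases), which(ok))
    counts[idx] <- counts[idx] + weights[i]
  }
  freq <- sweep(counts, 2, ifelse(support > 0, support, 1), "/")
  structure(list(matrix = freq, support = support, region = region,
                 positions = seq.int(region[1], region[2] - 1L)),
            class = "pfm")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> region [%d,%d), %d columns, max support %g\n",
              x$region[1], x$region[2], ncol(x$matrix), max(x$support)))
  invisible(x)
}
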