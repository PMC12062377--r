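#' Levenshtein edit distance between DNA strings
#'
#' Unit-cost substitutions and 1-bp-costed insertions/deletions, computed by
#' dynamic programming in compiled code. In banded mode the value is exact
#' whenever the true distance is at most `band`; otherwise a truncated lower
#' bound (`band + 1`) is returned with attribute `truncated = TRUE`.
#'
#' @param a,b DNA strings (A/C/G/T).
#' @param band Optional band half-width; `NULL` for the full program.
#' @return Integer distance (possibly with a `truncated` attribute).
#' @export
edit_distance <- function(a, b, band = NULL) {
  for (s in c(a, b))
    if (!grepl("^[ACGT]*$", s)) stop("sequences must contain only A/C/G/T")
  d <- lev_distance_cpp(a, b, if (is.null(band)) -1L else as.integer(band))
  if (!is.null(band) && d > band) attr(d, "truncated") <- TRUE
  d
}

#' Minimum distances from haplotypes to a genomic element set
#'
#' For every haplotype sequence, the minimum edit distance over the genomic
#' set and the nearest element (ties broken by lexicographically smallest
#' id), plus per-class distance summaries.
#'
#' @param sequences Named character vector of haplotype sequences (names =
#'   haplotype keys).
#' @param genomic Named character vector of genomic element sequences.
#' @param classes Optional character vector of class labels per haplotype
#'   (e.g. jumper classes) for the per-class summary.
#' @return List of class `distance_report`: `per_haplotype`
#'   (`data.frame(key, class, min_distance, nearest)`), `per_class` summary
#'   (min/median/max distance and count).
#' @export
min_distances <- function(sequences, genomic, classes = NULL) {
  if (length(sequences) == 0 || length(genomic) == 0)
    stop("need non-empty haplotype and genomic sets")
  ord <- order(names(genomic))  # lexicographic ids so ties pick smallest id
  genomic <- genomic[ord]
  res <- min_lev_distance_cpp(unname(sequences), unname(genomic))
  per <- data.frame(key = names(sequences) %||% as.character(seq_along(sequences)),
                    class = if (is.null(classes)) NA_character_ else classes,
                    min_distance = res$distance,
                    nearest = names(genomic)[res$index],
                    stringsAsFactors = FALSE)
  per_class <- NULL
  if (!is.null(classes)) {
    for (cl in sort(unique(classes))) {
      d <- per$min_distance[per$class == cl]
      per_class <- rbind(per_class, data.frame(
        class = cl, n = length(d), min = min(d),
        median = median(d), max = max(d), stringsAsFactors = FALSE))
    }
  }
  structure(list(per_haplotype = per, per_class = per_class),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("<distance_report> %d haplotypes; overall min distance %d\n",
              nrow(x$per_haplotype), min(x$per_haplotype$min_distance)))
  if (!is.null(x$per_class)) print(x$per_class)
  invisible(x)
}

#' Genomic elements nearest to high-jumper haplotypes
#'
#' Per genomic element, the smallest edit distance to any HIGH haplotype;
#' elements within `k_max` edits are returned sorted by ascending distance
#' (these are the elements that could become active with the fewest
#' nucleotide changes).
#'
#' @param genomic Named character vector of genomic element sequences.
#' @param high_sequences Character vector of HIGH-class haplotype sequences.
#' @param k_max Maximum distance to report.
#' @return `data.frame(element, min_distance, nearest_haplotype)` sorted
#'   ascending; zero rows when nothing is within `k_max`.
#' @export
nearest_activators <- function(genomic, high_sequences, k_max) {
  if (length(high_sequences) == 0) stop("empty HIGH haplotype set")
  res <- min_lev_distance_cpp(unname(genomic), unname(high_sequences))
  out <- data.frame(element = names(genomic) %||% as.character(seq_along(genomic)),
                    min_distance = res$distance,
                    nearest_haplotype = res$index,
                    stringsAsFactors = FALSE)
  out <- out[out$min_distance <= k_max, , drop = FALSE]
  out[order(out$min_distance, out$element), , drop = FALSE]
}

#' Trim a sequence to the core region of a reference
#'
#' Distances are computed on the core element (polyA tails and flanks
#' excluded); this helper applies the reference's core interval to the
#' reference itself or any same-coordinate sequence.
#'
#' @param sequence Sequence string in reference coordinates.
#' @param reference An [alu_reference()].
#' @return Substring over the core interval.
#' @export
trim_to_core <- function(sequence, reference) {
  substring(sequence, reference$core[1] + 1L, reference$core[2])
}
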