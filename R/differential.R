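#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over haplotypes of the
#' ratio of its count to the row geometric mean; rows containing any zero
#' are excluded from the median.
#'
#' @param counts Count matrix (haplotypes x samples) or a haplotype table
#'   data frame together with `samples`.
#' @param samples Optional character vector of sample columns.
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts, samples = NULL) {
  mat <- as_count_matrix(counts, samples)
  pos <- rowSums(mat == 0) == 0
  if (!any(pos))
    stop("no haplotype has positive counts in every sample; ",
         "consider a pseudocount before normalization")
  lg <- rowMeans(log(mat[pos, , drop = FALSE]))
  apply(mat[pos, , drop = FALSE], 2, function(k) exp(median(log(k) - lg)))
}

as_count_matrix <- function(counts, samples = NULL) {
  if (is.data.frame(counts)) {
    if (is.null(samples))
      samples <- setdiff(names(counts),
                         c("reference_id", "key", "nm", "aligned_length",
                           "sequence", "jumping_detected"))
    mat <- as.matrix(counts[, samples, drop = FALSE])
    rownames(mat) <- if ("key" %in% names(counts)) counts$key else NULL
    mat
  } else {
    if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
    as.matrix(counts)
  }
}

#' Per-haplotype dispersion with trend shrinkage
#'
#' Method-of-moments dispersion per haplotype from the within-condition
#' variance of normalized counts, a mean-dispersion trend
#' `phi(m) = a0 + a1 / m` fitted across haplotypes, and a shrunken estimate:
#' a degrees-of-freedom weighted average of the per-row estimate and the
#' trend, floored at `1e-8`.
#'
#' @param counts Count matrix or haplotype table.
#' @param sheet A [sample_sheet()].
#' @param sf Size factors (computed if `NULL`).
#' @param prior_df Weight of the trend in shrinkage (default 6; residual
#'   degrees of freedom of a 2x2 design are 2, so the trend dominates).
#' @return Data frame `mean`, `mom`, `trend`, `used` per haplotype.
#' @export
estimate_dispersion <- function(counts, sheet, sf = NULL, prior_df = 6) {
  mat <- as_count_matrix(counts, sheet$sample_id)
  if (is.null(sf)) sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  conds <- unique(sheet$condition)
  mu_c <- sapply(conds, function(cc)
    rowMeans(norm[, sheet$condition == cc, drop = FALSE]))
  var_c <- sapply(conds, function(cc) {
    cols <- sheet$condition == cc
    if (sum(cols) < 2) return(rep(NA_real_, nrow(norm)))
    apply(norm[, cols, drop = FALSE], 1, var)
  })
  mu_c <- matrix(mu_c, nrow = nrow(norm))
  var_c <- matrix(var_c, nrow = nrow(norm))
  num <- rowSums(var_c - mu_c, na.rm = TRUE)
  den <- rowSums(mu_c^2, na.rm = TRUE)
  # raw (untruncated) moments: truncating at zero before trend fitting
  # would bias the trend upward, since half the 1-df noise is negative
  mom_raw <- ifelse(den > 0, num / den, NA_real_)
  m <- rowMeans(norm)

  ok <- is.finite(mom_raw) & m > 0
  trend_fun <- fit_dispersion_trend(m[ok], mom_raw[ok])
  trend <- trend_fun(pmax(m, 1e-8))
  df_res <- sum(tabulate(factor(sheet$condition)) - 1L)
  w <- df_res / (df_res + prior_df)
  used <- pmax(w * ifelse(is.finite(mom_raw), mom_raw, trend) +
                 (1 - w) * trend, 1e-8)
  data.frame(mean = m, mom = pmax(mom_raw, 0), trend = trend, used = used)
}

# Robust fit of phi(m) = a0 + a1/m on raw (possibly negative) moment
# estimates: symmetric two-sided trimming guards outliers without biasing
# the level; coefficients are clamped to a nonnegative dispersion surface.
fit_dispersion_trend <- function(m, mom) {
  keep <- is.finite(mom) & m > 0
  m <- m[keep]; mom <- mom[keep]
  if (length(m) < 10) {
    a0 <- max(median(mom), 1e-8)
    return(function(mu) rep(a0, length(mu)))
  }
  q <- quantile(mom, c(0.01, 0.99))
  trim <- mom >= q[1] & mom <= q[2]
  fit <- lm.fit(cbind(1, 1 / m[trim]), mom[trim])
  a0 <- max(fit$coefficients[1], 1e-8)
  a1 <- max(fit$coefficients[2], 0)
  function(mu) a0 + a1 / mu
}

#' Negative-binomial Wald test of jumping vs plasmid counts
#'
#' Fits, per haplotype, the NB log-linear model
#' `log mu = log s_j + b0 + b1 * jumping_j` by iteratively reweighted least
#' squares with the shrunken dispersion plugged in; `b1 / log(2)` is the raw
#' log2 fold-change and the two-sided Wald p-value uses the normal
#' approximation. Rows with zero totals in one condition get a pseudocount
#' log2 fold-change (`log2((mJ + 1)/(mP + 1))` on normalized means) and an
#' `NA` test; all-zero rows are flagged.
#'
#' @param counts Count matrix or haplotype table.
#' @param sheet A [sample_sheet()].
#' @param sf Size factors (computed if `NULL`).
#' @param dispersion Optional fixed dispersion (scalar or per-row); when
#'   `NULL` the shrunken estimate of [estimate_dispersion()] is used.
#' @param prior_df Passed to [estimate_dispersion()].
#' @param max_iter,tol IRLS controls.
#' @return `data.frame(key, base_mean, log2fc_raw, se, wald, p, dispersion,
#'   status)` with `status` in `ok`/`zero_jumping`/`zero_plasmid`/
#'   `all_zero`.
#' @export
nb_wald_test <- function(counts, sheet, sf = NULL, dispersion = NULL,
                         prior_df = 6, max_iter = 50L, tol = 1e-10) {
  mat <- as_count_matrix(counts, sheet$sample_id)
  if (any(sheet$condition == "plasmid") + any(sheet$condition == "jumping") < 2)
    stop("need both plasmid and jumping samples")
  if (is.null(sf)) sf <- size_factors(mat)
  x <- as.numeric(sheet$condition == "jumping")
  norm <- sweep(mat, 2, sf, "/")
  base_mean <- rowMeans(norm)
  if (is.null(dispersion)) {
    phi <- estimate_dispersion(mat, sheet, sf, prior_df)$used
  } else {
    phi <- rep_len(dispersion, nrow(mat))
  }

  mP <- rowMeans(norm[, x == 0, drop = FALSE])
  mJ <- rowMeans(norm[, x == 1, drop = FALSE])
  status <- rep("ok", nrow(mat))
  status[mJ == 0] <- "zero_jumping"
  status[mP == 0] <- "zero_plasmid"
  status[mP == 0 & mJ == 0] <- "all_zero"
  fit_rows <- status == "ok"

  H <- nrow(mat); S <- ncol(mat)
  b0 <- rep(NA_real_, H); b1 <- rep(NA_real_, H); se1 <- rep(NA_real_, H)
  if (any(fit_rows)) {
    k <- mat[fit_rows, , drop = FALSE]
    ph <- phi[fit_rows]
    lsf <- matrix(log(sf), sum(fit_rows), S, byrow = TRUE)
    bb0 <- log(mP[fit_rows]); bb1 <- log(mJ[fit_rows]) - bb0
    for (it in seq_len(max_iter)) {
      eta <- lsf + bb0 + outer(bb1, x)
      mu <- pmin(exp(eta), 1e12)
      w <- mu / (1 + ph * mu)
      z <- (eta - lsf) + (k - mu) / mu
      Sw <- rowSums(w)
      Swx <- as.vector(w %*% x)
      Szw <- rowSums(w * z)
      Szwx <- as.vector((w * z) %*% x)
      det <- Sw * Swx - Swx^2  # Swxx == Swx for binary x
      nb0 <- (Swx * Szw - Swx * Szwx) / det
      nb1 <- (Sw * Szwx - Swx * Szw) / det
      delta <- max(abs(nb0 - bb0), abs(nb1 - bb1))
      bb0 <- nb0; bb1 <- nb1
      if (delta < tol) break
    }
    eta <- lsf + bb0 + outer(bb1, x)
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + ph * mu)
    Sw <- rowSums(w); Swx <- as.vector(w %*% x)
    det <- Sw * Swx - Swx^2
    b0[fit_rows] <- bb0; b1[fit_rows] <- bb1
    se1[fit_rows] <- sqrt(Sw / det)
  }
  log2fc <- b1 / log(2)
  # pseudocount convention for rows with an all-zero condition
  pc <- status %in% c("zero_jumping", "zero_plasmid")
  log2fc[pc] <- log2((mJ[pc] + 1) / (mP[pc] + 1))
  se <- se1 / log(2)
  wald <- b1 / se1
  p <- 2 * pnorm(-abs(wald))
  data.frame(key = rownames(mat) %||% as.character(seq_len(H)),
             base_mean = base_mean, log2fc_raw = log2fc, se = se,
             wald = wald, p = p, dispersion = phi, status = status,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize fold-changes to the reference haplotype
#'
#' @param results Output of [nb_wald_test()].
#' @param ref_key Key of the wild-type reference haplotype (default `""`).
#' @return `results` with a `log2fc_wt` column
#'   (`log2fc_raw - log2fc_raw(reference)`); the reference row is exactly 0.
#' @export
normalize_to_reference <- function(results, ref_key = "") {
  i <- which(results$key == ref_key)
  if (length(i) != 1 || !is.finite(results$log2fc_raw[i]))
    stop("reference haplotype absent or without a defined fold-change")
  results$log2fc_wt <- results$log2fc_raw - results$log2fc_raw[i]
  results
}

#' Classify haplotypes into jumper classes
#'
#' Applies the study thresholds to WT-normalized fold-changes:
#' `HIGH` (log2FC > `lfc_cut`, p < `p_cut`), `LOW` (log2FC < -`lfc_cut`,
#' p < `p_cut`, jumping reads present), `NON` (log2FC < -`lfc_cut`, zero
#' jumping reads, plasmid total > `nonjumper_plasmid`), `REFERENCE` for the
#' wild-type key, otherwise `UNCLASSIFIED`. The non-jumper rule is
#' count-based by default; set `require_p_non = TRUE` to also demand
#' p < `p_cut` (a Wald p for an all-zero group is convention-dependent).
#'
#' @param results Output of [normalize_to_reference()].
#' @param counts Count matrix or haplotype table (raw counts).
#' @param sheet A [sample_sheet()].
#' @param lfc_cut,p_cut Significance thresholds (defaults 2 and 1e-5).
#' @param nonjumper_plasmid Plasmid floor for non-jumpers (default 50).
#' @param require_p_non Also require p < `p_cut` for `NON`.
#' @param ref_key Wild-type key.
#' @return `results` with `class` and the raw `plasmid_total` /
#'   `jumping_total` columns.
#' @export
classify_jumpers <- function(results, counts, sheet, lfc_cut = 2,
                             p_cut = 1e-5, nonjumper_plasmid = 50,
                             require_p_non = FALSE, ref_key = "") {
  mat <- as_count_matrix(counts, sheet$sample_id)
  idx <- match(results$key, rownames(mat))
  if (anyNA(idx)) stop("results contain keys absent from the count table")
  pt <- rowSums(mat[idx, sheet$condition == "plasmid", drop = FALSE])
  jt <- rowSums(mat[idx, sheet$condition == "jumping", drop = FALSE])
  lfc <- results$log2fc_wt
  p <- results$p
  sig <- !is.na(p) & p < p_cut
  cls <- rep("UNCLASSIFIED", nrow(results))
  cls[!is.na(lfc) & lfc > lfc_cut & sig] <- "HIGH"
  cls[!is.na(lfc) & lfc < -lfc_cut & sig & jt > 0] <- "LOW"
  non <- !is.na(lfc) & lfc < -lfc_cut & jt == 0 & pt > nonjumper_plasmid
  if (require_p_non) non <- non & sig
  cls[non] <- "NON"
  cls[results$key == ref_key] <- "REFERENCE"
  results$class <- cls
  results$plasmid_total <- pt
  results$jumping_total <- jt
  results
}

#' Replicate correlation QC
#'
#' Pearson and Spearman correlations of `log2(count + 1)` between replicate
#' pairs within each condition; a condition is flagged when its minimum
#' Spearman correlation falls below `threshold` (poorly correlating
#' libraries are excluded from analysis, as for elements whose replicates
#' fail to agree).
#'
#' @param counts Count matrix or haplotype table.
#' @param sheet A [sample_sheet()].
#' @param threshold Spearman flag threshold (default 0.3).
#' @return Data frame per condition pair: `condition`, `rep_a`, `rep_b`,
#'   `pearson`, `spearman`, `flagged`.
#' @export
replicate_qc <- function(counts, sheet, threshold = 0.3) {
  mat <- as_count_matrix(counts, sheet$sample_id)
  lg <- log2(mat + 1)
  out <- NULL
  for (cc in unique(sheet$condition)) {
    cols <- sheet$sample_id[sheet$condition == cc]
    if (length(cols) < 2) {
      warning("condition '", cc, "' has fewer than 2 replicates; QC skipped")
      next
    }
    prs <- utils::combn(cols, 2)
    for (j in seq_len(ncol(prs))) {
      a <- lg[, prs[1, j]]; b <- lg[, prs[2, j]]
      sp <- cor(a, b, method = "spearman")
      out <- rbind(out, data.frame(
        condition = cc, rep_a = prs[1, j], rep_b = prs[2, j],
        pearson = cor(a, b), spearman = sp,
        flagged = sp < threshold, stringsAsFactors = FALSE))
    }
  }
  out
}
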