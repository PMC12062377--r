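#' Replicate-conditional regression design
#'
#' Builds the stacked design of the variant-effect model: one row per
#' (replicate, haplotype) with response `log2(jumping_{i,j} + 1)`, one
#' plasmid covariate per replicate (`log2(plasmid_{rep i, j} + 1)` on the
#' rows of replicate i, zero elsewhere), and a binary membership matrix `N`
#' (haplotype x variant) restricted to variants carried by at least
#' `min_carriers` haplotypes.
#'
#' @param table Filtered haplotype table (full-length rows; keys are parsed
#'   back into variant lists).
#' @param sheet A [sample_sheet()] with >= 2 replicates per condition.
#' @param min_carriers Minimum carrier count for a variant column
#'   (default 3).
#' @param pseudocount Added inside both log2 transforms (default 1).
#' @return List: `y`, `plasmid` (matrix of replicate-conditional
#'   covariates), `N` (design-expanded membership), `N_hap`
#'   (haplotype-level membership), `tokens`, `carriers`, `haplotype`,
#'   `replicate`, `variant_pos` (0-based position per token).
#' @export
build_design <- function(table, sheet, min_carriers = 3L, pseudocount = 1) {
  reps <- sort(unique(sheet$replicate))
  if (length(reps) < 2) stop("need at least two replicates per condition")
  pcol <- function(r) sheet$sample_id[sheet$condition == "plasmid" &
                                        sheet$replicate == r]
  jcol <- function(r) sheet$sample_id[sheet$condition == "jumping" &
                                        sheet$replicate == r]
  for (r in reps)
    if (length(pcol(r)) != 1 || length(jcol(r)) != 1)
      stop("each replicate needs exactly one plasmid and one jumping sample")

  vlists <- lapply(sub("\\|.*$", "", table$key), parse_variant_key)
  tokens_by_hap <- lapply(vlists, variant_tokens)
  all_tok <- unlist(tokens_by_hap, use.names = FALSE)
  carriers <- table(all_tok)
  keep_tok <- sort(names(carriers)[carriers >= min_carriers])
  H <- nrow(table); V <- length(keep_tok)
  N_hap <- matrix(0L, H, V, dimnames = list(NULL, keep_tok))
  for (j in seq_len(H)) {
    hit <- intersect(tokens_by_hap[[j]], keep_tok)
    if (length(hit)) N_hap[j, hit] <- 1L
  }
  vpos <- as.integer(sub(":.*$", "", keep_tok))

  y <- numeric(0); plasmid <- NULL; hap <- integer(0); repl <- integer(0)
  for (r in reps) {
    y <- c(y, log2(table[[jcol(r)]] + pseudocount))
    block <- matrix(0, H, length(reps))
    block[, match(r, reps)] <- log2(table[[pcol(r)]] + pseudocount)
    plasmid <- rbind(plasmid, block)
    hap <- c(hap, seq_len(H)); repl <- c(repl, rep(r, H))
  }
  colnames(plasmid) <- sprintf("plasmid_rep%d", reps)
  N <- N_hap[hap, , drop = FALSE]
  list(y = y, plasmid = plasmid, N = N, N_hap = N_hap,
       tokens = keep_tok, carriers = as.integer(carriers[keep_tok]),
       haplotype = hap, replicate = repl, variant_pos = vpos,
       min_carriers = min_carriers, pseudocount = pseudocount)
}

ols_with_se <- function(X, y) {
  qr_x <- qr(X)
  r <- qr_x$rank
  piv <- qr_x$pivot
  coefs <- qr.coef(qr_x, y)  # NA for aliased columns
  used <- piv[seq_len(r)]
  fitted <- X[, used, drop = FALSE] %*% coefs[used]
  resid <- y - fitted
  df <- length(y) - r
  sigma2 <- sum(resid^2) / df
  Rm <- qr.R(qr_x)[seq_len(r), seq_len(r), drop = FALSE]
  XtXinv <- chol2inv(Rm)
  se <- rep(NA_real_, ncol(X))
  se[used] <- sqrt(pmax(diag(XtXinv), 0) * sigma2)
  names(se) <- colnames(X)
  tstat <- coefs / se
  p <- 2 * stats::pt(-abs(tstat), df)
  list(coef = coefs, se = se, t = tstat, p = p, df = df, sigma2 = sigma2,
       aliased = colnames(X)[piv[-seq_len(r)]], rank = r)
}

#' Fit the per-variant activity model
#'
#' Ordinary least squares of the replicate-conditional design; the
#' coefficients on the `N` columns are the per-variant effects in log2
#' jumping units. Collinear variant columns are dropped and reported as
#' aliased.
#'
#' @param design Output of [build_design()].
#' @return List: `effects` (`data.frame(variant, pos, coefficient, se, t, p,
#'   carriers)`), `plasmid_slopes`, `intercept`, `aliased`, `fit` (full OLS
#'   summary object).
#' @export
fit_variant_model <- function(design) {
  X <- cbind(`(Intercept)` = 1, design$plasmid, design$N)
  fit <- ols_with_se(X, design$y)
  vcols <- design$tokens
  eff <- data.frame(variant = vcols,
                    pos = design$variant_pos,
                    coefficient = unname(fit$coef[vcols]),
                    se = unname(fit$se[vcols]),
                    t = unname(fit$t[vcols]),
                    p = unname(fit$p[vcols]),
                    carriers = design$carriers,
                    stringsAsFactors = FALSE)
  list(effects = eff,
       plasmid_slopes = fit$coef[colnames(design$plasmid)],
       intercept = fit$coef["(Intercept)"],
       aliased = intersect(fit$aliased, vcols),
       fit = fit)
}

#' 5-bp sliding-window activity profile
#'
#' For each window of `window` consecutive reference positions (1-bp step,
#' partial end windows skipped) the variant membership matrix is replaced by
#' a single indicator — "haplotype carries at least one variant positioned
#' in the window" — and the replicate-conditional model is refit. The
#' window coefficient is assigned to the window's center position.
#'
#' @param design Output of [build_design()] (built with `min_carriers = 1`
#'   if every variant should contribute).
#' @param ref_length Reference length in bases.
#' @param window Window width (default 5).
#' @param step Offset between windows (default 1).
#' @return `data.frame(start, center, coefficient, se, t, p, n_variants,
#'   n_haplotypes)`; windows containing no variant have `NA` coefficients.
#' @export
window_profile <- function(design, ref_length, window = 5L, step = 1L) {
  if (ref_length < window) stop("reference shorter than the window")
  starts <- seq.int(0L, ref_length - window, by = step)
  base_X <- cbind(`(Intercept)` = 1, design$plasmid)
  H <- nrow(design$N_hap)
  out <- data.frame(start = starts, center = starts + (window %/% 2L),
                    coefficient = NA_real_, se = NA_real_, t = NA_real_,
                    p = NA_real_, n_variants = 0L, n_haplotypes = 0L)
  for (i in seq_along(starts)) {
    w0 <- starts[i]; w1 <- w0 + window
    in_w <- design$variant_pos >= w0 & design$variant_pos < w1
    out$n_variants[i] <- sum(in_w)
    if (!any(in_w)) next
    ind_hap <- as.integer(rowSums(design$N_hap[, in_w, drop = FALSE]) > 0)
    out$n_haplotypes[i] <- sum(ind_hap)
    ind <- ind_hap[design$haplotype]
    fit <- ols_with_se(cbind(base_X, window = ind), design$y)
    out$coefficient[i] <- fit$coef[["window"]]
    out$se[i] <- fit$se[["window"]]
    out$t[i] <- fit$t[["window"]]
    out$p[i] <- fit$p[["window"]]
  }
  out
}
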