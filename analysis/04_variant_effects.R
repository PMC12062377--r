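#!/usr/bin/env Rscript
# Per-variant activity coefficients from the replicate-conditional linear
# model, plus the 5-bp sliding-window profile along each element.

source("analysis/common.R")

for (ref_id in names(an_refs)) {
  tab <- read.table(an_path(ref_id, "_filtered.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(key = "character"))
  tab$key[is.na(tab$key)] <- ""
  des <- build_design(tab, an_sheet, min_carriers = 3L)
  if (length(des$tokens)) {
    fit <- fit_variant_model(des)
    write.table(fit$effects, an_path(ref_id, "_variant_effects.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    top <- fit$effects[order(-abs(fit$effects$coefficient)), ][1:5, ]
    cat(sprintf("%s: %d variant columns fitted (%d aliased dropped)\n",
                ref_id, length(des$tokens), length(fit$aliased)))
    cat("  strongest effects:", paste(sprintf("%s (%+.2f)", top$variant,
                                              top$coefficient),
                                      collapse = ", "), "\n")
  }
  wp <- window_profile(des, an_refs[[ref_id]]$length)
  write.table(wp, an_path(ref_id, "_windows.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  peak <- wp[which.max(abs(wp$coefficient)), ]
  cat(sprintf("  %d windows; peak |coefficient| %.2f at center %d (SRP regions: [%d,%d) and [%d,%d))\n",
              nrow(wp), abs(peak$coefficient), peak$center,
              an_refs[[ref_id]]$srp_left[1], an_refs[[ref_id]]$srp_left[2],
              an_refs[[ref_id]]$srp_right[1],
              an_refs[[ref_id]]$srp_right[2]))
}
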