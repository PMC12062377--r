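#!/usr/bin/env Rscript
# Hypergeometric enrichment of jumper-class variants in the SRP binding
# regions (one-sided, BH-corrected across class x region tests) and
# position frequency matrices for logo rendering.

source("analysis/common.R")

vars_of <- function(keys) unique(unlist(lapply(
  sub("\\|.*$", "", keys),
  function(k) variant_tokens(parse_variant_key(k)))))

enr_all <- NULL
for (ref_id in names(an_refs)) {
  ref <- an_refs[[ref_id]]
  res <- read.table(an_path(ref_id, "_differential.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(key = "character"))
  res$key[is.na(res$key)] <- ""
  sets <- list(high = vars_of(res$key[res$class == "HIGH"]),
               low_non = vars_of(res$key[res$class %in% c("LOW", "NON")]))
  sets <- sets[vapply(sets, length, 1L) > 0]
  if (!length(sets)) next
  enr <- hypergeom_enrichment(
    sets, vars_of(res$key),
    list(srp_left = ref$srp_left, srp_right = ref$srp_right,
         srp_both = list(ref$srp_left, ref$srp_right)))
  enr$library <- ref_id
  enr_all <- rbind(enr_all, enr)

  for (cl in names(sets)) {
    keys <- if (cl == "high") res$key[res$class == "HIGH"]
            else res$key[res$class %in% c("LOW", "NON")]
    if (!length(keys)) next
    for (rg in c("srp_left", "srp_right")) {
      pfm <- position_frequency_matrix(keys, ref, ref[[rg]])
      write.table(round(pfm$matrix, 4),
                  an_path(ref_id, "_pfm_", cl, "_", rg, ".tsv"),
                  sep = "\t", quote = FALSE)
    }
  }
}
enr_all$p_adj <- bh_adjust(enr_all$p)
write.table(enr_all, an_path("enrichment.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
for (i in seq_len(nrow(enr_all)))
  cat(sprintf("%s %-8s %-9s k/n = %d/%d vs K/N = %d/%d  p = %.3g  p_adj = %.3g\n",
              enr_all$library[i], enr_all$class[i], enr_all$region[i],
              enr_all$k[i], enr_all$n[i], enr_all$K[i], enr_all$N[i],
              enr_all$p[i], enr_all$p_adj[i]))
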