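#!/usr/bin/env Rscript
# Differential activity: median-of-ratios normalization, NB Wald test of
# jumping vs plasmid counts, WT-normalized log2 fold-changes, jumper
# classification and replicate QC, per library.

source("analysis/common.R")

for (ref_id in names(an_refs)) {
  tab <- read.table(an_path(ref_id, "_filtered.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(key = "character"))
  tab$key[is.na(tab$key)] <- ""
  res <- nb_wald_test(tab, an_sheet)
  res <- normalize_to_reference(res, ref_key = "")
  res <- classify_jumpers(res, tab, an_sheet)
  qc <- replicate_qc(tab, an_sheet)
  write.table(res, an_path(ref_id, "_differential.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(qc, an_path(ref_id, "_qc.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  cls <- table(res$class)
  cat(sprintf(
    "%s: %d haplotypes tested; %d high, %d low, %d non-jumpers; plasmid Spearman %.2f, jumping %.2f\n",
    ref_id, nrow(res),
    sum(res$class == "HIGH"), sum(res$class == "LOW"),
    sum(res$class == "NON"),
    qc$spearman[qc$condition == "plasmid"][1],
    qc$spearman[qc$condition == "jumping"][1]))
  if (any(qc$flagged))
    cat(ref_id, ": WARNING, replicate correlation below threshold;",
        "this library would be excluded from downstream analysis\n")
}
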