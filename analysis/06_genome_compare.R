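#!/usr/bin/env Rscript
# Compare jumping haplotypes to a synthetic genomic AluS-like element set
# by Levenshtein edit distance: per-class distance distributions and the
# genomic elements nearest to any high jumper (candidate reactivations).

source("analysis/common.R")

genomic <- simulate_genomic_alus(an_refs[[1]], n = 100,
                                 divergence = c(0.02, 0.10),
                                 seed = an_seed + 600L)
write.table(data.frame(element = names(genomic), sequence = genomic),
            an_path("genomic_alus_synthetic.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ref_id <- names(an_refs)[1]
tab <- read.table(an_path(ref_id, "_filtered.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(key = "character"))
tab$key[is.na(tab$key)] <- ""
res <- read.table(an_path(ref_id, "_differential.tsv"), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(key = "character"))
res$key[is.na(res$key)] <- ""

jump <- tab[tab$jumping_detected, ]
cls <- res$class[match(jump$key, res$key)]
seqs <- setNames(jump$sequence, jump$key)
dr <- min_distances(seqs, genomic, classes = cls)
write.table(dr$per_haplotype, an_path("distances.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(dr$per_class, an_path("distances_by_class.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%s: %d jumping haplotypes vs %d genomic elements; closest is %d mismatches away\n",
            ref_id, length(seqs), length(genomic),
            min(dr$per_haplotype$min_distance)))
print(dr$per_class)

high_seqs <- seqs[!is.na(cls) & cls == "HIGH"]
if (length(high_seqs)) {
  na <- nearest_activators(genomic, high_seqs, k_max = 16L)
  write.table(na, an_path("nearest_activators.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%d genomic elements within 16 edits of a high jumper\n",
              nrow(na)))
}
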