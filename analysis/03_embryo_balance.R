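#!/usr/bin/env Rscript
# Classify each imaged blastocyst as balanced or unbalanced in lineage
# contribution to the embryonic/abembryonic poles, under all three counting
# methods, and compare with the generator's truth.
suppressMessages(library(lineageseq))

counts <- read_image_counts("results/synthetic/image_counts.tsv")
truth <- read.delim("results/synthetic/image_truth.tsv")

res <- do.call(rbind, lapply(c("one_third", "half", "all"), function(m)
  balance_classify(counts, m)))
write.table(res, "results/balance.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
summ <- summarize_balance(res)
write.table(summ, "results/balance_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(summ, row.names = FALSE)

one <- res[res$method == "one_third" & res$included, ]
agree <- merge(one, truth, by = "embryo_id")
cat(sprintf("one-third method agrees with generator truth for %d/%d included embryos\n",
            sum((agree$classification == "unbalanced") == agree$unbalanced),
            nrow(agree)))
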