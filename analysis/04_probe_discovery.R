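#!/usr/bin/env Rscript
# Rediscover the ARG box de novo from synthetic band-shift probe sets: 30
# positive probes each carrying one box sampled from the model, 20 negative
# probes of matched high-GC background, searched with the discriminative
# palindromic ZOOPS EM.

library(argboxr)

dir.create("results", showWarnings = FALSE)

model <- build_arg_model()
seed <- 5L

probes <- generate_probe_sets(model, n_pos = 30, n_neg = 20,
                              probe_len = 100, seed = seed)
write_fasta(probes$positives, "results/probes_positive.fa")
write_fasta(probes$negatives, "results/probes_negative.fa")

motif <- em_discover(probes$positives, probes$negatives,
                     width_min = 20, width_max = 20,
                     mode = "zoops", palindrome = TRUE, seed = seed)

planted <- build_model(build_pfm(probes$truth$box1_seq, both_strands = TRUE))
planted_cons <- as.character(consensus_sequence(planted))
hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
dist <- min(hd(motif$consensus, planted_cons),
            hd(reverse_complement(motif$consensus), planted_cons))

cat("Discovered consensus :", motif$consensus, "\n")
cat("Planted-box consensus:", planted_cons, "\n")
cat("Hamming distance (up to strand):", dist, "\n")
cat("Site calls:", nrow(motif$site_calls), "of", length(probes$positives),
    "positive probes;", "EM objective monotone:",
    motif$min_trace_delta >= -1e-8, "\n")

utils::write.table(motif$site_calls, "results/discovery_site_calls.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
aligned <- site_calls_to_alignment(motif, probes$positives)
rebuilt <- build_model(build_pfm(aligned, both_strands = TRUE))
write_model(rebuilt, "results/discovered_model.txt")
cat(sprintf("Rebuilt model conservation: %.2f bits (planted boxes: %.2f)\n",
            rebuilt$rsequence, planted$rsequence))
run_config("results/04_probe_discovery.yaml", step = "probe_discovery",
           seed = seed, n_pos = 30, n_neg = 20, probe_len = 100,
           width = 20, mode = "zoops", palindrome = TRUE)
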