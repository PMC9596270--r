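#!/usr/bin/env Rscript
# Step 2 — run the emotion-transfer analysis on the simulated dataset.
#
# Labels every photogram with the EMFACS conjunction rules, pairs each
# original with its fakes, and writes the full report: recording rates per
# performer and emotion (table2.csv), pooled per-emotion agreement counts
# and percentages (table3.csv), per-performer all-emotions totals
# (table4.csv), the per-performer scatter quantities per emotion
# (figure_data_*.csv), and the zero-baseline exclusion list.

library(emotransfer)

res <- run_analyze("results/synthetic", "results/tables")

cat("== pooled agreement by emotion (table3) ==\n")
print(res$by_emotion, n = 20)
cat("\n== per-performer totals (table4) ==\n")
print(res$by_performer, n = 12)
cat("\n== zero-baseline exclusions ==\n")
print(res$exclusions$summary)
cat("\nAt fidelity 0.7 multi-AU emotions (Fear, Anger) keep far lower\n")
cat("common percentages than Happiness: losing any one required AU breaks\n")
cat("the whole conjunction, so rules with more AUs degrade fastest.\n")
cat("report written to results/tables\n")
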