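#!/usr/bin/env Rscript
# Stage 4 — exercise the bench-quantification formulas.
#
# Simulates a small qPCR Ct table for the marker panel and computes
# relative expression under both sign conventions; fits a nitrite-style
# standard curve from a serial dilution; prints tumor-volume and
# arginase-unit examples. Writes results/quant/.

suppressPackageStartupMessages(library(polarnet))
dir.create("results/quant", recursive = TRUE, showWarnings = FALSE)

# Marker-like Ct profile: M2 markers abundant (low Ct), M1 markers scarce
ct <- generate_ct_table(genes = c("ARG1", "MRC1", "RETNLA", "IL1B", "TNF"),
                        ct_gene_mean = c(21, 23, 24, 28, 27),
                        ct_reference_mean = 18, noise_sd = 0.15,
                        n_replicates = 3L, rng_seed = 11L)
ct$rel_expr <- relative_expression(ct$ct_gene, ct$ct_reference)
ct$rel_expr_as_printed <- relative_expression(ct$ct_gene, ct$ct_reference,
                                              sign_convention = "as_printed")
write.table(ct, "results/quant/ct_relative_expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
means <- sort(tapply(ct$rel_expr, ct$gene, mean), decreasing = TRUE)
cat("mean relative expression (x100, vs. reference gene):\n")
print(round(means, 3))

# Standard curve from a 0.25 mM serial halving dilution
conc <- 0.25 / 2^(0:7)
set.seed(11)
absb <- 1.6 * conc + 0.04 + rnorm(8, sd = 0.003)
curve <- fit_standard_curve(conc, absb)
cat(sprintf("standard curve: slope %.4f, intercept %.4f, r^2 %.4f\n",
            curve$slope, curve$intercept, curve$r_squared))
cat(sprintf("absorbance 0.12 -> %.4f mM nitrite\n",
            interpolate_concentration(curve, 0.12)))
jsonlite::write_json(curve[c("slope", "intercept", "r_squared")],
                     "results/quant/standard_curve.json",
                     auto_unbox = TRUE, digits = NA)

cat(sprintf("tumor_volume(10 mm, 5 mm) = %.1f mm^3\n", tumor_volume(10, 5)))
cat(sprintf("arginase_units(4.5 umol, 45 min) = %.2f U\n",
            arginase_units(4.5, 45)))
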