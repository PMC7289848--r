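#!/usr/bin/env Rscript
# Fit the scaling models to the measured per-cell table: power law in
# double-logarithmic space with a 50,000-resample bootstrap CI for the
# exponent, compared against linear and logarithmic models; binned means
# for plotting. Writes the JSON fit report and the binned means.

suppressPackageStartupMessages(library(ringscale))

tab <- read.csv("results/per_cell_summary.csv")
report <- run_fit(tab, n_boot = 50000, seed = 1,
                  out_json = "results/fit_report.json")
write.csv(report$binned, "results/binned_means.csv", row.names = FALSE)
print(report)

# geometry regression: d against V^(1/3) and elongation-like L / V^(1/3)
acc <- tab[tab$accepted, ]
reg <- two_var_regression(acc$median_d_um, acc$median_volume_fL^(1 / 3),
                          acc$median_length_um / acc$median_volume_fL^(1 / 3))
cat(sprintf("two-variable regression: d = %.2f V^(1/3) %+.2f L/V^(1/3) %+.2f\n",
            reg$coefficients[["x1"]], reg$coefficients[["x2"]],
            reg$coefficients[["offset"]]))
cat(sprintf("  p-values: %.3g (V^(1/3)), %.3g (L/V^(1/3))\n",
            reg$p_values[["x1"]], reg$p_values[["x2"]]))
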