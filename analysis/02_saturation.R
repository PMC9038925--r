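#!/usr/bin/env Rscript
# Saturation analysis: how many cultures are needed to observe essentially
# all accessible regions? Builds the random-subsampling discovery curve on
# a heavy-tailed sharing cohort, fits P(x) = a + B*exp(c*x), and inverts
# the fit for the 99%-of-asymptote sample number.

suppressPackageStartupMessages(library(gscatac))
seed <- 20260921
dir.create("results", showWarnings = FALSE)

presence <- generate_saturation_presence(60, 50000, sharing_exponent = 1.5,
                                         seed = seed)
hist <- presence_histogram(presence)
data.table::fwrite(hist, "results/presence_histogram.tsv", sep = "\t")
cat(sprintf("%.1f%% of peaks are private to a single culture; %.1f%% are in all 60.\n",
            100 * hist$n_peaks[1] / sum(hist$n_peaks),
            100 * hist$n_peaks[60] / sum(hist$n_peaks)))

curve <- build_saturation_curve(presence, n_draws = 50, seed = seed + 1)
fit <- fit_saturation_model(curve)
n99 <- saturation_sample_size(fit, 0.99)
data.table::fwrite(data.frame(x = curve$x, mean = curve$mean, sd = curve$sd),
                   "results/saturation_curve.tsv", sep = "\t")
jsonlite::write_json(list(a = fit$a, B = fit$B, c = fit$c, sse = fit$sse,
                          n_saturation_99pct = n99),
                     "results/saturation_fit.json", auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("Fitted asymptote %.0f predicted accessible regions (observed %.0f);\n",
            fit$a, curve$mean[60]))
cat(sprintf("99%% of the asymptote is reached with %d cultures.\n", n99))
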