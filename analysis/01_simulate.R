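#!/usr/bin/env Rscript
# Step 1: simulate the measurement campaign.
#
# Generates the working-standard calibration campaign (5 R levels of about
# 30/40/50/60/70%, duplicate mixtures, 10 scans each), three test mixtures
# of "unknown" powder at the working level, and an ICH-style validation
# campaign, then writes everything as plain-text fixture directories under
# results/sim/ (manifest.csv + one CSV per scan + truth.json).

suppressPackageStartupMessages(library(irquant))

seed <- 20260927L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

camp <- simulate_calibration_campaign(seed = seed)
export_campaign(file.path(out, "calibration"), camp$scansets, camp$records)
cat(sprintf("calibration: %d mixtures, %d spectra, R %.1f-%.1f%%\n",
            nrow(camp$records),
            sum(vapply(camp$scansets, function(s) length(s$spectra), 1L)),
            min(design_r(camp$records)), max(design_r(camp$records))))

tests <- lapply(1:3, function(i) {
  simulate_test_mixture(true_content = STOCK_CONTENT, seed = seed + i,
                        mixture_id = sprintf("test-%02d", i))
})
truth <- setNames(lapply(tests, `[[`, "true_content"),
                  vapply(tests, function(t) t$record$mixture_id, ""))
export_campaign(file.path(out, "test"),
                lapply(tests, `[[`, "scans"),
                do.call(rbind, lapply(tests, `[[`, "record")),
                truth = truth)
cat(sprintf("test mixtures: %d, 5 scans each, designed R = 50%%\n",
            length(tests)))

val <- simulate_validation_campaign(seed = seed + 100L)
export_campaign(file.path(out, "validation"), val$scansets, val$records)
cat(sprintf("validation: %d mixtures at levels %s (plus day 2 at 50)\n",
            nrow(val$records),
            paste(unique(val$records$level_label), collapse = "/")))
cat("wrote", out, "\n")
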