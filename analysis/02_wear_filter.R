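#!/usr/bin/env Rscript
# Stage 2 — detect non-wear (60-minute zero windows with up to 2 sub-100
# interruption minutes) and apply the half-week compliance filter: subjects
# must wear the device at least half of the expected 7 x 900 daytime minutes.
library(actigad)

series <- read_epoch_table("results/epochs.csv")
masks <- lapply(series, detect_nonwear, params = nonwear_params())
filt <- compliance_filter(masks, threshold_fraction = 0.5)

data.table::fwrite(filt$report, "results/wear_report.csv")
writeLines(filt$included, "results/included_ids.txt")

cat(sprintf("%d of %d subjects wore the device at least half the week (%.1f%%).\n",
            length(filt$included), length(series),
            100 * length(filt$included) / length(series)))
cat(sprintf("Mean wear fraction among excluded subjects: %.1f%%.\n",
            100 * mean(filt$report$wear_fraction[!filt$report$included])))
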