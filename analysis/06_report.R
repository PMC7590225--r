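#!/usr/bin/env Rscript
# Render the human-readable markdown report for the default synthetic study.

suppressPackageStartupMessages(library(communitygreen))

bundle <- run_pipeline(world_config(seed = 1))
dir.create("results", showWarnings = FALSE)
writeLines(render_report(bundle), "results/report.md")
cat("wrote results/report.md\n")
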