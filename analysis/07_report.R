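#!/usr/bin/env Rscript
# Stage 7 -- assemble the run report.
#
# Re-reads the persisted stage tables under results/ and writes
# results/report.txt: per-site events, adjusted means, model summary.

library(droughtring)

path <- report("results")
cat(readLines(path), sep = "\n")
cat("\nReport written to", path, "\n")
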