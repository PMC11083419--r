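#!/usr/bin/env Rscript
# Thin command-line wrapper over the lamorph pipeline.
# Usage: Rscript scripts/lam3d.R <subcommand> [--flags]
library(lamorph)
status <- lam_cli(commandArgs(trailingOnly = TRUE))
quit(status = status, save = "no")
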