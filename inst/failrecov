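#!/usr/bin/env Rscript
# Thin command-line front-end; all logic lives in the failrecov package.
suppressPackageStartupMessages(library(failrecov))
quit(save = "no", status = failrecov_cli(commandArgs(trailingOnly = TRUE)))
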