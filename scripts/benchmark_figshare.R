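#!/usr/bin/env Rscript
# Optional real-data benchmark; the script itself ships with the installed
# package (see its header for the figshare download and data layout).
source(system.file("scripts", "benchmark_figshare.R", package = "fecgx"))
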