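#!/usr/bin/env Rscript
# End-to-end comparison: semiclassical, path-integral and Rayleigh routes
# to the bulk enrichment factor of each element on a self-consistent toy
# scenario. Writes the machine-readable report bundle.

suppressPackageStartupMessages(library(isokie))

cfg_path <- system.file("extdata", "demo_config.yaml", package = "isokie")
cfg <- validate_config(cfg_path)
report <- run_demo(cfg, outdir = "results/demo")

cat("\nPer-element enrichment factors (permil) by route:\n")
print(report$table, row.names = FALSE)
h <- report$kie_pi_h
cat(sprintf(
  "\ntransfer-H PI KIE: %.3f +/- %.3f (finite-P closed-form %.3f)\n",
  h$value, h$se, h$finite_P_reference))
cat("The Rayleigh route recovers the generator truth within its fit\n")
cat("error, and the PI route agrees with the semiclassical route up to\n")
cat("the documented finite-bead offset; report under results/demo/.\n")
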