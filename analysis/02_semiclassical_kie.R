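#!/usr/bin/env Rscript
# Position-specific semiclassical (Bigeleisen) KIEs for the three elements
# on the transfer toys, element-wise bulk averages and enrichment factors,
# and the inverse-secondary back-inference for the hydrogen paradox: a
# primary H KIE of 4-5 forces the accompanying secondary effects to be
# inverse if the bulk value is to stay near -160 permil.

suppressPackageStartupMessages(library(isokie))
dir.create("results", showWarnings = FALSE)

cfg <- default_run_config()
th <- thermo_settings(cfg$temperature)
rx <- lapply(cfg$toys, function(tc) {
  make_toy_reaction(toy_system_spec(
    "collinear-transfer", masses = tc$masses, distances = tc$distances,
    k_bonds = tc$k_reactant, k_bend = tc$k_bend, ts_k_bonds = tc$k_ts,
    ts_k_couple = tc$couple_ts, ts_k_bend = tc$ts_k_bend),
    labels = tc$labels)
})

records <- list()
bulk_rows <- list()
for (el in c("C", "Cl", "H")) {
  sc <- cfg$substitutions[[el]]
  sub <- isotope_substitution(sc$index, el)
  fr <- isotopolog_frequency_sets(rx[[sc$toy]]$reactant, sub)
  ft <- isotopolog_frequency_sets(rx[[sc$toy]]$ts, sub)
  prim <- semiclassical_kie(fr$light, fr$heavy, ft$light, ft$heavy, th,
                            position = paste0(el, "1"), element = el)
  n <- cfg$n_positions[[el]]
  secs <- replicate(n - 1, position_kie(paste0(el, "s"), el,
                                        cfg$secondary[[el]],
                                        provenance = "assumed"),
                    simplify = FALSE)
  bulk <- average_kie(c(list(prim), secs))
  enr <- enrichment_from_kie(bulk)
  records <- c(records, list(prim), secs)
  bulk_rows[[el]] <- data.frame(element = el, kie_primary = prim$kie,
                                kie_secondary = cfg$secondary[[el]],
                                kie_av = bulk$kie_av, n = n,
                                epsilon_permil = enr$epsilon_permil)
  cat(sprintf("%-2s primary KIE %.4f, bulk KIE_av %.4f -> eps %.2f permil\n",
              el, prim$kie, bulk$kie_av, enr$epsilon_permil))
}
write_kie_table(records, "results/position_kies.csv")
write.csv(do.call(rbind, bulk_rows), "results/bulk_epsilon.csv",
          row.names = FALSE)

## what secondary average would reconcile a 4.5 primary with -160 permil?
inv <- infer_secondary_average(-160, primary_kie = 4.5, n = 6)
cat(sprintf(
  "bulk H of -160 permil with primary 4.5 needs secondary average %.3f%s\n",
  inv$secondary_mean,
  if (inv$inverse) " -- inverse (below unity)" else ""))

## ensemble spread of a weakly fractionating position across model variants
st <- model_ensemble_stats(c(1.0022, 1.0025, 1.0027, 1.0030, 1.0031))
cat(sprintf("model-ensemble example: %.4f +/- %.4f\n", st$mean, st$sd))
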