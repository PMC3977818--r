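#!/usr/bin/env Rscript
# dsRNA dosimetry: convert the experimental doses (ug scale) into
# molecules per cell through the mass-per-molecule / cell-volume chain.
library(iircross)
dir.create("results", showWarnings = FALSE)

cat("one 300-bp dsRNA molecule:",
    format(molecule_mass_ug(300, 650), digits = 3), "ug",
    sprintf("(%.0f kDa)\n", 300 * 650 / 1000))

ref <- molecules_per_cell(dose_model(4))
cat("4 ug/ml in a 4200 um^3 cell: upper bound",
    format(ref$upper_bound, digits = 3),
    "molecules; working value", format(ref$working, digits = 3), "\n")

doses <- c(0, 0.1, 1, 4, 5, 10, 20, 50)
tab <- data.frame(
  dose_ug = doses,
  upper_bound = vapply(doses, function(d)
    molecules_per_cell(dose_model(d))$upper_bound, numeric(1)),
  working_molecules = ug_to_molecules(doses))
write.csv(tab, "results/dosimetry.csv", row.names = FALSE)
print(tab)
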