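#!/usr/bin/env Rscript
# Step 4: worked arithmetic. (a) Pigment stoichiometry: how many astaxanthin
# molecules per monomer cannot be coupled to the Chls. (b) Branching yields
# of the target models: which fraction of the excitation flows through each
# pathway, from the rate constants alone.

suppressMessages(library(tafit))
out_dir <- "results/arithmetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_unc <- unconnected_carotenoids(chl_per_monomer = 14, chl_car_ratio = 2.37,
                                 n_binding_sites = 3)
message("14 Chls / (Chl/Car = 2.37) ~ ", round(14 / 2.37), " carotenoids; ",
        "3 binding sites -> ", n_unc, " unconnected astaxanthins per monomer")
writeLines(sprintf("unconnected_astaxanthin\t%d", n_unc),
           file.path(out_dir, "stoichiometry.tsv"))

for (nm in list_schemes()) {
  by <- branching_yields(load_scheme(nm))
  write.table(by, file.path(out_dir, sprintf("yields_%s.tsv", nm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gs <- by[by$to == "GS", ]
  message(nm, ": ground-state loss shares -- ",
          paste(sprintf("%s %.1f%%", gs$from, 100 * gs$yield), collapse = ", "))
}
message("Yields written under ", out_dir)
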