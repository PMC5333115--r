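#!/usr/bin/env Rscript
# Generate the synthetic raw data the rest of the workflow consumes:
# a pure-R reference injection, a composition series on the achiral column,
# a racemate resolved on the chiral column, and a pseudo-molecule TDDFT-style
# transition table with its mirror image.

library(chiroptic)

out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

det <- detector_model(noise_sd_rel = 0.01, seed = 101)

# composition series: R fraction 0..1 at fixed total concentration,
# with leftover substrate so conversion is non-trivial
f_grid <- seq(0, 1, by = 0.25)
truths <- list()
for (i in seq_along(f_grid)) {
  det$seed <- 101 + i
  gen <- gen_chromatogram(
    mixture_spec(total_conc = 1, f_R = f_grid[i], substrate_conc = 0.2),
    "achiral", detector = det)
  gen$chrom$meta$sample_id <- sprintf("mix_f%03d", round(100 * f_grid[i]))
  write_chromatogram(gen$chrom,
                     file.path(out_dir, sprintf("achiral_f%03d.csv",
                                                round(100 * f_grid[i]))))
  truths[[i]] <- c(list(sample_id = gen$chrom$meta$sample_id), gen$truth)
}
jsonlite::write_json(truths, file.path(out_dir, "achiral_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# noise-free pure-R reference (defines g_pure for the ee calculation)
ref <- gen_chromatogram(mixture_spec(f_R = 1), "achiral",
                        detector = detector_model())
write_chromatogram(ref$chrom, file.path(out_dir, "reference_pure_R.csv"))

# racemate on the chiral column: two resolved, ECD-mirrored peaks
rac <- gen_chromatogram(mixture_spec(total_conc = 2, f_R = 0.5,
                                     substrate_conc = 0.3),
                        "chiral", step = 0.02,
                        detector = detector_model(noise_sd_rel = 0.01,
                                                  seed = 150))
write_chromatogram(rac$chrom, file.path(out_dir, "chiral_racemate.csv"))

# pseudo-molecule transition tables (synthetic stand-ins for TDDFT output)
cs_R <- gen_transition_table(n_conformers = 5, n_transitions = 20,
                             seed = 160)
write_transition_table(cs_R, file.path(out_dir,
                                       "transitions_pseudoR_synthetic.csv"))
write_transition_table(mirror_transitions(cs_R),
                       file.path(out_dir,
                                 "transitions_pseudoS_synthetic.csv"))

message("simulated ", length(f_grid), " achiral mixtures (f_R = ",
        paste(f_grid, collapse = ", "), "), 1 reference, 1 chiral ",
        "racemate and 2 transition tables under ", out_dir)
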