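#!/usr/bin/env Rscript
# Step 1: simulate every cohort the downstream analyses consume.
#
# Emulates the three-phase study design: an exploratory untargeted cohort
# (200 cases / 100 controls, two ionization modes, pooled QCs every 10
# injections, injection-order drift, 5% below-detection censoring), three
# targeted SIL-IS cohorts (training 283/140, test 150/126, independent
# validation 70/42, each with 13 calibrators and 4 QC levels per analyte),
# and an NAC cohort with a pCR effect confined to inosine in TNBC.

suppressMessages(library(metabopanel))

seed <- 11
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- untargeted exploratory cohort (two ionization modes)")
modes <- generate_two_mode_cohort(
  cohort_spec(n_features = 479),   # ESI+ scale
  cohort_spec(n_features = 269),   # ESI- scale
  seed = seed)
for (m in names(modes)) {
  write_feature_table(modes[[m]],
                      file.path(out, sprintf("exploratory_%s.tsv", m)),
                      file.path(out, sprintf("exploratory_%s_metadata.tsv", m)))
  truth <- attr(modes[[m]], "truth")
  writeLines(truth$planted, file.path(out, sprintf("planted_%s.txt", m)))
  print(modes[[m]])
  message(sprintf("   %s: %d planted features at log2FC %.1f", m,
                  length(truth$planted), truth$planted_log2fc))
}

message("-- targeted cohorts (SIL-IS MRM runs)")
sizes <- list(training = c(283, 140), test = c(150, 126),
              validation = c(70, 42))
for (i in seq_along(sizes)) {
  nm <- names(sizes)[i]
  run <- generate_targeted_run(
    targeted_panel_spec(n_case = sizes[[i]][1], n_control = sizes[[i]][2]),
    seed + 200 + i)
  write_targeted_run(run, file.path(out, sprintf("targeted_%s.tsv", nm)))
  utils::write.table(attr(run, "truth"),
                     file.path(out, sprintf("targeted_%s_truth.tsv", nm)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("   %s: %d case / %d control subjects", nm,
                  sizes[[i]][1], sizes[[i]][2]))
}

message("-- NAC cohort (pCR effect on inosine, TNBC only)")
nac <- generate_nac_cohort(nac_cohort_spec(effect_d = 1.0), seed + 400)
utils::write.table(nac$concentrations, file.path(out, "nac_concentrations.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(nac$metadata, file.path(out, "nac_metadata.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
print(table(nac$metadata$subtype, nac$metadata$response))
message("done: inputs written under ", out)
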