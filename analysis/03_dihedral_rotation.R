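#!/usr/bin/env Rscript
# CCDA analysis. Two parts:
#  (a) classify the published per-residue CCDA values of the RadA linker
#      region (I71-K88) into rotary and zero-rotary residues;
#  (b) validate the recovery machinery end to end by programming the same
#      winding pattern into a synthetic backbone trajectory (10 degrees of
#      angular noise) and re-deriving the table and classification from the
#      simulated coordinates alone.

library(radmotor)

dir.create("results/ccda", showWarnings = FALSE, recursive = TRUE)

ref <- rada_linker_ccda()
cls <- classify_rotary(ref)
cat("Reference linker table (I71-K88):\n")
cat("  zero-rotary residues:", paste(cls$zero_rotary, collapse = ", "),
    "->", length(cls$zero_rotary), "residues\n")
cat("  rotary residues:     ", paste(cls$rotary, collapse = ", "),
    "->", length(cls$rotary), "residues\n")
cat("The five zero-rotary residues are the proposed axis of the rotary",
    "motion;\nnote 73 and 85 carry a single 360-degree entry and are",
    "rotary under the\nzero/nonzero rule.\n\n")

topo <- build_backbone(-57, -47, n_residues = 20)
region <- 2:19
prog <- data.frame(residue_id = integer(0), angle = character(0),
                   winding = integer(0))
for (k in seq_len(nrow(ref))) {
  if (ref$ccda_phi[k] > 0)
    prog <- rbind(prog, data.frame(residue_id = region[k], angle = "phi",
                                   winding = ref$ccda_phi[k] / 360))
  if (ref$ccda_psi[k] > 0)
    prog <- rbind(prog, data.frame(residue_id = region[k], angle = "psi",
                                   winding = ref$ccda_psi[k] / 360))
}
traj <- make_rotation_trajectory(topo, prog, n_frames = 160, noise_sd = 10,
                                 seed = 42)
tab <- ccda_table(traj, region = region)
write.table(tab, "results/ccda/recovered_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
ok <- sum(tab$ccda_phi == ref$ccda_phi) + sum(tab$ccda_psi == ref$ccda_psi)
cat("Generator round trip:", ok, "of 36 phi/psi entries recovered",
    "exactly from the noisy\nsynthetic trajectory;",
    length(classify_rotary(tab)$zero_rotary),
    "zero-rotary residues found, matching the reference.\n")
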