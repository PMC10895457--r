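#!/usr/bin/env Rscript
# D-NEMD response analysis: the branch-point schedule on the equilibrium
# metatrajectory, then the Kubo-Onsager subtraction over the paired
# perturbed/unperturbed runs, scored against the planted displacement.

library(allodyn)

demo <- "results/demo"
out <- "results/dnemd"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

topo <- read_structure(file.path(demo, "topology.pdb"))
ens <- read_ensemble(topo, file.path(demo, sprintf("coupled_r%d.pdb", 1:4)),
                     dt = 20)

bp <- extract_branch_points(ens, discard = 100, interval = 20)
write.table(bp, file.path(out, "branch_points.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Branch schedule (discard 100 ns, every 20 ns): %d points, %s per replica\n",
            nrow(bp), paste(unique(table(bp$replica)), collapse = "/")))

prs <- read_paired_runs(file.path(demo, "pairs.yaml"), topo)
rp <- compute_response(prs, superpose_first = FALSE)
write_response_tsv(rp, file.path(out, "response.tsv"))

truth <- jsonlite::read_json(file.path(demo, "ground_truth.json"),
                             simplifyVector = TRUE)
target <- truth$dnemd_target
snap <- response_snapshot(rp, max(rp$times), structure = topo)
write_structure(topo, file.path(out, sprintf("response_t%g.pdb", snap$time)),
                bfactor = attr(snap$structure, "bfactor"))

cat(sprintf("Response at t = %g ns: residue %d deviates %.3f A (planted %.1f A);\n",
            snap$time, target, snap$values[target],
            truth$dnemd_displacement_A))
cat(sprintf("largest off-target deviation %.4f A across %d pairs.\n",
            max(snap$values[-target]), rp$npairs))
cat("Shared branch-point noise cancels in the subtraction, isolating the\n")
cat("perturbation: only the displaced residue carries signal.\n")
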