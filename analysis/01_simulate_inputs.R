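#!/usr/bin/env Rscript
# Build the synthetic study bundle every later step consumes: a coding
# sequence for a GH13_36-like enzyme with an atypical (QPDLN) CSR V, a
# CSR reference panel, a Michaelis-Menten velocity table on the doubling
# substrate grid, temperature/NaCl activity profiles, and a small
# nucleotide alignment for the phylogeny step.

suppressPackageStartupMessages(library(amyprofiler))

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 2026

## enzyme: 23-aa signal peptide + 520-aa catalytic chain
g <- gen_gh13_sequence("gh13_36_atypical", seed = seed)
signal <- "MKKTLLAGAILSLFALSACSNDA"
precursor <- paste0(signal, g$record$residues)

# back-translate with one fixed codon per residue, append a stop
codon_of <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              E = "GAA", Q = "CAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
gene <- paste0(paste(codon_of[strsplit(precursor, "")[[1]]],
                     collapse = ""), "TAA")
write_fasta(seq_record("syn_amy_gene", gene, "nucleotide",
                       description = "synthetic GH13 amylase gene"),
            file.path(out, "gene.fasta"))
write_fasta(seq_record("syn_amy_precursor", precursor, "protein",
                       description = "synthetic precursor (23-aa signal)"),
            file.path(out, "precursor.fasta"))

## CSR reference panel (same background seed, one exemplar per subfamily)
panel <- default_csr_panel(seed = seed)
write_csr_panel(panel, file.path(out, "panel.fasta"),
                file.path(out, "panel.tsv"))

## kinetics: noiseless + 5%-noise velocity tables, study design
for (noise in c(0, 0.05)) {
  d <- gen_mm_data(km = 2.53, vmax = 0.125,
                   substrate = c(1.25, 2.5, 5, 10, 20),
                   noise_sd = noise, seed = seed)
  utils::write.csv(data.frame(substrate = d$substrate,
                              velocity = d$velocity),
                   file.path(out, sprintf("velocities_noise%02.0f.csv",
                                          noise * 100)),
                   row.names = FALSE)
}

## activity profiles: temperature (optimum 25 C, 53.2% at 0 C) and NaCl
## activation (127.5% of the no-salt control at 1 M)
temp <- gen_activity_profile(optimum = 25, reference_condition = 0,
                             reference_relative_pct = 53.2,
                             grid = seq(0, 60, 5), noise_sd = 0)
utils::write.csv(data.frame(temperature_c = temp$condition,
                            activity = temp$raw),
                 file.path(out, "temperature_profile.csv"),
                 row.names = FALSE)
utils::write.csv(data.frame(nacl_m = c(0, 1, 2, 3, 4, 5),
                            activity = c(40, 51, 48.8, 46, 42, 35.08)),
                 file.path(out, "nacl_profile.csv"), row.names = FALSE)

## small 16S-like nucleotide alignment: a ladder of divergence from one
## reference sequence
set.seed(seed)
bases <- c("A", "C", "G", "T")
ref <- sample(bases, 300, replace = TRUE)
aln <- list(M175 = paste(ref, collapse = ""))
for (i in 1:5) {
  x <- ref
  idx <- sample(length(x), 15 * i)
  x[idx] <- sample(bases, length(idx), replace = TRUE)
  aln[[paste0("rel", i)]] <- paste(x, collapse = "")
}
write_fasta(mapply(function(id, s) seq_record(id, s, "nucleotide"),
                   names(aln), aln, SIMPLIFY = FALSE),
            file.path(out, "rrna_alignment.fasta"))

cat("simulated bundle written to", out, "\n")
cat(sprintf("  gene %d bp -> precursor %d aa (planted subfamily: %s)\n",
            nchar(gene), nchar(precursor), "gh13_36_atypical"))
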