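#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system.
#
# Two demes ("ES", a small western population; "IQ", a large south-west
# Asian one) that split recently from a much smaller ancestral population
# and still exchange rare migrants -- the divergence history inferred for
# the marbled teal -- plus a pair of relatives and ~10% missing calls so
# the kinship and filtering stages have something to do.  Outputs: VCF +
# popmap + mtDNA FASTA under results/data/.

library(tealdemog)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 20240101

model <- demographic_model(c(ES = 16388, IQ = 48654), T_div = 407,
                           migration = 8.71e-7, anc_sizes = 3225)
cfg <- sim_config(n_loci = 32000, locus_length = 300, missing_rate = 0.1,
                  samples = c(ES = 24, IQ = 12), seed = seed)
ped <- pedigree_spec(data.frame(id = c("ES_sib1", "ES_sib2"),
                                parent1 = "ES_01", parent2 = "ES_02"))

G <- simulate_dataset(model, cfg, pedigree = ped)
cat("simulated", nrow(G$calls), "individuals x", ncol(G$calls),
    "SNPs across", length(unique(G$locus_ids)), "RAD loci\n")

write_vcf(G, "results/data/synthetic_snps.vcf")
write_popmap(G$pops, "results/data/synthetic_popmap.tsv",
             groups = c(ES = "west_mediterranean", IQ = "sw_asia"))

aln <- simulate_mtdna(model, cfg, seq_length = 169, seed = seed + 1)
write_fasta(aln, "results/data/synthetic_mtdna.fasta")
write_popmap(setNames(aln$pops, aln$ids),
             "results/data/synthetic_mtdna_popmap.tsv",
             groups = c(ES = "west_mediterranean", IQ = "sw_asia"))
cat("simulated", length(aln$sequences), "mtDNA sequences of",
    aln$length, "bp\n")
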