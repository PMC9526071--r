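# wolbscan

Endosymbiont infection surveys from host resequencing by-catch.

Reduced-representation sequencing (e.g. genotyping-by-sequencing, GBS) of
insect hosts incidentally captures reads from maternally inherited
endosymbionts such as *Wolbachia*. wolbscan turns per-read alignment
summaries of those by-catch reads into population-level results, for
researchers mining existing population-genomic data sets for infection
dynamics:

1. **Infection detection** — an individual is called infected when at least
   *r* reads of length ≥ *L* bp pass quality filters (SAM flag mask 2432,
   MAPQ > 20). Defaults *r* = 5, *L* = 80 bp; `threshold_sweep()`
   recalibrates (accuracy, FNR, FPR) against PCR gold-standard labels over a
   log-spaced threshold grid.
2. **Haploid haplotype calling** — per-site allele calls by depth majority
   under a haploid model (ties → missing), site filter at ≤ 25% missingness
   among infected individuals, then complete-case individuals; export to
   haploid VCF, NEXUS and FASTA.
3. **Strain grouping** — haplotypes are joined when their Hamming distance
   is within the 95% statistical-parsimony connection limit. The parsimony
   probability after *j* of *m* sites differ is the recursion
   *P(j) = P(j−1) · s(j/m)* with *s(q) = μ(q) e^(−μ(q)) / q* and
   *μ(q) = −¾ log(1 − 4q/3)* (Jukes–Cantor single-hit probability given a
   visible difference); the limit is the largest *j* with *P(j) ≥ 0.95* —
   5 steps for 115 variant sites. Connected components are strains, labeled
   by decreasing abundance, with components under 11 individuals flagged
   rare.
4. **Ordination and divergence** — classical PCoA of p-distances and
   within/between-strain percent-divergence tables.
5. **Prevalence summaries** — per-locality and per-lineage infection rates
   and strain tallies, including a packaged 107-locality *Lycaeides* survey
   table.
6. **Synthetic data** — a seeded generator emulating the whole survey
   (divergent strain founders, star-like haplotype clouds, read-count
   mixtures, imperfect PCR labels), so the full pipeline runs and is tested
   without raw sequencing data.

## Worked example

```r
library(wolbscan)

## packaged survey table
t1 <- load_locality_table()
st <- locality_stats(t1)
# 105/107 localities infected; mean rate 91%; 2117/2377 individuals
strain_tallies(t1)[1:3, ]
#   strain n_individuals n_haplotypes major
# 1      A           999           19  TRUE
# 2      C           172            3  TRUE
# 3      B           102           44  TRUE

## synthetic survey end to end
cfg <- simulation_config(n_localities = 20, individuals_per_locality = 20,
                         prevalence_per_locality = 0.9, seed = 42)
ds <- simulate_dataset(cfg)
calls <- classify_infection(ds$reads)          # 356 of 400 called infected
confusion_vs_gold(calls, ds$gold)
# confusion vs gold (n = 128): accuracy 0.961, FNR 0, FPR 0.278

mat <- call_haploid(ds$depths)
mat <- filter_sites(mat, 0.25, among = calls$individual_id[calls$infected])
mat <- filter_complete_individuals(mat)        # 217 individuals x 115 sites

uh <- unique_haplotypes(mat)
labels <- paste0("H", seq_len(nrow(uh$unique)))
d <- hamming_matrix(setNames(uh$unique$haplotype, labels))
parsimony_connection_limit(d$n_sites, 0.95)    # 5 steps
net <- build_network(d, multiplicities = setNames(uh$unique$count, labels))
asg <- assign_strains(net, data.frame(
  individual_id = names(uh$by_individual),
  haplotype = labels[match(uh$by_individual, uh$unique$haplotype)]))
asg$strains
#   strain component n_haplotypes n_individuals major
# 1      A         1            5            79  TRUE
# 2      B         2            7            72  TRUE
# 3      C         3            2            66  TRUE
divergence_table(d, asg)
# A   2.1 (0.8)
# B  37.8 (1.3)   2.7 (1.0)
# C  33.0 (1.0)  14.0 (1.2)  1.7 (0.0)
```

The confusion statistics above are against *simulated, imperfect* PCR labels
(sensitivity 0.96, specificity 0.98 by default): the FPR of 0.278 reflects
PCR-negative but truly infected individuals, not detection errors. The three
recovered strains match the planted founders; within-strain divergence
(1.7–2.7%) sits far below between-strain divergence (14–38%).

`run_pipeline(list(seed = 1, out_dir = "out"))` chains all stages and writes
CSV/VCF/NEXUS artifacts plus an md5 manifest; identical seeds give identical
checksums. A thin command-line wrapper with `all`, `detect`, `calibrate` and
`summarize-table` subcommands is installed at
`system.file("scripts", "wolbscan.R", package = "wolbscan")`.

## References

* Templeton AR, Crandall KA, Sing CF (1992). A cladistic analysis of
  phenotypic associations with haplotypes inferred from restriction
  endonuclease mapping and DNA sequence data. III. Cladogram estimation.
  *Genetics* 132:619–633.
* Gower JC (1966). Some distance properties of latent root and vector
  methods used in multivariate analysis. *Biometrika* 53:325–338.
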