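# daasel

Deterministic multi-allele viability selection and overdominance models for
studying how balancing selection maintains allelic diversity — the question
posed most sharply by the extreme polymorphism of Major Histocompatibility
Complex (MHC) loci.  The package is for population geneticists and
immunogeneticists who want to compare overdominance mechanisms within one
computational framework: classical *asymmetric overdominance* (AO), where a
heterozygote's fitness is determined by its alleles' intrinsic merits alone,
against *divergent allele advantage* (DAA), where it is determined by how
complementary the two alleles' pathogen-recognition repertoires are.

## The model

A single autosomal locus with alleles $A_1,\dots,A_k$ evolves in an
effectively infinite, randomly mating population with discrete generations:

$$p_i(t+1) = p_i(t)\,\frac{(Fp)_i}{p^\top F p},$$

with $F=(f_{ij})$ the symmetric genotype fitness matrix and
$w_i = f_{ii} \in [0,1]$ the *intrinsic merit* of allele $A_i$ (its
homozygote's fitness).  Equilibria are computed by solving
$Fx = \mathbf 1$, eliminating alleles with nonpositive entries and
re-solving until all entries are positive, then normalizing; a time-step
iterator validates every equilibrium independently.  Fitness models:

| model | heterozygote fitness $f_{ij}$ |
|---|---|
| symmetric overdominance | $1$ |
| AO | $w_i + w_j - w_i w_j$ |
| DAA | fraction of the $l_S$ epitope sets recognized by the **union** of the two alleles' binary recognition patterns |

In the AO model all $k$ alleles persist iff every merit exceeds
$t = \frac{k-1}{k}\hat w$ ($\hat w$ = harmonic mean of merits), so
persisting merits must crowd together as $k$ grows.  In the DAA model two
alleles of modest merit but complementary patterns can form a highly fit
heterozygote, so alleles far below that threshold can persist — the package's
simulation layer quantifies this with paired AO/DAA sweeps over 80 scenarios
and equilibrium metrics (allele count, merit range, overdominance
$\bar h$, recognition overlap $\bar g$).

## A worked example

Three alleles with merits 0.8, 0.7 and 0.1.  Under AO the weakest allele
sits below the stability threshold and is lost; with a complementary
recognition layout the DAA model keeps all three:

```r
library(daasel)

ao_threshold(c(0.8, 0.7, 0.1))
#> AO stability threshold: t = 0.157746 (harmonic mean 0.23662 , k = 3 )
#> Not all merits exceed t: the full k-allele polymorphism is NOT stable.

pats <- rbind(A1 = c(0,1,1,1,1,1,1,1,1,0),
              A2 = c(1,1,1,1,1,1,1,0,0,0),
              A3 = c(0,0,0,0,0,0,0,0,0,1)) > 0
f <- fitness_daa(allele_set(patterns = pats))
f
#> Genotype fitness matrix (daa model, k = 3)
#>     A1  A2  A3
#> A1 0.8 0.9 0.9
#> A2 0.9 0.7 0.8
#> A3 0.9 0.8 0.1

solve_equilibrium(f)
#> Allele equilibrium (linear_solve, status: stable)
#> 3 of 3 allele(s) persist; population fitness 0.834783
#>  allele proportion
#>      A1     0.6522
#>      A2     0.3043
#>      A3     0.0435
```

The DAA heterozygote fitnesses (0.9, 0.9, 0.8) sit closer together than the
AO values for the same merits (0.94, 0.82, 0.73), which is what stabilizes
the three-allele polymorphism: even the merit-0.1 allele is retained at
4.3% because it recognizes the one epitope set the others miss.

A scaled-down paired sweep over all 80 study scenarios:

```r
rec <- run_experiment("random", scale = 0.01, min_repeats = 20, base_seed = 1)
pooled_summary(aggregate_records(rec))$random$scenario_mean_range_daa_wider
#> [1] 54.9125   # percent of repeats where the DAA merit range is wider
```

## Command line

A thin executable wraps the same functions:

```sh
daasel equilibrium --matrix F.csv
daasel simulate --experiment fixed --scenario 62 --scale 0.01 --seed 1 --out run/
daasel daa-score --patterns alleles.csv
daasel make-alleles --scenario 62 --experiment fixed --seed 1 --out alleles.csv
```

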