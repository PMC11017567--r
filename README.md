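# tindex

Most sex differences in cancer biology are not dichotomous. Male and female
tumor transcriptomes overlap broadly and vary between female- and male-skewed
extremes, which makes strictly sex-specific treatment stratification
unrealistic. `tindex` computes a **Transcriptomic Index (TI)** that places
each tumor sample on a continuous female-to-male axis: the Bayesian posterior
probability that the sample is male, given the recorded sexes of its nearest
transcriptome neighbors. TI near 0 marks a female-enriched neighborhood of
expression space, TI near 1 a male-enriched one, and the midrange is where
male and female phenotypes coexist. The package is aimed at cancer
transcriptomics analysts who want to quantify sex-skewed expression programs
(cell cycle, inflammation/immunity, oxidative phosphorylation, ...) per
patient rather than per category.

## The model

For a target sample x<sub>&tau;</sub>, order the training samples of the same
cancer type by Euclidean distance in expression space,
x<sub>0</sub>, ..., x<sub>&tau;-1</sub>, with x<sub>0</sub> farthest. The
binary sex labels (x = 1 male) along this sequence are modeled with a
changepoint partition: writing k<sub>i</sub> for the number of points sharing
the current partition before position i,

- p(k<sub>0</sub> = 0) = 1,
- p(k<sub>i</sub> = 0 | k<sub>i-1</sub>) = p<sub>&gamma;</sub> (a breakpoint
  starts a new partition),
- p(k<sub>i</sub> = k<sub>i-1</sub> + 1 | k<sub>i-1</sub>) = 1 -
  p<sub>&gamma;</sub>,

and within a partition the labels are i.i.d. Bernoulli(&theta;) with
&theta; ~ Beta(&alpha;, &beta;), so the predictive probability that the next
label is male given m males among k block members is
(&alpha; + m) / (&alpha; + &beta; + k). A forward recursion over the joint
p(k<sub>i</sub>, x<sub>0..i</sub>) (renormalized each step, with the log
constant carried) yields the exact posterior

TI = p(x<sub>&tau;</sub> = 1 | x<sub>0</sub>, ..., x<sub>&tau;-1</sub>)
= &Sigma;<sub>k</sub> p(k<sub>&tau;</sub> = k | data) &middot;
(&alpha; + m<sub>k</sub>) / (&alpha; + &beta; + k),

marginalizing the prediction over the partition of nearest neighbors.
Defaults are &alpha; = &beta; = 10 and p<sub>&gamma;</sub> = 0.05. A
`balanced` weighting mode replaces label counts with weights
N/(2N<sub>m</sub>) and N/(2N<sub>f</sub>) so both sexes contribute equal
total evidence in imbalanced cohorts. The exactness of the recursion is
verified against brute-force enumeration over all 2<sup>&tau;</sup>
breakpoint configurations (`bnn_posterior_bruteforce()`).

Downstream, per-gene OLS of expression on TI calls male-skewed
(positive slope) and female-skewed genes at Benjamini–Hochberg FDR < 0.05;
skewed lists are tested for gene-set over-representation with one-sided
Fisher exact tests against GMT collections; and midrange samples
(0.25 &le; TI &le; 0.75) are contrasted with their own sex's pole gene by
gene (Welch t).

## Worked example

```r
library(tindex)

sim <- simulate_cohort(cohort_spec(n_samples = 100, n_genes = 500,
                                   module_size_male = 50,
                                   module_size_female = 50), seed = 7)
ti <- compute_ti(sim$expression, sim$annotations)
head(ti, 3)
#>   sample cancer_type    sex    ti support
#> 1  S0001       SYNTH   male 0.687    28.2
#> 2  S0002       SYNTH female 0.309    30.8
#> 3  S0003       SYNTH   male 0.520    18.9
```

`ti` is the posterior male probability of each sample given its neighborhood;
`support` is E[k<sub>&tau;</sub> | data], how many nearest neighbors
effectively back that posterior. Sample S0001 sits in a male-enriched
neighborhood (TI 0.69 backed by ~28 neighbors), S0003 in a mixed one.

```r
summarize_cohorts(ti)
#>   cancer_type n_male n_female irr median_ti   q05   q25   q75   q95
#> 1       SYNTH     50       50   1     0.475 0.302 0.378 0.659 0.727

rec <- associate_genes(sim$expression, setNames(ti$ti, ti$sample))
table(rec$skew)
#> female   male   none
#>     53     52    395

poles <- classify_poles(rec)
sets  <- register_genesets(sim$truth, seed = 7)
fisher_enrichment(poles$male, rec$gene, sets)[1:3, ]
#>             set query_size set_size overlap        p        q
#> 1   male_module         52       50      50 5.73e-67 5.73e-66
#> 2 female_module         52       50       0 1.00e+00 1.00e+00
#> 3      decoy_01         52       50       0 1.00e+00 1.00e+00
```

The 52 genes called male-skewed recover the 50-gene planted male module
exactly (overlap 50, q = 5.7e-66) and nothing else; Spearman correlation
between TI and the generator's latent sex continuum is 0.98 in this cohort.

The same pipeline runs from the shell on TSV/GMT files:

```sh
Rscript inst/cli/tindex.R simulate --out run --seed 7 --n 100 --genes 500 --module-size 50
Rscript inst/cli/tindex.R ti        --expr run/expression.tsv --ann run/annotations.tsv --out run
Rscript inst/cli/tindex.R associate --expr run/expression.tsv --ti run/ti.tsv --out run
Rscript inst/cli/tindex.R enrich    --gmt run/modules.gmt --associations run/associations.tsv --out run
Rscript inst/cli/tindex.R report    --ti run/ti.tsv --out run
```

## Scope notes

Sex labels are strictly binary (male/female), mirroring the classifications
available in current clinical data — a documented limitation, not an
endorsement. The generator produces Gaussian expression on a latent
continuum; it does not emulate RNA-seq count noise, batch effects, or
copy-number structure. UMAP visualization, survival analysis, and
ranked-list (GSEA-style) enrichment are out of scope.
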