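# sshray — quantitative screening of SSH cDNA libraries on two-colour microarrays

Suppression subtractive hybridization (SSH) is a PCR-based subtraction
method that enriches cDNA clones for transcripts differing between a
treated ("tester") and a control ("driver") sample. It is a workhorse for
gene discovery in organisms without an annotated genome, but the resulting
libraries contain subtraction escapes (false positives) and heavy
redundancy, so sequencing every clone is wasteful. `sshray` screens an SSH
library that has been spotted on a small number of two-colour microarrays
and hybridized with the subtracted and unsubtracted cDNA samples, ranking
every clone by the statistical evidence that it is worth sequencing. It
also manages the clone sequences afterwards: vector trimming, grouping of
redundant clones, and annotated exports.

## The model

Four cDNA samples are hybridized in pairs: **UT** (unsubtracted treated),
**UC** (unsubtracted control), **ST** (subtracted treated = forward-library
material) and **SC** (subtracted control = reverse-library material). Each
clone is characterised by two log2 enrichment ratios:

* **ER3** = log2(UT/UC) for forward-library clones, log2(UC/UT) for
  reverse-library clones — differential expression under the treatment;
* **inverse ER2** = log2(UT/ST) (forward) or log2(UC/SC) (reverse) —
  negative values mean the transcript was *rare* before subtraction and
  was enriched by the SSH normalization step.

Because an SSH array is enriched for changed genes by construction, the
usual "most genes are unchanged" loess normalization is invalid. Instead,
four alien control probes (gfp, globin, nptII, its) are spotted as two-fold
dilution series and hybridized against a spike-in mix added in equal
amounts to both channels; a robust loess curve of M on A is fitted per
print-tip group **through the control spots only** (full weight to
controls, zero to library clones) and subtracted from every spot.
Background correction uses the normexp convolution model (x = B + S,
B ~ N(mu, sigma^2), S ~ Exp(alpha)) with an offset of 50; A-values are
Aquantile-normalized between arrays.

For each clone, dye-swap replicate arrays are combined by weighted least
squares into a single log2-ratio estimate per contrast, and variances are
moderated across clones with the empirical-Bayes machinery: the posterior
variance is s2_post = (d0 s0^2 + d s2)/(d0 + d), the moderated t has
d0 + d degrees of freedom, p-values are Benjamini–Hochberg adjusted, and
the B-statistic reports the log posterior odds of differential expression
(prior probability 0.5 by default — half of a subtracted library is
expected to be truly changed). Clones are classified into quadrants
(Up/Down x Rare/Abundant) from the signs of ER3 and inverse ER2.

Redundant clone sequences are grouped by local alignment (match +1,
mismatch −2, affine gaps 5/2) with Karlin–Altschul E-values
E = K·m·n·exp(−lambda·S); pairs with E < 1e-10 are linked and groups are
the connected components, represented by their longest member.

## Worked example

Everything is testable hermetically through the synthetic-experiment
generator, which writes a complete GPR/GAL/Targets/SpotTypes/FASTA bundle
with known truth:

```r
library(sshray)
cfg <- sim_config(n_forward = 300, n_reverse = 300, blocks = 8, cols = 12,
                  seed = 7)
bundle <- generate_experiment(cfg, dir = "demo")
fit <- ssh_screen(bundle$targets, bundle$spot_types, bundle$gal,
                  gpr_dir = bundle$dir)
summary(fit)
```

```
forward library: 300 clones, 291 classified

      Up.Rare   Up.Abundant     Down.Rare Down.Abundant
          110            12            25           144
  % significant: 7.2  % positive B: 16.5  % negative invER2: 87.4
reverse library: 300 clones, 293 classified

      Up.Rare   Up.Abundant     Down.Rare Down.Abundant
           13           105           156            19
  % significant: 9.9  % positive B: 15.4  % negative invER2: 88.9
```

About 7–10% of clones are significantly differentially expressed (the
generator plants 10% true changes) and ~88% carry negative inverse ER2
(the generator plants 90% rare transcripts, the situation SSH is designed
to produce). The ranked top table uses the standard eight-column layout:

```r
head(top_table(fit, "forward"), 3)
```

```
      ID logFC(ER3) AveExpr    t  P.Value adj.P.Val   B    invER2 quadrant
1 0108-F       2.60    13.1 21.1 1.41e-98  4.11e-96 209 -0.000255  Up.Rare
2 0151-F       2.58    12.0 20.9 5.74e-97  8.35e-95 206 -0.736649  Up.Rare
3 0087-F       2.23    11.0 18.0 9.76e-73  9.47e-71 153 -1.176145  Up.Rare
```

The top clone's logFC(ER3) of 2.60 means `fold_change(2.60)` ≈ 6.1-fold
up-regulation; its negative invER2 says the transcript was rare before
subtraction. `plot(fit, "forward")` draws the ER3 vs inverse ER2 plot with
the most significant clones highlighted; `er_plot(..., groups = ...)`
colour-codes redundant-partner groups, which cluster together on that
plane. Sequence management:

```r
trimmed <- trim_vector(Biostrings::readDNAStringSet(bundle$fasta))
groups  <- group_redundant(trimmed)
merge_annotations_export(groups, fit$top_tables, dir = "demo/out",
                         gal = fit$design$gal)
```

A thin command-line wrapper is installed at
`inst/scripts/sshray` (`sshray simulate|screen|group|export`), driven by
`run_config()` / a YAML configuration file.

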