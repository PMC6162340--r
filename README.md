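# shmstop

Premature stop-codon risk from somatic hypermutation in germinal-center
B cells.

Somatic hypermutation (SHM) deposits ~10⁻³ point mutations per nucleotide
per division into immunoglobulin V genes while B cells proliferate in the
germinal-center dark zone (DZ). Because mutation is blind to consequence,
a predictable fraction of cells destroys its own receptor with a premature
stop codon (TAA/TAG/TGA) or a frameshifting deletion. `shmstop` is for
immunologists and modellers who want to (a) predict that fraction from
first principles, (b) validate the prediction by stochastic simulation,
(c) call premature stops in Sanger or NGS amplicon reads against a V-gene
template, and (d) turn per-gate calls from index-sorted, deliberately
enrichment-sorted subpopulations into unbiased population frequencies.

## The model in brief

For a template of length *L* with region enrichment weights *wᵢ* (CDR ×5,
AID hotspot motifs RGYW/WRCY ×2, motif-in-CDR ×10), the probability that a
single random point mutation creates a stop is

    q = Σᵢ wᵢ·cᵢ/3 / Σᵢ wᵢ

with *cᵢ* the number of the three substitutions at position *i* yielding a
stop (per-codon enumeration: at-risk codons 1/9, doubly at-risk 2/9). The
per-division chain is then

    p_m     = L·μ                                (0.393 for 393 nt, μ = 10⁻³)
    p_point = q·p_m                              (0.025)
    p_del   = 1 − mean[(1 − delfracᵢ)^(p_m/loadᵢ)]   (0.006)
    p_fs    = (2/3)·p_del                        (0.004)
    p_stop  = p_point + p_fs                     (0.029)

and the expected stop-codon frequency of a snapshot DZ cohort completing at
most *D* divisions (2ᵏ-weighted: 14%/29%/57% for D = 2) is

    E = Σₖ P(k)·(1 − (1 − p_stop)ᵏ)              (4.1% for D = 2)

An alignment-based pipeline (needle-style global alignment, frame-aware
translation, strict (100/n)% read-abundance filter) measures the same
quantity in reads, and a gating-tree rollup

    f(node) = Σ_children f(child)·fraction_of_parent(child)

corrects for deliberate oversampling of rare gates during FACS sorting
using pre-enrichment gate fractions.

## Worked example

```r
library(shmstop)

# analytic expectation for the canonical 393-nt gene
run_expectation_workflow(q = 0.064)
#> q = 0.0640 | p_m = 0.393 -> p_point = 0.025 | retain = 0.994 -> p_del = 0.006 -> p_fs = 0.004
#> p_stop = 0.029 -> expected DZ stop frequency = 4.1% (printed mode; 4.12% full precision)

# synthetic index-sorted germinal center: DZ truth 4.6%, LZ truth 1.3%,
# BCR-low gates enriched 10x during sorting, 500 cells sequenced per zone
sc  <- generate_scenario("wildtype", seed = 101, total_cells = 8000, seq_budget = 500)
res <- run_analysis_workflow(sc, ngs = FALSE)
res$estimates
#>  node rollup_percent    ci_low  ci_high pooled_percent n_sequenced truth_percent
#>    DZ       4.051049 2.3435951 7.644883            9.4         500           4.6
#>    LZ       1.073738 0.4230734 3.709807            2.6         500           1.3
```

The enrichment-corrected rollup lands on the configured zone truths (the
Wilson intervals cover 4.6% and 1.3%), while naive pooling — dominated by
the 10×-oversampled high-frequency BCR-low gates — overshoots the DZ value
more than twofold. The numbered scripts under `analysis/` run these studies
at full size and write their tables to `results/`:

* `01_expectation.R` — the analytic chain and its division sensitivity,
* `02_simulator_check.R` — 20,000-cell simulator vs. closed form,
* `03_synthetic_recovery.R` — ten-seed end-to-end recovery,
* `04_ngs_threshold.R` — abundance-filter behaviour on bulk NGS samples.

See `vignettes/stop-codon-risk.Rmd` for the model assumptions, rounding
modes, generator calibrations and known limitations.

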