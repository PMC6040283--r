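# amyprofiler

In silico characterization of GH13 alpha-amylases, for enzymologists and
sequence analysts triaging novel candidates — in particular cold-adapted,
salt-tolerant amylases cloned from environmental bacteria. From a gene or
protein sequence, the package answers the questions such a study asks
before (or instead of) the wet lab:

* **What is the enzyme?** ORF location, standard-code translation,
  signal-peptide trimming (cleavage site supplied as an annotation),
  molecular weight, and the isoelectric point from Henderson–Hasselbalch
  net charge — pI is the pH where
  `Σ pos 1/(1+10^(pH−pKa)) − Σ neg 1/(1+10^(pKa−pH)) = 0`,
  solved by bisection under a pinned Bjellqvist (ProtParam) pKa table.
* **Which GH13 subfamily?** The seven conserved sequence regions
  (CSR I–VII) are transferred from an annotated reference panel through
  an anchored global alignment (BLOSUM62, affine gaps), and the motif
  rules applied: CSR V pentapeptide QPDLN → oligo-1,6-glucosidase,
  MPKLN → neopullulanase, MPDLN → GH13_36; invariant CSR VI Trp and a
  Tyr before the CSR VII-terminal "GEE" are GH13_36 core supports, a
  CSR II terminal His and a CSR III aromatic auxiliary ones. A
  non-GH13_36 pentapeptide with both core supports yields the
  `gh13_36_like_atypical_csr5` call — the QPDLN-bearing GH13_36
  configuration. Every call carries its evidence trail.
* **Is it cold-adapted / halotolerant?** Arg% and Arg/(Arg+Lys) (low in
  flexible cold-active enzymes) and the acidic excess
  (Asp+Glu)% − (Arg+Lys)% (high in salt-tolerant enzymes), with shipped
  panels of published reference values for context.
* **Where does it sit phylogenetically?** From-scratch Saitou–Nei
  neighbor joining on p- or Poisson-corrected distances, with seeded
  column-resampling bootstrap supports and Newick output.
* **How does it behave?** Michaelis–Menten kinetics via the
  Lineweaver–Burk regression (`1/v = (Km/Vmax)(1/s) + 1/Vmax`), with a
  nonlinear cross-check; relative-activity and residual-stability
  normalization and optimum detection for temperature/pH/NaCl profiles.

A synthetic-data module generates GH13-like sequences with planted CSRs,
composition-controlled sequences, noisy kinetic datasets and anchored
activity profiles, so the full pipeline runs and is tested without any
network access.

## Worked example

The `analysis/` scripts run the whole study on a simulated enzyme:

```sh
Rscript analysis/01_simulate_inputs.R        # synthetic gene, panel, assays
Rscript analysis/02_sequence_features.R
Rscript analysis/03_subfamily_classification.R
Rscript analysis/04_phylogeny.R
Rscript analysis/05_kinetics_profiles.R
Rscript analysis/06_full_report.R            # single JSON/text report
```

`03_subfamily_classification.R` prints (abridged):

```
best reference: panel_gh13_36_atypical (alignment score 2715.0)
 label query_start query_end   peptide identity_pct
     V         286       290     QPDLN          100
    VI         338       342     GWSTR          100
   VII         390       398 GVPLIYGEE          100
CSR V pentapeptide: QPDLN | CSR VI Trp: TRUE | CSR VII Tyr-GEE: TRUE
CSR II terminal His: FALSE | CSR III aromatic: FALSE | triad: D134, E182, D239
subfamily call: gh13_36_like_atypical_csr5
```

— the planted configuration: a QPDLN pentapeptide (nominally
oligo-1,6-glucosidase) overridden to a GH13_36-like call by the two core
supports, with the catalytic D/E/D triad located on the mature chain.
`05_kinetics_profiles.R` prints:

```
velocities_noise00.csv: LB Km 2.53 mg/mL, Vmax 0.125 mg/mL/min (R2 1.0000); NLS Km 2.53
temperature optimum: 25 C (53.2% retained at 0 C)
NaCl optimum: 1 M (127.5% of the no-salt control)
```

i.e. the Lineweaver–Burk fit returns the generating Km/Vmax exactly on
noiseless data, the temperature profile peaks at 25 °C while retaining
53.2% activity at 0 °C (a cold-active signature), and activity at 1 M
NaCl exceeds the no-salt control by 27.5% (salt activation).

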