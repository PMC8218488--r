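---
title: "Ranking submolecular moieties by binding destabilization: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking submolecular moieties by binding destabilization: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lead optimization asks which part of a candidate molecule should be changed to
bind its target more tightly. Given an MD trajectory of the bound complex,
`moietyrank` ranks *atom subtypes* — groups of ligand atoms with similar
Lennard-Jones parameters, the submolecular unit of analysis — by how much their
contact dynamics deviate below the stability of the whole molecule. Subtypes
that fragment into many short-lived contact states while the molecule as a
whole sits in one persistent binding mode are flagged as *malicious*:
candidates for chemical modification. No structure–activity data are needed;
the inputs are a trajectory, atom selections, and a force-field parameter
table.

## The pipeline

1. **Contacts.** Each frame yields a binary N×M matrix: ligand atom i touches
   protein atom j iff their distance is ≤ the contact cutoff (closed
   comparison). The cutoff defaults to 4.5 Å over all atom pairs, hydrogens
   included — subtypes themselves contain hydrogens, so excluding them would
   blind the method to e.g. hydroxyl-hydrogen contacts. M defaults to every
   atom of the protein selection; restrict the selection to binding-site
   residues to sharpen the signal and cut cost.
2. **Subtypes.** CHARMM-style nonbonded tables give each atom type a well
   depth ε (stored as its magnitude) and a size parameter (R~min~/2, used
   directly: converting to σ rescales both sides of a relative comparison and
   cannot change any grouping). Two types are compatible when both parameters
   agree within 10% of the larger of the pair; subtypes are the connected
   components of that graph. Components make the relation a true partition —
   the pairwise 10% rule alone is not transitive — and IDs are assigned by
   ascending (min size, min ε, type name) so the table is independent of row
   order. Types with ε = 0 pair with each other (|0−0| passes any relative
   test) but never with ε > 0 types.
3. **Dynamism.** Each frame becomes a 2-channel tensor: the contact matrix at
   *t* and the absolute difference against frame *t−δ* (equal to XOR for
   binary data, hence direction-independent: a formed and a lost contact look
   the same). δ defaults to 500 frames = 10 ns at the 20 ps snapshot spacing.
   Frames with *t* ≤ δ compare against frame 1, so the series keeps length T
   and stays aligned with the reference series — dropping early frames would
   desynchronize the per-frame comparison metrics.
4. **Embedding.** A convolutional variational autoencoder per subtype: four
   valid convolutions (f filters, 1×7 kernels, stride 2 along the protein-atom
   axis, no padding or pooling — the 1-high kernel keeps the contact and
   change rows spatially separate), then affine heads for a d-dimensional
   Gaussian latent. The decoder mirrors the encoder with transposed
   convolutions whose output lengths are read off the encoder's shape trace
   (the per-layer "output padding" cells that valid stride-2 convolution never
   reads are reconstructed from the bias alone). Loss is summed binary
   cross-entropy plus KL against a standard normal; RMSprop at 0.005; at most
   600 epochs, stopping after 10 epochs without a strict decrease of the
   training loss. Six architectures per subtype — f ∈ {32, 64} × d ∈ {3, 5,
   10} — form an ensemble; metrics are averaged over members and their
   population standard deviation serves as an agreement score.
5. **Clustering.** HDBSCAN over the per-frame latent means (means, not
   samples, for determinism) with minimum cluster size 50 and all other
   settings at their defaults (`min_samples` equal to the minimum cluster
   size). Each frame's *cluster size* — the population of the cluster it
   belongs to — is the stability signal; noise frames count as singletons.
6. **Reference.** The whole-molecule yardstick defaults to quality-threshold
   RMSD clustering: frames are superposed on the protein (least-squares fit to
   frame 1), the pairwise ligand RMSD matrix is computed without refitting,
   and clusters are grown greedily from the frame with the most neighbors
   within 2.0 Å (lowest index on ties). A binding mode is *stable* when its
   largest cluster's total membership exceeds the persistence threshold
   (default 50 ns). Precomputed assignments (`frame,label` CSV) and an
   all-atom autoencoder reference are supported alternatives.
7. **Metrics and ranking.** For subtype series A versus reference series S:
   CosSim = ΣA~t~S~t~ / (‖A‖‖S‖) and AvgDiff = Σ(A~t~−S~t~)/T. Both are
   centered by their unweighted mean over the subtypes present in the ligand
   (not a global subtype inventory). Subtypes are ranked by the average of
   their two per-metric ranks, ties broken by subtype ID; rank 1 is the most
   malicious. The composite is one defensible combiner, not the only one, so
   both per-metric ranks are reported for users with their own rule. When the
   reference itself is not stable the malicious-atom reading is invalid; the
   ranking is still returned, with a prominent warning.

## Free-energy verification

Suggested modifications are verified by alchemical relative binding free
energies. Treating relative potency as a readout of the dissociation
constant, log~10~ CRS = −(ΔΔF − ΔΔF~ref~)/(RT ln 10) with R = 1.987×10⁻³
kcal/(mol·K), and a modification changing binding by ΔΔF kcal/mol multiplies
potency by exp(−ΔΔF/RT). Temperature is always explicit because the shipped
reference table is only self-consistent at 310 K while the verification fold
factors round as reported at 298.15 K; the two functions default accordingly
and either accepts any temperature.

## The synthetic generator

Real trajectories of proprietary complexes cannot ship with a package, so
every stage is exercised on synthetic systems with planted ground truth. A
system is a stack of subtype blocks over T frames and M pseudo-protein
columns:

* **stable** blocks hold one random fingerprint (density 0.3) with
  independent per-cell noise, default 5×10⁻⁴ per frame — about one spurious
  contact event per pair per 40 ns at 20 ps/frame. Aggregation across a
  block's atoms is a logical OR, which roughly doubles the effective noise;
  at this rate most frames still carry the exact clean fingerprint, as a
  stably hydrogen-bonded moiety should.
* **intermittent** blocks — the planted unstable behavior — run a two-state
  detach/attach process: no contacts while detached, a fresh random
  fingerprint per attachment episode, switching each frame with probability
  0.02 (mean 1 ns episodes). This is the contact signature of a moiety that
  repeatedly loses and regains transient interactions, and its embedding
  fragments into many small or sub-threshold clusters.
* **flicker** blocks flip each cell independently per frame. This behavior is
  kept for completeness but deliberately *not* used as the planted-unstable
  default: per-cell flipping is a continuous random walk, its latent
  trajectory is a connected filament, and the single-linkage backbone of
  HDBSCAN chains a filament into one cluster spanning the whole series —
  which scores as perfectly stable. The lesson generalizes to real data:
  the method detects instability that *revisits discrete states*, not slow
  continuous drift.
* **switching** blocks alternate two fingerprints on a fixed schedule and
  drive the whole-molecule regime labels, giving multi-mode references.

The toy trajectory writer emits a 12-atom rigid ligand beside a 120-atom
pseudo-helix as multi-model PDB text, with an optional two-pose mode (> 5 Å
apart in ligand RMSD) for exercising the reference clustering.

What passing these tests shows — and does not show. The generator emulates
binarized contact streams with planted temporal structure; it has no force
field, no solvent, no correlation between blocks, and its "protein" columns
are exchangeable. Recovery of the planted subtype demonstrates that the
featurization, embedding, clustering and metrics compose correctly, not that
the method's suggestions are chemically valid on any particular real complex.

## Numerical and design choices

* **Contact boundary.** Distance exactly at the cutoff counts as a contact
  (with a 10⁻⁹ guard), so exact fixtures are deterministic.
* **Subtype aggregation.** Logical OR, because the cross-entropy
  reconstruction loss requires binary inputs; summation would break that
  contract.
* **Autoencoder internals.** ReLU activations, standard reparameterized
  sampling, batch size 64, KL weight 1, Glorot-uniform initialization,
  log-variance clamped to ±10, probabilities clamped to [10⁻⁶, 1−10⁻⁶] in the
  cross-entropy; "improvement" for early stopping is any strict decrease of
  the epoch training loss (no validation split). Arithmetic is single
  precision; all randomness (initialization, shuffling, sampling noise) draws
  from R's RNG, so a seed reproduces a training run bit-for-bit at a fixed
  BLAS thread count. The minimum input length for the default four-layer
  stack is M ≥ 91.
* **Cluster extraction.** The HDBSCAN implementation allows the tree root to
  be returned as a cluster (`allow_single_cluster = TRUE` by default),
  diverging from implementations that always discard the root. A stably
  bound molecule is *expected* to produce a single dominant conformational
  state; with the root excluded, a perfectly stable series would come back
  100% noise and be indistinguishable from a maximally unstable one.
* **QT reference internals.** Alignment reference is frame 1; the greedy
  center tie-break is the lowest frame index; noise appears only when a
  cluster-count cap is set. Stability uses total membership time, not the
  longest contiguous run — "cluster size" is a population, not an interval.
* **Ranking normalization.** Per-subtype metrics are first averaged over the
  ensemble, then centered across subtypes; centering is linear, so the order
  of those two steps does not affect the means, but the reported agreement
  standard deviations are those of the raw per-model values.
* **Seeds.** The pipeline derives one seed per subtype (base + 1000·k) and
  one per ensemble member (subtype seed + member index), all below 2³¹.

## Problem sizes

The shipped study conditions are desk-scale by design: T = 1000 frames
(20 ns at 20 ps spacing), M = 128 protein atoms, five 2-atom subtype blocks,
a reduced ensemble f = 32, d ∈ {3, 5}, and an epoch cap of 60 — with the full
600-epoch cap, early stopping typically fires between 60 and 140 epochs and
pilot rankings were identical at caps 600, 80 and 60, so the cap trades a few
percent of final loss for a several-fold shorter study. The stability
threshold for these 20 ns runs is 10 ns — half the trajectory — since the
50 ns default presumes the 50–100 ns production runs it was stated for.
Recovery is assessed over 10 independently seeded replicates.

## Known limitations

* CosSim between cluster-size series is scale-invariant: against an exactly
  constant reference (a single cluster spanning every frame), *any* uniform
  subtype outcome — one big cluster or all singletons alike — scores 1.
  Discrimination there rests on the size *heterogeneity* of unstable
  subtypes (transient clusters straddling the minimum cluster size) and on
  AvgDiff, which is magnitude-aware. Real references are rarely exactly
  constant.
* Instability expressed as slow continuous drift embeds as a filament and is
  invisible to density clustering (see the flicker discussion above).
* The 46-subtype table of the full CHARMM36 + CGenFF inventory is not
  reproducible without those distributions; the package ships only toy
  parameter fixtures and parses user-supplied tables.
* Trajectory input is PDB/PSF topology with DCD or multi-model PDB
  coordinates; no periodic-boundary imaging is applied beyond what the
  coordinates already contain.
* Whether the original 10% subtype window was applied pairwise-transitively
  or against seed types is unknowable from the description; connected
  components is this package's documented choice.
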