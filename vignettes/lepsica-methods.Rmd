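---
title: "Source imaging and group ICA of laser-evoked potentials: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source imaging and group ICA of laser-evoked potentials: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lepsica)
```

# The analysis problem

A brief noxious laser pulse to the skin activates A-delta nociceptors and
evokes a stereotyped sequence of scalp potentials — the laser evoked
potential (LEP), with successive deflections (N1, N2, P2/N3, P3) between
roughly 150 and 400 ms. When the laser arrives while the subject views an
emotional picture, the perceived pain and the cortical response are
modulated by the picture's valence. `lepsica` implements the full analysis
chain for asking *where* and *when* that modulation acts:

1. **Preprocessing** of multichannel epochs into condition-wise averaged
   evoked potentials (common average reference, PCA eyeblink removal,
   epoch rejection, zero-phase band-pass, baseline correction).
2. A **three-shell spherical head model** and its lead field, mapping
   dipole moments (nA·m) at a regular voxel grid to average-referenced
   scalp potentials (µV).
3. The **LAURA distributed inverse** (local autoregressive average): a
   weighted-minimum-norm solution whose source-space metric couples each
   voxel to its lattice neighbors with distance-power weights, evaluated
   at every time point to give a series of source-magnitude volumes.
4. **Group spatial ICA** of the concatenated volume series (PCA
   reduction, Infomax, ICASSO stability selection), yielding shared
   spatial maps with per-subject, per-condition time courses.
5. **Pointwise repeated-measures statistics** on those time courses:
   one-way RM-ANOVA with Greenhouse–Geisser correction, max-statistic
   permutation control of the family-wise error over components × time,
   paired contrasts, polynomial trends, and RM-ANCOVA with pain, valence
   and arousal covariates.

Because no raw data from the original study are available, the package
ships a first-class synthetic-data generator with known ground truth, so
every stage is testable end to end.

# The forward model

The volume conductor is three concentric spheres (scalp/skull/brain,
default radii 88/85/81 mm, conductivities 0.33/0.0042/0.33 S/m — the
conventional ~80:1 skull contrast). The potential of a dipole inside the
innermost shell is computed from the Legendre-series solution: for each
harmonic degree the interface conditions give a transfer factor relative
to the infinite homogeneous medium, obtained from a 2×2 transfer-matrix
propagation in normalized radius (stable to high degree, unlike a direct
solve of the 5×5 boundary system). Two hundred terms are kept by
default; doubling them changes no gain entry by more than 1e-6 because
grid sources are bounded away from the brain-shell boundary. The
homogeneous-sphere limit was checked against an independently derived
closed form (the infinite-medium term plus the gradient of a logarithmic
image term obtained from the generating-function integral); agreement is
at the 1e-11 level. Electrode montages are quasi-uniform Fibonacci
lattices over the upper scalp; lead-field columns are average-referenced.

# The LAURA inverse

The local autoregressive operator `A` has, for every voxel, negative
weights proportional to `d^-3` toward its 26-neighborhood and a
compensating diagonal `(N_max/N_i) * sum d^-e` that keeps boundary voxels
(with fewer realized neighbors) comparably weighted. The source metric is
`W = A'A`, applied identically to the three orientation components, and
the inverse is

```
G = W^-1 L' (L W^-1 L' + lambda I)^+ ,   lambda = alpha * mean eig(L W^-1 L')
```

with `alpha = 3e-4` by default (the "0.03%" percent convention, scaled by
the mean gram eigenvalue; the scaling base is configurable because the
original software's convention is not documented). At `alpha = 0` the
operator reprojects noiseless data exactly. Magnitude (not signed
moment) volumes feed the ICA stage, matching activation-strength maps.

**Localization behavior.** Like every weighted-minimum-norm inverse,
LAURA's point-spread peak is typically displaced by up to one lattice
step: on a fixed 30-node panel of superficial and mid-depth voxels under
the sensor cap, all nodes localize within one 10-mm step and roughly half
exactly, and LAURA's mean peak error is substantially below the
unweighted minimum-norm comparator on the same grid. Exactly-zero peak
error *everywhere* is not a property this family of inverses has; the
package documents the attained profile (`localization_error_profile()`)
rather than claiming it.

# Group ICA and ICASSO

Subject × condition volume series are concatenated in time, each time
point is centered over voxels, and PCA over the time dimension retains
`n_pc` components (30 by default), whitened. Infomax ICA (natural
gradient, logistic nonlinearity, bias term, annealed learning rate,
random orthogonal initialization) estimates spatial maps that are unit
variance and sign-aligned (map peak positive). Per-subject, per-condition
time courses come from least-squares projection of each block onto the
group maps.

ICASSO repeats the estimation (15 runs by default), each from a fresh
random rotation *and on a bootstrap resample of the voxels*, pools the
maps, clusters them by average linkage on `1 - |spatial correlation|`,
and scores each cluster by within- minus between-cluster mean similarity.
A cluster represented in only one run scores 0 — it has not replicated.
The selected model order is the largest candidate in the contiguous run
of candidates whose clusters all reach the 0.8 stability floor. Two
design notes, found the hard way:

* Without random initialization and bootstrapping, every run converges to
  the same attractor of the same fixed dataset, and stability is high at
  *every* candidate order — the index cannot discriminate.
* "Maximize mean stability" systematically underestimates the order:
  merged components (order below truth) are deterministic and therefore
  maximally stable. One order *above* truth is also inherently stable,
  because a single extra noise dimension has no rotational freedom; hence
  order recovery to within ±1 is what the statistic can deliver, and that
  is what the tests assert.

On source-**magnitude** volumes, the number of genuinely stable
components exceeds the number of simulated dipoles: magnitudes are a
nonlinear function of moments, so residual pulse overlap and the fixed
background-activity realization form real, reproducible components. On
linear mixtures the selection recovers the true count within ±1; on the
end-to-end simulation it reports the (larger) number of stable magnitude
components. The acceptance suite records this honestly.

# Statistics

The pointwise one-way RM-ANOVA uses the standard within-subject
decomposition, vectorized over time; `epsilon` is the Greenhouse–Geisser
factor of the double-centered condition covariance at each time point,
clipped to `[1/(k-1), 1]`, and the adjusted p uses `pf(F, eps*df1,
eps*df2)` without monotonization (for F below ~1 the adjustment can
lower p slightly; nothing is significant there). Family-wise control
permutes condition labels within subject (all `k!` relabelings equally
likely; exhaustive enumeration when `(k!)^n` does not exceed the
requested count), takes the maximum F over all components × time points
of one analysis family, and declares a point significant when
`(1 + #{max-null >= F}) / (n_perm + 1) <= alpha` — valid by construction.
The RM-ANCOVA centers the dependent measure and all covariates within
subject and fits condition plus pooled covariate slopes jointly; error df
is `n(k-1) - (k-1) - p` (for 16 subjects, 3 conditions and 3 covariates:
27). A covariate with no within-subject variance is dropped, so the model
reduces exactly to the RM-ANOVA.

# The synthetic-data generator

The generator emulates the study design: 16 subjects, 128 channels at
1000 Hz, 40 trials per emotional condition, laser onset 1.1 s after
picture onset, with a desk-scale profile (8 subjects, 64 channels,
500 Hz, 20 trials, 10-mm grid) used by the tests; `paper_scale = TRUE`
restores the full sizes. Ground truth is three Gaussian-pulse dipoles:

* an insula-like right-anterior source, 150 ms, gains (1, 1, 1.3) —
  negative-enhanced;
* a posterior-cingulate/precuneus-like source, 210 ms, gains (1.3, 1, 1)
  — positive-enhanced;
* an unmodulated midline premotor source at 300 ms.

Positions are nominal (a spherical model has no anatomy): each is placed
within the sensor cap's sensitivity so every simulated cluster is
recoverable in principle, and latencies are separated by more than two
pulse widths, as successive LEP component peaks are. Single-trial noise
has two parts: ongoing background brain activity — 50 random interior
dipoles with white moment time courses (15 nA·m SD each, about 6.5 µV
sensor RMS), spatially correlated through the same head model — plus
1.5 µV white instrumental noise. An earlier all-white noise model with
the same total power was discarded as unphysical: white sensor noise
loads the smallest eigendirections of the gram matrix and swamps source
space even at 7:1 sensor SNR, which no realistic recording does.
Eyeblinks arrive at Poisson times (3/min) with a frontal-positive
topography and a ~300 ms bump, at 120 µV. Between-subject spread is
10 ms latency jitter and log-normal amplitude scatter (SD 0.2).
Behavioral ratings are truncated normals whose condition means default to
the published pain/valence/arousal means (2.78/2.83/3.34 etc.), with
0.5 between-subject and 1.0 trial SD.

What the generator does *not* emulate: realistic cortical geometry,
multiphasic component waveforms, 1/f spectra and alpha rhythms,
ECG artifacts, or picture-locked visual potentials. Passing tests
therefore demonstrate the correctness of the machinery under a
known-truth model, not performance on real recordings.

# Problem sizes and numerical choices

The test suite runs the desk profile end to end (8 subjects, 64
channels, 10-mm grid ≈ 2 200 voxels, 350-sample series), with the
permutation calibration at reduced dimensions (8 × 3 × 100 points, 200
permutations, 100 replicates) and the selectivity check over 20 seeded
replicates at 500 permutations. The acceptance script uses the full
stated calibration (200 null datasets of 16 × 3 × 800 points, 500
permutations). Pseudo-inverses use an eigenvalue cutoff at 1e-12 of the
largest eigenvalue (the average reference makes the gram matrix rank
`C-1`). Filters are 4th-order Butterworth applied forward–backward with
reflection padding; the 2 Hz edge places poles near the unit circle, so
linear identities (e.g. filter/average commutation) hold to ~1e-8
relative rather than machine precision. All randomness flows from a
single integer seed; identical configurations reproduce byte-identical
outputs.

# Known limitations

* The spherical head model and Fibonacci montage are stand-ins; no
  electrode digitization or MRI geometry is supported.
* Epoch rejection uses a peak-to-peak threshold (default 100 µV in the
  standalone function; 300 µV in the simulated pipeline where blink
  residues are the only large artifacts) in place of visual inspection.
* The EDF format is not read or written; the documented plain-text
  fixture container (YAML header + TSV matrices) is the interchange
  format, with NIfTI export for volumes and TSV for all tables.
* Anatomical labeling of cluster peaks is out of scope; peak tables
  report head-frame coordinates, cluster extent and T values only.
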