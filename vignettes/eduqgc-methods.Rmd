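---
title: "Equivariant quantum graph circuits for molecular regression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivariant quantum graph circuits for molecular regression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eduqgc)
```

## The problem

Predicting scalar molecular properties — here the HOMO-LUMO gap in Hartree —
from a molecular graph is a regression task over attributed graphs: heavy
atoms (C, N, O, F, at most nine per molecule) carry discrete features
(atomic number, bonded-hydrogen count, aromaticity, hybridization) and bonds
carry a type (single, aromatic, double, triple). Any useful model must be
invariant under relabelling of the atoms. `eduqgc` implements a quantum
circuit model with that invariance built into its gate structure, plus
matched classical baselines, a synthetic data generator, and an exact
training stack, so that the whole pipeline runs reproducibly without
external data.

## Model

### Encoding

One qubit per node, prepared from $|0\rangle$ by $RY(\theta_1)$ then
$RZ(\theta_2)$, with all rotations in the convention $\exp(-i\theta P/2)$.
$\theta_1$ is the Bloch polar angle and $\theta_2$ the azimuth of the
prepared single-qubit state. The fixed schemes:

* `an` — only the element: the four states sit at the vertices of a
  tetrahedron inscribed in the Bloch sphere (polar angle $\arccos(-1/3)$ for
  N, O, F; azimuths $0, \pm 2\pi/3$), the maximally separated arrangement of
  four pure states. The printed form of this scheme in the source material
  is internally inconsistent ("cos(−1/3)" for a polar angle and a category
  range that does not match the element set); the tetrahedral reading is the
  only one that realizes the stated geometry, and the tests verify all
  pairwise Bloch inner products equal $-1/3$.
* `an_nh` — element on RY and hydrogen count on RZ, evenly spaced:
  $\theta_1 = (2z-7)\pi/4$, $\theta_2 = 2\pi n_h/5$.
* `an_arom_hyb` — element on RY as above; aromaticity $a \in \{0,1\}$ and
  hybridization $h \in \{1,2,3\}$ (sp, sp2, sp3) jointly on RZ as
  $(-1)^a (2h-1)\pi/6$.

The hybrid schemes replace the fixed table by a trainable *angle extraction
network*: one-hot features (length 9 for element + hydrogen count, length 8
for element + aromaticity + hybridization, with aromaticity as a single
binary entry — this is what reconciles the 46-parameter count), one hidden
layer of dimension 4 with ReLU, an output layer of dimension 2 squashed by
$2\pi\cdot\mathrm{sigmoid}$ so both angles stay in $(0, 2\pi)$. The same
network is shared by all nodes, preserving equivariance. Its parameter count
is $4d + 14$: 50 for $d = 9$, 46 for $d = 8$.

### EDU-QGC layers

Each layer is a *node layer* followed by a *link layer*. The node layer
applies one shared single-qubit unitary to every atom qubit — an arbitrary
ZYZ unitary $RZ(a)RY(b)RZ(c)$ with three angles in the **default** variant,
a single $RY$ in the **simple** variant. The link layer applies one EDU per
bond,

$$\mathrm{EDU} = (V^\dagger \otimes V^\dagger)\, D\, (V \otimes V),
\qquad D = RZZ(d),$$

with the diagonal angle $d$ trainable per layer (shared by all EDUs in the
layer) and the node-local $V$ trainable per bond type (shared across
layers). This split follows the per-bond-order/per-layer parameter notation
of the circuit diagrams; the prose description admits a second reading, but
only this one keeps the parameter count per extra layer minimal and matches
the diagram labels. Because $D$ is diagonal and symmetric under qubit
exchange, every EDU commutes with the swap of its two qubits, and EDUs of
the same bond type commute with each other. EDUs of *different* types
generally do not commute, so the link layer applies bond-type blocks in a
fixed total order: single, aromatic, double, triple, then master. Within a
block, bonds are applied in ascending (min endpoint, max endpoint) order —
harmless by commutation, fixed for reproducibility.

Two optional modifications: **re-uploading** repeats the full encoding
after every layer ($2L$ extra single-qubit gate layers for $L$ layers — 6
for the standard 3-layer model); a **master node** appends one qubit
prepared in $|+\rangle$ (i.e. $RY(\pi/2)$, no RZ), linked to every atom by a
fifth bond type with its own EDU parameters and its own node-layer unitary.
The master state is fixed, not trainable: the model description requires
only a state distinct from all encoding states, and a fixed choice keeps
parameter-count comparisons across architectures clean. The master bond
block is applied last, after triple — the enforced ordering must be total
and the master link has no chemical bond order to slot it elsewhere. The
master qubit participates in the readout sum and tensor product as a full
node of the augmented graph.

### Readout

Local: $r_0 + \frac{r_1}{|V|}\sum_v \langle Z_v\rangle$; global adds
$r_2\,\langle \bigotimes_v Z_v\rangle$. All $r$ coefficients are trainable
(the expectations are bounded by 1, so the affine envelope sets the output
scale), and local $\equiv$ global at $r_2 = 0$ exactly. Predictions are
therefore bounded by $|r_0| + |r_1| (+ |r_2|)$.

### Classical baselines

Three message-passing layers over the same initial information (the two
fixed-encoding angles as node features, dimension 2 throughout):

* GGNN-style convolution
  $x_i' = \Phi x_i + \mathrm{aggr}_{j\in N(i)} NN(e_{ij})\,x_j$, with the
  edge network $NN$ mapping one-hot bond type through a hidden layer of 2
  (ReLU — the activation is not pinned down by the source; ReLU is the
  conventional choice) to a $2\times2$ matrix, and aggregation add, mean or
  max. The aggregation over an empty neighbourhood is defined as the zero
  vector so the layer is total on any graph. No nonlinearity between GGNN
  layers (the update equation is stated without one).
* GCN layer
  $x' = \mathrm{ReLU}(\tilde D^{-1/2}(A+I)\tilde D^{-1/2}\,x\,W^\top)$ with
  the standard self-loop normalization and bond orders
  $\{1, 1.5, 2, 3\}$ as adjacency entries (the source states only that link
  features enter the adjacency; bond order is the natural scalarization).

The mean over nodes yields a 2-vector; a scalar head $w\cdot\bar x + b$
(the minimal scalarization, which the source leaves unstated) produces the
prediction. Master nodes are a quantum-side device and are rejected by the
classical layers.

## Gradients

Every rotation angle $\theta$ parameterizes a gate $\exp(-i\theta P/2)$
with $P^2 = I$, so the parameter-shift rule
$\partial_\theta f = \tfrac12[f(\theta + \pi/2) - f(\theta - \pi/2)]$ is
exact. Shared parameters (node angles across qubits, $d$ across EDUs, $V$
angles across layers and across the $V$/$V^\dagger$ factors — the daggered
factor contributes with coefficient $-1$ and reversed ZYZ order) are
handled by summing the shift-rule contribution of every gate occurrence.
Readout-coefficient gradients are the measured expectations themselves.
For hybrid encodings the shift rule gives the sensitivity of the prediction
to each encoding angle (summed over re-uploading repetitions), which is
then chained through the angle extraction network analytically. The
implementation replays only the circuit suffix after the shifted gate,
using prefix states cached from the unshifted forward pass, and compiles
gate index sets once per circuit.

Classical-baseline gradients are computed by central finite differences:
the baselines have a few dozen parameters and a cheap dense forward pass,
and at step $10^{-6}$ the truncation error is far below any
training-relevant scale. Tests compare the quantum/hybrid analytic
gradients against the same finite-difference oracle on every coordinate;
coordinates whose true derivative is below the finite-difference noise
floor (about $10^{-10}$ for this step size) are compared absolutely, since
a relative comparison of two numbers that are both numerically zero is
meaningless.

## Training protocol

Adam with learning rate $0.01$, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$; batch size 128 (the final incomplete minibatch is
used, not dropped); 150 epochs with validation every 10 epochs and the
lowest-validation-loss weights selected — the final epoch is always
validated. Quantum weights (all angles and all $r$ coefficients) start at
exactly 1; network and classical weights use seeded Glorot-uniform
initialization with zero biases. Classical models run 3 restarts and keep
the overall best validation weights; quantum and hybrid models run once.
Validation is computed at epochs $10, 20, \dots$; no epoch-0 validation
point is recorded, since model selection can never prefer the untrained
weights in practice and the choice only shifts the curve's origin. Epoch
shuffling is seeded from the training seed, making runs bit-reproducible.

## Synthetic data

`generate_molecules()` emulates the small-organic regime the model targets:
sizes 1–9 weighted towards larger molecules (as in QM9), elements drawn
with carbon-dominant composition (C 70 %, O 16 %, N 12 %, F 2 %), a random
spanning tree plus occasional ring-closing bonds under a simplified valence
budget (C 4, N 3, O 2, F 1; aromatic bonds count 1.5), benzene-like
aromatic six-rings with probability 0.2 when size permits, occasional
double (15 %) and triple (5 %) bonds where the budget allows, hydrogens
set to the leftover valence clipped to 0–4, and hybridization derived from
the incident bonds (sp for triple, sp2 for aromatic/double, else sp3).
These are statistical choices, not chemistry: there is no kekulization, no
3D geometry, and no guarantee that every sampled graph is a stable
molecule. Consequently, passing tests demonstrate the *model machinery* —
equivariance, gradients, optimization, recoverability of a function in the
model class — on realistic graph statistics; they say nothing about
predictive accuracy on DFT-labelled data, which requires the external QM9
dataset and full-scale training.

Labels come from `teacher_label()`: a frozen model of the same circuit
family evaluated on each graph plus optional Gaussian noise. This makes the
regression target realizable by construction, which is exactly what a
parameter-recovery check needs: a model trained on 64 noiseless
teacher-labelled molecules for 50 epochs must cut its training MSE by at
least half (it achieves ~98 % in practice).

## Numerical choices

* Dense statevector simulation only, up to 12 qubits; double precision
  throughout; no shot sampling — the reference experiments are noiseless,
  and exactness is what makes oracle tests sharp. Global phase is never
  compared, only observables and amplitude moduli.
* Tolerances: gate/EDU algebra to $10^{-12}$; state equalities that
  accumulate over a layer to $10^{-10}$; full-model permutation invariance
  to $10^{-9}$; gradient agreement to $10^{-5}$ relative with the absolute
  floor discussed above.
* The link-layer scheduler computes an exact minimum edge coloring per
  bond-type block by backtracking (at most ~12 edges per molecule), so the
  rounds-per-block equal the block's chromatic index, always within
  $[\Delta, \Delta+1]$ by Vizing's theorem. Scheduling is an analysis tool
  (parallel-depth accounting); execution through the schedule provably
  reproduces the sequential layer because same-type EDUs commute.
* The single-qubit gate-layer counter uses a fixed convention — encoding
  contributes 2 layers per application, a node layer 3 (default) or 1
  (simple), each EDU block twice the single-qubit gate count of $V$, and
  adjacent same-axis RZ layers between consecutive EDU blocks merge — which
  reproduces the unambiguous re-uploading overhead of $2L$ layers. The
  default-vs-simple comparison additionally depends on circuit-diagram
  details that admit multiple readings and is reported by the counter but
  not singled out as a guarantee.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to exercise every code path with comfortable margins:
10-molecule sweeps for the invariance properties (20 permutations each,
eight architecture variants), a 4-atom molecule for the coordinate-complete
gradient checks (five variants including master-node and hybrid), and the
64-molecule/50-epoch teacher recovery. Full-scale training
(10,000 molecules, 150 epochs) is a protocol the package supports but does
not ship as a test; it requires externally sourced labelled data to be
scientifically meaningful.

## Known limitations

* The valence model is a simplification; generated aromatic systems are
  restricted to isolated six-rings.
* SMILES input is out of core scope: molecules enter through the JSON-lines
  interchange format (or the generator). An external cheminformatics
  toolkit can populate that format.
* Simulation cost grows as $2^n$; the implementation caps registers at 12
  qubits (9 atoms + master fits comfortably).
* Training at the full published protocol is CPU-hours in this
  implementation; the package targets method study at small scale, not
  state-of-the-art benchmarking.
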