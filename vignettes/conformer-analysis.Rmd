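---
title: "Methods: rotational-spectroscopy conformational analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rotational-spectroscopy conformational analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotjet)
```

This vignette is the package's own account of the models it implements,
the choices that were genuinely open, and what its tests do and do not
demonstrate.

## The semi-rigid asymmetric rotor

Rotational energy levels are computed from the Watson A-reduced
Hamiltonian in the I^r representation (molecular a axis along the
symmetric-top z axis),

$$H = \tfrac{B+C}{2}\,\mathbf{J}^2 + \left(A - \tfrac{B+C}{2}\right)J_a^2
      + \tfrac{B-C}{4}\,(J_+^2 + J_-^2)
      - \Delta_J \mathbf{J}^4 - \Delta_{JK}\mathbf{J}^2 J_a^2
      - \Delta_K J_a^4 - \text{(the two } \delta \text{ terms)},$$

with all parameters in MHz. The A-reduction and I^r representation are the
community defaults for near-prolate tops (Ray's asymmetry parameter for
the systems of interest here is around $-0.99$); nothing in the package
depends on the molecule being near-prolate, but the assignment heuristics
do (see below). Five-parameter fits float $A, B, C, \Delta_J, \Delta_{JK}$
and hold $\Delta_K, \delta_J, \delta_K$ at zero, matching common practice
for jet-cooled spectra of this resolution; all eight parameters are
available.

Each J block is built in the signed-K symmetric-top basis and
Wang-symmetrized into four parity blocks before diagonalization. This is
not merely traditional: near-degenerate asymmetry doublets at high $K_a$
are degenerate to machine precision, and a plain full-matrix
diagonalization then returns arbitrarily mixed eigenvectors whose
direction-cosine line strengths leak across parity classes. Per-block
diagonalization keeps eigenvectors parity-pure at any degeneracy, and the
Wang symmetry fixes the $K_c$ label exactly: within a block, ascending
eigenvalues follow the $K_a$ ladder, and the Wang sign distinguishes
$K_a + K_c = J$ from $J+1$. Exact degeneracies are ordered lower-$K_a$
first.

Line strengths use the Wigner–Eckart theorem with molecular-frame rank-1
spherical tensor components of the dipole; the needed 3j symbols are
evaluated by the Racah factorial sum. Intensities follow the thermal
line-strength model $\mu_g^2\, S\, (e^{-E_l/kT} - e^{-E_u/kT})$ on an
arbitrary shared scale — no chirp-polarization or radiative-transfer
physics, which cancels in the relative comparisons the pipeline makes.
The default rotational temperature is 2 K, typical of neon expansions.
In the symmetric-top limit the a-type strengths reduce analytically to
Hönl–London factors, which the tests use as an independent oracle, and a
brute-force enumeration of all state pairs validates the selection-rule
logic at small J.

## Least-squares fitting

`fit_constants()` minimizes $\sum_i w_i(\nu_i^{obs} - \nu_i^{calc})^2$ by
Gauss–Newton iteration. Because every Hamiltonian parameter enters
linearly, the frequency derivatives are exact Hellmann–Feynman quadratic
forms $v^\top (\partial H/\partial p)\, v$ — no finite differencing, which
matters for the tiny quartic constants. Weights are uniform by default
(published fits of this kind quote a single RMS, implying uniform
measurement uncertainty); per-line $1/u^2$ weighting is available.
Convergence is declared when the relative RMS change falls below $10^{-6}$
(or the RMS is below 1 Hz); 50 iterations flag non-convergence rather
than fail silently. Steps that would leave the physical region
($A \ge B \ge C > 0$) are halved. Standard errors come from the
covariance at the optimum scaled by the reduced chi-square; replicate
simulations in the test suite confirm the reported uncertainties are
calibrated (z-score spread within 0.7–1.3). Blended lines share one
observed frequency and are compared against the mean of their components'
calculated frequencies, counting once in N.

## Automated assignment

The assignment problem — from a broadband spectrum and quantum-chemistry
constants good to a few percent, to a fitted line list — is where the
open design space was largest. A naive predict-match-fit loop with a
shrinking tolerance fails immediately: a 0.5% error in $B+C$ displaces the
$J+1 \leftarrow J$ cluster at 8 GHz by tens of MHz, and centrifugal
distortion alone sags the high-J end of the $K_a = 0$ series by up to
$\sim$60 MHz relative to a rigid comb. `iterate_assign_fit()` therefore
mirrors how such spectra are assigned by hand:

1. **Comb bootstrap.** Peaks are searched for progressions
   $\nu \approx s\,n + b\,n^3$ near the predicted $B+C$; the cubic term is
   exactly the leading distortion signature ($b = -4\Delta_J$ for the
   $K_a = 0$ series). The $K_a = 0$ series and both $K_a = 1$ doublet
   series all form such combs, so each candidate is tentatively read as
   $K_a = 0$ ((n)~0,n~ ← (n−1)~0,n−1~), fitted, and scored by cluster
   symmetry: a genuine $K_a = 0$ member has doublet satellites at roughly
   $\pm(B-C)/2$ per harmonic on *both* sides, while an impostor comb sits
   at a cluster edge. This calibrates $B+C$ and $\Delta_J$ before any
   tolerance matching; the correction is split evenly between B and C,
   keeping the theoretical $B-C$ (the best estimate until doublets are
   assigned).
2. **$K_a = 1$ satellite series.** Each doublet side is detected as a
   whole progression and refined per harmonic (an iterated
   one-peak-per-n comb fit that converges to the majority series), at low
   harmonics first — above $n \approx 8$ the satellites of a strong
   species interleave with its $K_a = 2$ components and branch identity
   needs the fitted $\Delta_{JK}$. Their joint fit with the $K_a = 0$
   lines separates B from C and exposes $\Delta_{JK}$.
3. **Polish and full admission.** The $K_a \le 1$ solution is re-assigned
   at shrinking tolerance; then all predicted lines — high-$K_a$ cluster
   stacks entering as blends, and any b/c-type lines — are admitted at
   tight tolerance (where chance matches are improbable), with robust
   (MAD-based) outlier trimming at every step. $A$ floats last: a-type
   $K_a \le 1$ lines leave it essentially unobservable, so it is fixed
   until $K_a \ge 2$ structure, b/c-type lines, or both doublet series
   constrain it. When b- or c-type dipoles are present, $A$ is first
   calibrated by a scan that counts b/c-type prediction–peak matches,
   since those lines carry $A$ at full weight but are useless while $A$
   is tens of MHz off.

Peaks not explained by the final model are returned as leftovers; a
second species is found by re-running on them, reproducing the
discard-and-search workflow by which weaker rotamers are discovered.

Ambiguity handling follows two regimes: `assign_lines()` by default
leaves a peak with two candidate predictions inside the tolerance
unassigned and reports it (the conservative rule appropriate for final
line lists), while the iterative loop internally assigns to the nearest,
because during bootstrap the predictions are dense relative to the
tolerance and the trimmed refits correct occasional mistakes.

## Populations, relaxation, barriers

Pre-expansion populations are Boltzmann fractions
($k = 0.6950348\ \mathrm{cm^{-1}\,K^{-1}}$) at a user-supplied
temperature, defaulting to 298 K since the relative Gibbs energies are
computed there; laser-ablation effective temperatures are not well known,
so the temperature is an explicit, logged parameter everywhere. The
energy field follows the precedence Gibbs > ZPE-corrected > electronic.
Collisional relaxation in the expansion is modelled by the empirical
barrier-threshold rule: population transfers *completely* from a
higher-energy conformer to a lower one when their interconversion barrier
is below 400 cm⁻¹ (partial-transfer kinetics are out of scope). Transfers
are applied repeatedly until stable, so chains drain correctly; the
operation conserves total population exactly and is idempotent.

Barriers are read off scanned 1D or 2D torsional energy grids as the
minimax path energy (minimum over 4-neighbour periodic grid paths of the
path maximum, minus the start energy), computed by a widest-path variant
of Dijkstra's algorithm — exact for the given grid resolution. The tests
verify it against an independent exact characterisation (the smallest
level set connecting start and end) and against exhaustive path
enumeration on tiny grids.

Detectability scores, fraction × $\mu_a^2$ relative to the strongest
species, capture why a low-dipole conformer can escape detection at
appreciable population; the threshold is advisory, never a hard filter,
as is the dipole-type consistency check in `match_conformers()`
(a predicted 0.5 D component counts as "expected observable").

## Glucophore evaluation

`glucophore_triangle()` computes the three pairwise distances of the
AH/B/γ contact from Cartesian coordinates, with γ optionally the centroid
of a ring. Compliance applies the classic criterion — the two
electronegative atoms separated by 2.5–4 Å — to the heavy-atom A⋯B
distance (not H⋯B; the criterion is stated for the electronegative atoms,
though which distance the original model intended is genuinely ambiguous).
Rotational constants from geometries use
$X\,(\mathrm{MHz}) = 505379.07 / I_x\,(\mathrm{amu\,Å^2})$ with
most-abundant-isotope masses (parent species).

## The synthetic-data generator

`gen_broadband()` emulates the data products of a 2–8 GHz broadband
jet experiment: per-conformer a-type combs weighted by population and
dipole-squared intensities, Gaussian frequency noise of order 10 kHz on
every line, uniformly placed interloper lines (photofragments, water
clusters) drawn from the same intensity scale as real lines, Gaussian
line profiles of 0.15 MHz FWHM on a 0.03 MHz grid (Doppler-limited
broadband resolution; Gaussian rather than Voigt because jet spectra are
Doppler-dominated), and white baseline noise. It does **not** model
baseline drift, FID-level artifacts, intensity calibration error,
hyperfine structure, or correlated noise — so passing recovery tests
demonstrate the assignment/fitting machinery under idealized line shapes,
not robustness to every instrumental pathology. The ground-truth ledger
(which stick belongs to which species) ships with each spectrum for use
as a test oracle.

Default study conditions follow the dulcin experiment: a 2–8 GHz window,
two a-type rotamers at 10:1 intensity, ~10 kHz line noise, 20
interlopers, rotational temperature 2 K. Problem sizes in the test suite
(J ≤ 20, 52-line fits, 100 replicate seeds for the calibration study)
were chosen as representative of desk-scale analyses of a single
molecule.

## Known limitations

* The weak second species in a 10:1 two-conformer spectrum yields B and C
  within their standard errors, but its A — constrained only through the
  $K_a = 1$ asymmetry splitting of a-type lines — is recovered at the
  percent level (entirely sufficient for conformer identification, and
  mirroring the two-orders-of-magnitude larger A uncertainty such fits
  show in practice), and its $\Delta_{JK}$ at the few-percent level.
* Sextic and higher distortion, internal rotation, and ¹⁴N quadrupole
  hyperfine structure are out of scope (the latter unresolved at
  broadband resolution in the motivating experiment).
* The assignment heuristics assume a near-prolate a-type R-branch comb;
  b/c-type-only spectra or near-oblate tops would need a different
  bootstrap.
* `relax_fractions()` is all-or-nothing per edge; no master-equation
  collision dynamics.
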