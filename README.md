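# qsgwst — quasiparticle self-consistent GW for molecules, in imaginary time

`qsgwst` computes charged excitation energies — ionization potentials (IP)
and electron affinities (EA) — of small closed-shell molecules with the
quasiparticle self-consistent *GW* method (qs*GW*), using the space-time
formulation of the *GW* self-energy.

## The method

The *GW* approximation truncates the self-energy expansion after the first
order in the screened Coulomb interaction, Σ = *GW*. qs*GW* removes the
starting-point dependence of one-shot *G*₀*W*₀ by mapping the dynamic,
non-Hermitian self-energy onto a static Hermitian exchange-correlation
potential and iterating a mean-field-like SCF:

1. From the current spectrum {ε_p, φ_p}, build the non-interacting Green's
   function G₀(iτ), diagonal in the MO basis, with a mid-gap chemical
   potential so both time branches decay.
2. Build the RPA polarizability as a product of Green's functions in
   imaginary time, Π(iτ)_PQ = −2 Σ_ia B^P_ia B^Q_ia e^(−Δ_ia τ), in an
   auxiliary (RI) basis; cosine-transform to imaginary frequency and solve
   the screening Dyson equation W̃(iω) = (1 − Π(iω))⁻¹ − 1 (symmetric
   metric, so the bare interaction is the identity).
3. Contract Σ_c(iτ) = G(iτ)·W̃(iτ) as a direct product in imaginary time;
   Fourier-transform the even/odd parts to the imaginary-frequency grid.
4. Analytically continue each matrix element of Σ_c to the real axis with
   Vidberg–Serene continued-fraction Padé approximants, and build the static
   potential: mode A, V_pq = ½[ReΣ_pq(ε_p) + ReΣ_pq(ε_q)]; or mode B
   (default), the optimum potential ReΣ_pp(ε_p) on the diagonal and the
   static limit ReΣ_pq(0) off the diagonal. Off-diagonal entries below
   10⁻⁶ Ha are zeroed (analytic-continuation noise).
5. Assemble H = H_Hartree + ΔV_H + Σ_x + V_c, accelerate with Pulay DIIS
   (depth 10) or linear mixing (α = 0.35), diagonalize, rotate the orbitals,
   and repeat until the RMS density residual N_F stays below 10⁻⁷ for two
   consecutive iterations (30 iterations maximum).

At convergence, IP = −ε_HOMO and EA = −ε_LUMO of the qsGW spectrum,
independent of whether the cycle started from PBE, PBE0 or HF.

The non-uniform imaginary time/frequency grids are regenerated from the
current spectrum at every iteration; transforms between the two domains use
least-squares-fitted cosine/sine weights (see the methods vignette).

The package is self-contained: it ships its own Gaussian-integral engine
(McMurchie–Davidson), restricted HF/PBE/PBE0 mean fields, even-tempered
orbital basis sets (`et-dz`, `et-min`) and an automatic even-tempered
auxiliary-basis generator, plus a 15-molecule fixture library with
literature geometries.

## Worked example

```r
library(qsgwst)

mol <- fixture_molecule("H2O")
res <- run_qsgw(mol, basis = "et-dz", guess = "PBE0",
                config = qsgw_config(mode = "B", n_grid = 32))
print(res)
#> <qsgw_result> PBE0 guess, mode B: converged in 9 iterations
#>   IP = 12.9930 eV   EA = -2.8936 eV   (N_F = 1.01e-08)
```

The IP is the negative HOMO quasiparticle energy of the converged qsGW
spectrum (experimental vertical IP of water: 12.62 eV; the residual
difference is the small even-tempered basis). Repeating the run with
`guess = "PBE"` or `guess = "HF"` changes the IP by about a microvolt —
the starting-point independence that defines qsGW:

```r
r_hf <- run_qsgw(mol, basis = "et-dz", guess = "HF",
                 config = qsgw_config(mode = "B", n_grid = 32))
abs(r_hf$IP - res$IP) * 1000   # meV
#> 0.00099
```

A command-line front end is included:

```sh
Rscript inst/cli/qsgw.R run inst/extdata/geometries/H2O.xyz \
    --basis et-dz --guess pbe0 --grid-points 32 --out h2o.json
Rscript inst/cli/qsgw.R bench --molecules H2O,CH4 --out bench.json
Rscript inst/cli/qsgw.R fixtures list
```

## Benchmark reproduction

`scripts/acceptance.R` reruns the two scaled-down benchmark experiments from
scratch on the fixture set (32 grid points, ε_SCF = 10⁻⁷): the
starting-point sweep over PBE/PBE0/HF with mode B, from which it reports the
mean absolute pairwise IP deviation and the maximum absolute IP/EA deviation
across starting points, and a mode A vs mode B comparison from a PBE0 guess,
reporting the average absolute IP/EA difference between the two potential
constructions. All three statistics are written (in meV) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The sweep takes roughly 15 minutes on one CPU core.
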