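# aquabridge

Detection and ensemble statistics of protein–water bridges in R.

Water molecules couple protein residues by donating and accepting
hydrogen bonds: a chain of one or more waters hydrogen-bonded between
two residues is a *water bridge*, and across an NMR ensemble or an MD
trajectory the persistence of such bridges marks functionally relevant
hydration. `aquabridge` is for structural biologists and simulators who
want those interactions quantified from standard files — PDB, mmCIF, or
a topology plus a binary DCD trajectory — without leaving R.

## The model in brief

A hydrogen bond D–H···A is accepted when the heavy-atom distance
satisfies `dist(D, A) ≤ distDA` (default 3.5 Å) and the angle at the
hydrogen between the H→D and H→A vectors falls in the applicable range
(`anglePDWA`, `anglePAWD` for protein↔water, default [100°, 180°];
`angleWW` for water–water, default [140°, 180°]). Each water donates
and accepts at most two bonds; excess candidates are pruned
longest-first. An angle-free mode (distance only) serves hydrogen-less
crystal structures. On the resulting graph:

* the **Chain method** reports every residue pair linked through at
  most `maxDepth` waters (default 2), with the shortest water path,
  the water multiplicity, and the endpoint distance;
* the **Cluster method** reports connected components of waters and
  the residues they touch;
* `analyze_ensemble()` aggregates frame-wise detections into per-pair
  bridge frequency, endpoint-distance mean ± population SD, water
  counts, and interaction duration (longest consecutive run, in ps
  when a timestep is known);
* `cluster_waters()` condenses recurrent water positions into
  hydration sites by density-based clustering (eps = 1.0 Å,
  min_samples = 4 by default).

Everything is tested against independent oracles (exhaustive path
enumeration, all-pairs scans, reference density clustering) on
synthetic fixtures with exactly known planted truth; the fixture
generators ship with the package.

## A worked example

```r
library(aquabridge)

# a seeded 10-frame trajectory with two planted bridges (depths 1 and 2)
# switching on with probability 0.7 per frame
sp <- fixture_spec(planted_depths = c(1, 2), occupancy_p = 0.7,
                   n_frames = 10, seed = 42)
tf <- make_trajectory_fixture(sp)

ens <- analyze_ensemble(tf$trajectory)
ens$stats[, c("res_a", "res_b", "frequency", "mean_distance",
              "mean_waters", "max_consecutive")]
#>     res_a   res_b frequency mean_distance mean_waters max_consecutive
#> 1 A:3:GLY A:4:GLY       0.6           8.4           2               3
#> 2 A:1:GLY A:2:GLY       0.5           5.6           1               2
```

The depth-2 bridge (residues `A:3`–`A:4`, two bridging waters, 8.4 Å
between the endpoint N and O atoms) was realized in 6 of 10 frames, the
depth-1 bridge in 5 — exactly the planted on-fractions recorded in the
fixture truth (`tapply(tf$truth$on, tf$truth$pair, mean)` gives 0.5 and
0.6). Because detection is deterministic given coordinates, recovered
frequencies equal planted fractions with no tolerance.

Hydration sites from pooled water positions:

```r
sf <- make_site_fixture(fixture_spec(seed = 42))   # 3 sites, sigma 0.3 A
cw <- cluster_waters(sf$observations, eps = 1.0, min_samples = 5)
cw$sites[, c("site", "x", "y", "z", "n_members")]
#>   site           x           y           z n_members
#> 1    1 -0.01070153 0.030210424 -0.04537533        50
#> 2    2  5.99288510 0.002381963 -0.00860287        50
#> 3    3 -0.01846240 6.038224283 -0.03582634        50
```

All three planted centers — (0,0,0), (6,0,0), (0,6,0) — are recovered
to within 0.07 Å.

A command-line front end lives at `inst/scripts/aquabridge`
(subcommands `bridges`, `ensemble`, `sites`, `fixture`; flags mirror
the criteria fields, e.g. `--distDA 3.2 --maxDepth 3 --angle-free`).

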