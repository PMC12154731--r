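# lapnet

Substrate-activation detection for hydrolases from Laplacian
electron-density contour maps.

Enzymes that hydrolyse ester, peptide and related bonds initiate catalysis
by a nucleophilic attack on the substrate's carbonyl carbon. Whether a
given molecular-dynamics frame of the enzyme–substrate complex is
*reactive* (activated) is visible in the Laplacian of the electron
density, ∇²ρ(**r**): a reactive frame shows a charge-depletion region
(∇²ρ > 0) breaking the valence-shell charge-concentration envelope
(∇²ρ < 0) of the carbonyl carbon on the attack side; a non-reactive frame
keeps the envelope closed. The fraction of reactive frames along a
trajectory is the activation efficiency of the active site for that
substrate.

`lapnet` is for computational enzymologists who have per-frame
wavefunctions (e.g. from QM/MM MD) and want this decision automated. It
implements:

* **Molden wavefunction I/O** for closed-shell s/p/d Gaussian bases
  (`read_molden`, `write_molden`);
* **analytic ρ and ∇²ρ evaluation** on the plane through the carbonyl C,
  carbonyl O and the nucleophile (`plane_from_atoms`, `sample_map`);
* **zero-contour imaging**: the single ∇²ρ = 0 contour, rendered to a
  fixed 960 × 720 canvas and cropped to a 550 × 720 carbonyl-only image
  (`zero_contour`, `render_map`, `crop_carbonyl`);
* **two independent classifiers**: a small CNN trained with early stopping
  and best-weight restoration (`cnn_train`, `cnn_predict`, sigmoid score
  ≥ 0.5 ⇒ reactive, confidence = max(p, 1 − p)), and a rule-based
  valence-shell probe (`classify_map`) used to label synthetic data and
  cross-check the network;
* **trajectory statistics**: reactive fraction, run lengths, a
  Wald–Wolfowitz randomness test of state alternation (exact conditional
  null for short series), per-class confidence summaries, and k-component
  normal-mixture decomposition of nucleophilic-attack distances by EM
  (`reactive_fraction`, `runs_test`, `confidence_summary`,
  `fit_distance_mixture`);
* **a synthetic-data module** (`make_promolecule`, `generate_dataset`,
  `generate_label_series`, `generate_distance_series`) producing labeled
  promolecular wavefunctions, contour images, label series and distance
  series, so the full pipeline runs and is tested without any
  quantum-chemistry engine.

## Worked example

Generate a labeled synthetic dataset, train the classifier, and push one
wavefunction through the whole pipeline:

```r
library(lapnet)

ds <- generate_dataset(synthetic_spec(n_images = 200, seed = 42))
#> contour_dataset: 200 images ( 100 reactive / 100 nonreactive ), physical tier
#>   image size: 72 x 55   regenerated: 0

split <- split_dataset(ds, c(4, 1), seed = 2)   # 160 train / 40 validation
model <- cnn_train(ds, split, cnn_spec(), seed = 1)
cnn_evaluate(model, ds$images[split$val], ds$labels[split$val])
#> cnn_evaluation: accuracy 1
#>              predicted
#> truth         reactive nonreactive
#>   reactive          20           0
#>   nonreactive        0          20

# one frame: Molden file -> map -> contour image -> verdict
wfn <- read_molden(system.file("extdata", "carbonyl_frame_synthetic.molden",
                               package = "lapnet"))
plane <- plane_from_atoms(wfn, 1, 2, 5, resolution = 10)
map <- sample_map(wfn, plane, "laplacian")
classify_map(map)              # geometric probe
#> reactivity_label: reactive
img <- crop_carbonyl(render_map(zero_contour(map), map), map)
cnn_predict(model, img)        # CNN agrees, with its confidence
#>      raw    label confidence
#> 1 0.9979 reactive     0.9979
```

The raw score is the sigmoid output (here 0.9979, far above the 0.5
decision line), so the frame is classified reactive with confidence
0.9979 — both classifiers find the depletion break that the lobe
perturbation of this fixture creates.

Trajectory-level analysis of per-frame labels and attack distances:

```r
s <- generate_label_series(2000, p_reactive = 0.5, mean_run = 6, seed = 8)
reactive_fraction(s)
#> [1] 0.5095
runs_test(s)       # persistent runs are *not* random alternation
#> Wald-Wolfowitz runs test (normal approximation)
#>   runs = 337  expected = 1001  p = 1.633e-193 -> nonrandom

d <- generate_distance_series(n = 5000, seed = 4)   # 3-population mixture
fit_distance_mixture(d$distance, k = 3, seed = 1)
#> normal mixture fit, k = 3
#>   weight   mean     sd
#> 1 0.3005 2.7097 0.0611
#> 2 0.4193 2.8850 0.0606
#> 3 0.2802 3.0539 0.0589
#>   log-likelihood: 2854.477  converged: TRUE
```

The mixture fit recovers the three generating populations (2.71, 2.88 and
3.05 Å with weights 0.29/0.42/0.29) from the raw distances. The runs test
flags the Markov-generated series (mean run length 6) as non-random —
far fewer runs than the 1001 expected under independence — while i.i.d.
label series pass as random at the nominal 5% level.

## Command line

A thin wrapper around the same functions ships at `inst/cli/lapnet.R`:

```sh
Rscript inst/cli/lapnet.R map --wfn frame.molden --carbon 1 --oxygen 2 \
    --nucleophile 5 --out frame            # frame.png + sidecar JSON
Rscript inst/cli/lapnet.R synth --n 1000 --seed 7 --out dataset/
Rscript inst/cli/lapnet.R train --data dataset/ --out run
Rscript inst/cli/lapnet.R classify --model run_model.json --images dataset/ --out conf.csv
Rscript inst/cli/lapnet.R traj --labels labels.csv --distances dist.csv --out report.json
```

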