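# USWIcrack

In silico ultrasonic shear-wave imaging (USWI) of thin blood-filled cracks
(lacerations) in a liver-mimicking elastic medium, with crack localization
that never reconstructs an elasticity map.

## The problem and the method

A hepatic laceration is almost invisible to B-mode ultrasound — the
blood-filled tear is hypoechoic and the surrounding parenchyma is
homogeneous. Mechanically the situation is reversed: blood carries no shear
stress, so even a tear one-tenth of a shear wavelength thick reflects a
shear wave almost totally. `USWIcrack` simulates the whole imaging
experiment and exploits that reflection:

1. **Phantom** — a 5.0 × 5.0 cm elastic medium
   (ρ = 1200 kg/m³, ν = 0.499, E = 6 kPa, shear speed
   c = √(E/3ρ) ≈ 1.29 m/s) with one of three analytic cracks: straight
   (3.2 cm deep, 1.6 mm thick, 15° from vertical), curved (two arcs of
   radius 4.5 cm, 1.8 cm tall) or slim (0.5 cm deep, 0.5 mm thick), filled
   with a blood-mimicking material (E = 0.005 Pa).
2. **Shear-wave simulation** — ρ ∂²u/∂t² = ∇·(μ∇u) solved by explicit
   finite differences; a rod on the centre plane pushes one 100 Hz cycle;
   the axial displacement movie is exported as a 200 × 400 × 106 array
   (0.0125 cm grid, 5000 frames/s).
3. **RF synthesis** — a 5 MHz separable point spread function convolved
   with a deforming random scatterer field; 2596 samples × 256 beams per
   frame at 40 MHz.
4. **Phase-sensitive speckle tracking** — baseband correlation with a
   speckle-sized kernel, Hanning correlation filtering, phase
   zero-crossing refinement (Δ = φ·c/4πf₀), Eulerian accumulation over
   105 frame pairs.
5. **Directional filter** — per depth row, the [k, ω] quadrants of the
   x–t Fourier plane separate the incident (toward the crack) from the
   reflected (back toward the source) wave; R(x, y) = Σₜ |u_r| is the
   reflected-amplitude image.
6. **Detection** — Sobel gradients + Otsu threshold on R; the leftmost
   connected component taller than 3 mm is the crack's near-end (right)
   edge; per depth the detected position is compared with the analytic
   edge x(d) = x_top − d·tan 15° (straight/slim) or
   x(d) = x_c + √(r² − d²) (curved).

## Worked example

```r
library(USWIcrack)

cfg <- pipelineConfig("straight", preset = "reduced", seed = 1)
report <- runFullDetection(cfg, path = "direct")
report
```

```
DetectionReport: straight crack, direct path - ok
  detected depth 3.138 cm / given 3.2 cm (ratio 98.0% )
  max |relative error| of right-edge position: 1.15%
  depth given_x detected_x relative_error
1 0.208  1.4633     1.4537        -0.6530
2 0.291  1.4410     1.4288        -0.8456
3 0.416  1.4075     1.3993        -0.5824
4 0.917  1.2733     1.2662        -0.5530
5 1.291  1.1731     1.1663        -0.5803
6 1.709  1.0611     1.0522        -0.8346
7 2.083  0.9609     0.9528        -0.8360
8 2.500  0.8491     0.8414        -0.9136
9 2.917  0.7374     0.7289        -1.1516
```

The detected depth (3.138 cm) is the vertical extent of the extracted
edge contour — slightly short of the 3.2 cm truth because the reflection
weakens toward the crack tip. Each table row compares the detected
transverse position with the analytic ("given") edge at that depth; the
negative errors mean the detection sits just left of the true wall, where
the reflected-amplitude step lives. `path = "speckle"` runs the same
phantom through RF synthesis and speckle tracking instead of using the
simulated displacement directly (a few minutes of tracking), and
`pipelineConfig("none")` is the homogeneous control, which reports
`no crack detected`.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/uswi-crack.R --shape curved --path speckle \
        --seed 1 --out results/curved
```

## Package layout

- `R/phantom.R` — geometry, materials, ground-truth edges
- `R/wavesim.R` — finite-difference shear-wave solver (C++ core)
- `R/rf.R` — PSF, scatterers, RF frame synthesis
- `R/tracking.R` — demodulation, correlation tracking, accumulation
- `R/directional.R` — [k, ω] incident/reflected separation
- `R/detect.R` — Sobel edge detection, contour extraction, reports
- `R/pipeline.R` — configuration, orchestration, fixtures
- `vignettes/uswi-crack-methods.Rmd` — model, assumptions and design
  choices
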