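# srsdepth

Measurement-depth analysis for spatially resolved near-infrared
spectroscopy (SRS) tissue oximetry.

Continuous-wave SRS oximeters shine near-infrared light into tissue and
read the decay slope of the diffusely reflected intensity across two
source–detector distances ρ₁ < ρ₂; from the slopes at 770 and 830 nm
they estimate absorption, hemoglobin concentrations and regional oxygen
saturation rSO₂ = [O₂Hb]/([O₂Hb]+[HHb]). What such a probe actually
measures depends on *where* its sensitivity lies: shallow for short
separations, deep for long ones. `srsdepth` answers that question
quantitatively for probe designers and for anyone selecting a probe for
a target depth (skin/subcutaneous monitoring, gastric-tube viability
assessment through an endoscope, flap surgery):

* a compiled Monte Carlo photon-transport engine for layered turbid
  media (weighted packets, Henyey–Greenstein scattering, Fresnel
  boundaries, Russian roulette, per-voxel path-length tallies, annular
  surface detectors, bit-reproducible seeding);
* SRS measurement sensitivity per voxel and per depth,
  ΔS(x,y,z) = Δμₐ(x,y,z)·{L_B(x,y,z) − L_A(x,y,z)}, from the
  detection-weighted mean partial path lengths L = ΣLᵢIᵢ/ΣIᵢ of the two
  detectors, with peak depth, half-maximum range and 10%-of-peak depth
  summaries;
* peak-depth maps over all (ρ₁, ρ₂) combinations and the linear
  calibration D_p = a·ρ₁ + b·ρ₂ + c fitted to them, per tissue model;
* the full oximeter computation: spatial slope S = ln(I_A/I_B)/(ρ₂−ρ₁),
  absorption by the diffusion-approximation inversion
  μₐ = (S − 2/ρ)²/(3μ_s′) or by a Monte Carlo slope lookup table for
  short probes, two-wavelength hemoglobin concentrations and rSO₂;
* an in-silico analogue of the classic validation phantom: a thin,
  fully oxygenated blood layer at variable depth in an Intralipid-like
  scattering medium, measured by all four standard probes (3–5, 6–8,
  9–14, 20–30 mm).

## Worked example

Where does a 6–8 mm probe measure in skin-like tissue?

```r
library(srsdepth)

model  <- make_preset_model("homogeneous_skin", "770")
tally  <- run_simulation(model,
                         run_config(n_photons = 1e6, seed = 42),
                         annuli_at(c(3, 5, 6, 8, 9, 14, 20, 30)))
profile_metrics(depth_profile(tally, pair = c(6, 8)))
#> pair 6-8 mm: peak 2.26 mm, 50% range 0.67-4.68 mm, 10% depth 7.82 mm
```

So a 6–8 mm pair is most sensitive to tissue ~2 mm deep, keeps half its
peak sensitivity between roughly 0.7 and 4.7 mm, and sees essentially
nothing below ~8 mm. The same tally object answers for all four probes;
their peaks (≈1.4, 2.3, 3.5 and 6 mm at this photon count) shift deeper
with increasing separation — the basis for depth-selectable oximetry.

The oximetry chain on raw two-wavelength intensities:

```r
eps <- extinction_table()
p   <- probe_geometry(6, 8)
h   <- rso2_from_intensities(intensity_pair(2.54e-4, 1.00e-4, "770"),
                             intensity_pair(2.80e-4, 1.10e-4, "830"),
                             p, inversion = "diffusion", eps = eps,
                             mu_s_prime = c("770" = 1.2, "830" = 1.2))
h
#> O2Hb 0.03009, HHb 0.01502, totalHb 0.04511 mmol/L; rSO2 66.7%
```

A command-line front end over the same functions ships in
`exec/srs-workbench` (commands `simulate`, `sensitivity`, `table2`,
`map`, `regress`, `lut`, `oximeter`, `phantom`).

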