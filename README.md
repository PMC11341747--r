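# aneutreat

In silico comparison of endovascular treatments for middle-cerebral-artery
(MCA) bifurcation aneurysms. Treating these aneurysms is hard: a
conventional braided flow-diverter laid from the parent artery into one
daughter branch disrupts inflow to the sac but *jails* the other branch,
risking its occlusion; an intrasaccular flow disruptor (a dual-layer
braided bowl seated inside the sac at the neck) targets the neck without
covering any branch. `aneutreat` reproduces that comparison end to end on
synthetic, parametric vascular geometry — no patient imaging required:

1. **Generate** a watertight bifurcation-aneurysm lumen with prescribed
   neck width *d*<sub>n</sub> and maximum width *d*<sub>a</sub>;
2. **Measure** the sac (*d*<sub>n</sub>, *d*<sub>a</sub>, neck plane,
   daughter-to-parent ratio) off the surface;
3. **Size** both devices from a catalogue keyed on
   (*d*<sub>n</sub>, *d*<sub>a</sub>);
4. **Deploy** strut-level device wireframes by fast damped relaxation
   (crimp → align → progressive release → wall-constrained equilibrium);
5. **Solve** steady incompressible Newtonian flow (ρ = 1000 kg/m³,
   μ = 0.004 Pa·s, parabolic inlet, fixed-pressure outlets) on an
   immersed-boundary Cartesian grid, with the deployed device coupled as
   an anisotropic homogenized porous screen;
6. **Report** aneurysm inflow *Q*<sub>in</sub> (directional influx
   through the neck plane), daughter-vessel inflow *Q*<sub>in-DV</sub>,
   wall shear stress (WSS = μ‖∂u<sub>t</sub>/∂n‖, regional maxima), and
   treated-versus-untreated statistics: percentage reduction
   100·(1 − *Q*<sub>treated</sub>/*Q*<sub>untreated</sub>) and signed
   relative change 100·(*Q*<sub>device</sub> − *Q*<sub>baseline</sub>)/*Q*<sub>baseline</sub>.

The intended audience is researchers prototyping device-comparison
pipelines and teaching cerebrovascular CFD at desk scale; the methods
vignette (`vignettes/virtual-treatment.Rmd`) documents every model and
its limits.

## Worked example

```r
library(aneutreat)

## a wide-neck terminal-bifurcation aneurysm (case-I-like preset)
cfg  <- caseConfig("caseI", density = 27)
geom <- do.call(generateBifurcationAneurysm, cfg$geometry)
m    <- measureAneurysm(geom)
m
#> aneurysmMeasures: d_n = 8.580 mm, d_a = 9.403 mm, sdr = 0.917

selectContour(m$d_n, m$d_a)
#> deviceSpec: CNS014-15 ( contour )
#>   nominal diameter: 14 mm; microcatheter 0.027 in
#>   d_n range [ 7 , 10 ] mm; d_a range [ 8 , 10.5 ] mm

## full three-arm comparison (untreated / braided stent / intrasaccular);
## a few minutes at 27 elements per mm^3
res <- runCase(cfg)
res$report$inflow
#>      id  device      Q_in reduction
#>   caseI   stent  4.549351      93.9
#>   caseI contour 10.863656      85.5
res$report$daughter
#>      id  device  Q_in_DV relative_change
#>   caseI   stent 52.58760          -14.62
#>   caseI contour 69.91828           13.52
```

Reading: untreated, essentially the whole parent inflow
(127 of 126.4 ml/min configured) transits the sac; either device cuts
that by well over half. The stent reduces flow into the jailed
(non-stented) daughter by ~15%, while the intrasaccular device *raises*
it by ~14% — the neck is closed from inside the sac without covering the
branch. That is the clinically decisive sign pattern.

The comparison arithmetic is exact and reproduces published worked
examples directly:

```r
percentReduction(126.4, 16.5)   # 86.9
relativeChange(23.01, 27.75)    # 20.6
```

A thin CLI wraps the same functions:

```sh
exec/aneutreat size-device --dn 8.58 --da 9.37      # CNS014-15
exec/aneutreat generate-geometry --dn 3.11 --da 5.56 --out sac.stl
exec/aneutreat run-case --preset caseI --density 27 --out out/
```

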