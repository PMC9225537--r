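# silentsub

Silent-substitution stimulus design for melanopsin / ipRGC research.

Intrinsically photosensitive retinal ganglion cells (ipRGCs) respond to
light through their own photopigment, melanopsin, in addition to cone and
rod input.  Testing whether they influence color vision requires *metameric
ipRGC stimuli*: pairs of spectra with identical L-, M-, S-cone and rod
excitations but different melanopsin excitation.  Because the melanopsin
sensitivity overlaps all four other curves, such pairs cannot be built
wavelength by wavelength; `silentsub` builds them in function space, for a
multispectral projector whose output at each wavelength is bounded between
0 and 100 % of maximum drive.

The core construction: Gram–Schmidt orthogonalization of the five
sensitivities in the order L, M, S, rod, melanopsin gives basis functions
e₁…e₅ with

    [l m s r i] = [e1 e2 e3 e4 e5] α,   α upper triangular, unit diagonal.

Spectra are synthesized as p = ω₁e₁ + … + ω₅e₅.  Since e₅ is orthogonal to
l, m, s and r, the coefficient ω₅ modulates melanopsin excitation *only*.
Excitations are expressed in percent of the flat equal-energy white at 100
(every receptor sees that white at exactly 100).  On top of this the
package computes:

* the **feasible melanopsin interval** at any target cone+rod excitation
  under the device bounds (exact closed form);
* the **global modulation capacity** with and without rod matching (linear
  programs);
* a **chromaticity-plane gamut scan** with band classification and
  hue-group stimulus-point selection;
* **pentameric pairs** (all five excitations equal, spectra maximally
  different in the receptor null space);
* **colorimetric verification** (xy, CIELAB with a pluggable CMF table);
* **discrimination-experiment analysis** (rates, trends) with a synthetic
  response generator.

The bundled five-photoreceptor observer is a documented reconstruction
from public standard data (Judd/Vos-corrected CIE 1931 functions inverted
through the cone-fundamental XYZ transform, scotopic V′, a pigment-template
melanopic curve) — see `vignettes/melanopsin-metamer-design.Rmd` and
`inst/extdata/README.md` for provenance and accuracy.

## Worked example

Design the widest metameric ipRGC pair at a saturated orange chromaticity
whose cone and rod excitations are L = 47.9, M = 36.4, S = 5.86,
rod = 14.9 % of flat white:

```r
library(silentsub)
obs <- load_standard_observer()          # 380-780 nm @ 5 nm

build_basis(obs)$alpha |> round(4)
#>    L      M      S    rod  ipRGC
#> e1 1 0.8097 0.0549 0.4936 0.3130
#> e2 0 1.0000 0.2646 1.5087 1.2201
#> e3 0 0.0000 1.0000 0.4911 0.6184
#> e4 0 0.0000 0.0000 1.0000 1.1413
#> e5 0 0.0000 0.0000 0.0000 1.0000

feasible_iprgc_interval(obs, c(47.9, 36.4, 5.86, 14.9))
#> <feasible_interval: ipRGC in [9.773, 10.32] % (width 0.5472 %)>

design_metamer_pair(obs, c(47.9, 36.4, 5.86, 14.9), delta = "max")
#> <metamer_pair: delta ipRGC = 0.5472 %>
#>          L    M    S    R      I
#> max_i 47.9 36.4 5.86 14.9 10.321
#> min_i 47.9 36.4 5.86 14.9  9.773

max_metamer_range(obs)                   # best case anywhere in the gamut
#> <metamer_range: max delta ipRGC = 4.56 % (with rod matching, cap 100)>
```

Reading: at this chromaticity the device can move melanopsin excitation by
about 0.55 percentage points of the white-light level while cones and rods
see *exactly* the same stimulation (equal to 1e-8); near the white point
the ceiling rises to about 4.6 %.  The two spectra of the pair are ordinary
`spd` objects, exportable with `write_spectra_csv()` for the projector.

A thin command-line front end over the same functions ships as
`inst/cli/silentsub.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","silentsub.R",package="silentsub"))')" \
    design --L 47.9 --M 36.4 --S 5.86 --rod 14.9 --max --out pair.csv
```

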