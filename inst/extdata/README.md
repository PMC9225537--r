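# Bundled spectral tables

All tables use the spectra CSV dialect (`wavelength_nm` first, one column per
function, comma separated).

Transcribed standard data (10 nm tabulations):

- `cie1931_judd_vos_cmf_2deg_10nm.csv` — the CIE 1931 2° color-matching
  functions with the Judd (1951) correction to the luminosity curve and the
  Vos (1978) corrections to the deep-blue x̄ and z̄ values (380–450 nm);
  values above 450 nm are the unmodified 1931 tabulation.
- `scotopic_v_1951_10nm.csv` — the CIE 1951 scotopic luminosity function
  V′(λ).

Derived tables, generated by `tools/make_extdata.R` from the transcribed
tables and the reconstruction code in `R/observer-model.R` (the `synthetic`
suffix marks them as package reconstructions rather than official CIE
tabulations):

- `standard_observer_2deg_5nm_synthetic.csv` — the five photoreceptor
  sensitivities (L, M, S cone fundamentals recovered by inverting the
  cone-fundamental→XYZ transform on the corrected CMFs; rod = V′;
  melanopic ipRGC = Govardovskii A1 pigment template at 480 nm filtered by
  the ocular-media density derived from V′), energy units, peak-normalized,
  380–780 nm at 5 nm.
- `xyz_cmf_2deg_5nm_synthetic.csv` — XYZ color-matching functions obtained as
  the exact linear transform of the reconstructed cone fundamentals, so that
  cone-matched spectra are tristimulus-matched by construction.
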