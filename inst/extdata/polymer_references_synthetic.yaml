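# SYNTHETIC reference emission library for the five model polymers stained
# with the solvatochromic dye. The band positions/widths below are invented
# stand-ins: no published per-polymer emission maxima exist for this dye.
# They are chosen once to respect the qualitative constraints of the method:
#   - polyolefins (PP, LDPE, HDPE): two bands between 450 and 520 nm
#   - polar polymers (PS, PET): one band with its maximum above 520 nm,
#     PET the reddest and broadest
#   - polarity (dielectric constant) ordering PP -> LDPE/HDPE -> PS -> PET
#   - LDPE and HDPE nearly identical (minor differences in bulk spectra,
#     superimposed phasor clouds in images)
# Edit freely; centers must stay inside the acquisition axis.
- name: PP
  peaks:
    - {center: 455, sigma: 13, amplitude: 1.0}
    - {center: 485, sigma: 13, amplitude: 0.85}
  dielectric_range: [2.2, 2.5]
  display_color: blue
- name: LDPE
  peaks:
    - {center: 470, sigma: 14, amplitude: 1.0}
    - {center: 505, sigma: 14, amplitude: 0.8}
  dielectric_range: [2.2, 2.35]
  display_color: cyan
- name: HDPE
  peaks:
    - {center: 472, sigma: 14, amplitude: 1.0}
    - {center: 507, sigma: 14, amplitude: 0.85}
  dielectric_range: [2.3, 2.4]
  display_color: green
- name: PS
  peaks:
    - {center: 545, sigma: 35, amplitude: 1.0}
  dielectric_range: [2.4, 3.1]
  display_color: yellow
- name: PET
  peaks:
    - {center: 600, sigma: 55, amplitude: 1.0}
  dielectric_range: [3.0, 4.0]
  display_color: red
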