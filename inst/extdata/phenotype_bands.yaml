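# Default spectral band tables for the three middle-ear phenotypes.
# Amplitudes are dimensionless relative intensities (multiplied by
# band_scale counts at render time); centers and fwhm in cm^-1.
# Roles mark the apatite bands whose shape/strength follow the
# substitution degree of the mineral phase:
#   nu1_main     - phosphate nu1 at 960; fwhm broadens with substitution
#   nu3          - substituted-phosphate nu3 at 1044; grows with substitution
#   nu1_shoulder - nu1 component at 948; resolved only in the pure-apatite limit
version: 1
band_scale: 300
substitution_kappa: 1.5
baseline_coefficients: [1.0, 1.2, -1.4, 0.4]
phenotypes:
  cholesteatoma:
    baseline_scale: 400
    bands:
      - {center: 956,  amplitude: 0.25, fwhm: 14, shape: lorentzian}
      - {center: 1005, amplitude: 1.00, fwhm: 10, shape: lorentzian}
      - {center: 1032, amplitude: 0.45, fwhm: 12, shape: lorentzian}
      - {center: 1128, amplitude: 0.30, fwhm: 14, shape: lorentzian}
      - {center: 1447, amplitude: 0.90, fwhm: 18, shape: lorentzian}
      - {center: 1654, amplitude: 1.00, fwhm: 26, shape: gaussian}
      - {center: 1680, amplitude: 0.35, fwhm: 22, shape: gaussian}
  mineralized_myringosclerosis:
    baseline_scale: 350
    substitution_degree: 0.7
    bands:
      - {center: 748,  amplitude: 0.25, fwhm: 12, shape: lorentzian}
      - {center: 948,  amplitude: 0.35, fwhm: 7,  shape: lorentzian, role: nu1_shoulder}
      - {center: 960,  amplitude: 1.20, fwhm: 8,  shape: lorentzian, role: nu1_main}
      - {center: 1044, amplitude: 0.90, fwhm: 16, shape: lorentzian, role: nu3}
      - {center: 1447, amplitude: 0.20, fwhm: 18, shape: lorentzian}
      - {center: 1654, amplitude: 0.22, fwhm: 26, shape: gaussian}
  # collagen-dominated hyalinized membrane: same protein band set as
  # cholesteatoma at comparable overall intensity, but with the keratin
  # markers (phenylalanine 1005/1032, the 1680 amide-I shoulder) attenuated,
  # so the two non-mineralized pathologies differ only subtly relative to
  # the specimen-to-specimen amplitude variation
  nonmineralized_myringosclerosis:
    baseline_scale: 450
    bands:
      - {center: 956,  amplitude: 0.08,  fwhm: 14, shape: lorentzian}
      - {center: 1005, amplitude: 0.45,  fwhm: 10, shape: lorentzian}
      - {center: 1032, amplitude: 0.25,  fwhm: 12, shape: lorentzian}
      - {center: 1128, amplitude: 0.20,  fwhm: 14, shape: lorentzian}
      - {center: 1447, amplitude: 0.75,  fwhm: 18, shape: lorentzian}
      - {center: 1654, amplitude: 0.85,  fwhm: 26, shape: gaussian}
      # faint mineral traces at lesion margins, 5% of the mineralized
      # amplitudes
      - {center: 960,  amplitude: 0.060, fwhm: 10, shape: lorentzian}
      - {center: 1048, amplitude: 0.045, fwhm: 14, shape: lorentzian}
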