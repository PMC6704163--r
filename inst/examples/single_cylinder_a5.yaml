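# Single cylinder, a = 5 um, analytic scattering path.
# All quantities in SI units.
instrument:
  f1: 25.0e-3          # collimating lens focal length (m)
  f2: 36.0e-3          # focusing lens focal length (m)
  h: 3.5e-3            # aperture radius (m)
  n_med: 1.35          # background refractive index
  w0: 4.6e-6           # half fiber mode-field diameter (m)
  lambda0: 1.3e-6      # central vacuum wavelength (m)
  delta_lambda: 170.0e-9   # FWHM bandwidth (m)
  epsilon: 1.0e-3      # spectral cut-off
  n_wavenumbers: 160   # must be even
scene:
  type: single_cylinder
  radius: 5.0e-6
  n_cyl: 1.42
  n_med: 1.35
  center: [0.0, 0.0]
solver:
  path: analytic       # analytic | grid
scan:
  y_from: -12.0e-6
  y_to: 12.0e-6
  n_positions: 9
  polarisation: perpendicular
output:
  dir: octsim_out
  formats: [csv, json]
  scale: log
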