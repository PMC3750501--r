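# Sensor case study: five-state transcriptional sensor construct under a
# rectangular inhibitor pulse, with two weighted squared-deviation features
# (monomer and dimer) and designable binding rates k7 and k9.
#
# Window placement and target values follow the qualitative behavioral
# intent of the construct -- the dimer should drop to a low level while the
# inhibitor is present and recover to a high level after washout, with the
# monomer constrained alongside -- and are reconstructions shipped with this
# package, not literature values. Feature units are nM^2*sec.
model:
  type: sensor
  x5_total: 10          # total promoter concentration, nM
  horizon: 600          # seconds
  rtol: 1.0e-8
  atol: 1.0e-10
  n_grid: 400
  x0: steady_state      # relax the inhibitor-free system, then pulse
  input:                # inhibitor y(t): 100 nM on [100, 300) s
    breakpoints: [0, 100, 300]
    levels: [0, 100, 0]
spec:
  features:
    - species: x2       # protein monomer: long constraint intervals
      windows: [[180, 230], [400, 450]]
      targets: [10, 10]
    - species: x3       # dimer: brief checkpoints ("drops fast, recovers fast")
      windows: [[180, 185], [400, 405]]
      targets: [5, 100]
algorithm:
  design_parameters: [k7, k9]
  eps: 150              # reverse-forward error tolerance, nM^2*sec
  region:               # specification box S around the nominal features
    lo: [1040, 2500]
    hi: [1160, 3500]
  max_balls: 50
  coverage_target: 0.98
  n_mc: 100000
  rho:
    n_delta: 4
    n_samples: 20
  seed: 1
output:
  directory: specmap_out
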