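# Default study configuration: species masses/lifespans, human tissue
# stem-cell parameters, calibration target and anchor, MR scaling exponents.
p_target: 0.01
u_anchor: 1.0e-05
M_max: 10
betas: [0.0, -0.15, -0.3]
reference_species: human
baseline_species: mouse
target_species: [human, whale]
species:
  mouse:
    weight: 0.02
    lifespan: 2.0
  human:
    weight: 60.0
    lifespan: 80.0
  whale:
    weight: 150000.0
    lifespan: 90.0
tissues:
  colorectal:
    cells: 2.0e+08
    divisions_per_year: 73.0
  hepatocellular:
    cells: 3.01e+08
    divisions_per_year: 0.9125
  esophageal:
    cells: 6.6528e+06
    divisions_per_year: 33.2
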