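# Receptor analysis presets: residue spans, kink pivots and the standard
# two-helix starting-orientation table (d_HH in nm, angles in degrees).
IR:
  residues: {first: 940, last: 988}
  dhh_span: {first: 953, last: 979}
  tilt_span: {first: 957, last: 979}
  membrane_span: {first: 953, last: 979}
  kink_pivot: 960
IGF1R:
  residues: {first: 919, last: 967}
  dhh_span: {first: 937, last: 959}
  tilt_span: {first: 937, last: 959}
  membrane_span: {first: 937, last: 959}
  kink_pivot: 941
orientations:
  O1: {dhh: 7.2, theta: 45, omega: 0}
  O2: {dhh: 3.5, theta: 45, omega: 0}
  O3: {dhh: 2.4, theta: 45, omega: 45}
  O4: {dhh: 3.5, theta: 45, omega: 0}
  O5: {dhh: 3.1, theta: 0, omega: 0}
# recorded system sizes (atoms) per orientation O1..O5; metadata only,
# solvent packing is not modelled here
system_sizes:
  IR: [50822, 51159, 50330, 50895, 48940]
  IGF1R: [58464, 58403, 58408, 58459, 58505]
# three independent 10-us replicates per system
production_us_per_system: 30
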