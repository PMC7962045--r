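# Default lesion-detectability experiment: layered foot + insole + shoe slab,
# six lesion centre depths, both lesion types, sock on/off.
# Thicknesses and depths in mm (see `units`), everything else SI; temperatures degC.
units:
  thickness: mm

grid:
  footprint: [0.26, 0.09]   # m
  dx: 0.002                 # m
  z_refine: 1

layers:                     # top (deep tissue) first
  - {material: muscle,           thickness: 25,    n_cells: 12, grading: 0.78}
  - {material: fat,              thickness: 5,     n_cells: 6}
  - {material: reticular_dermis, thickness: 1.67,  n_cells: 3}
  - {material: papillary_dermis, thickness: 1.67,  n_cells: 3}
  - {material: epidermis,        thickness: 0.46,  n_cells: 3}
  - {material: polyurethane,     thickness: 1,     n_cells: 3}
  - {material: kapton,           thickness: 0.36,  n_cells: 3}
  - {material: copper,           thickness: 0.018, n_cells: 3}
  - {material: polyurethane,     thickness: 3,     n_cells: 4}
  - {material: rubber,           thickness: 15,    n_cells: 5}

blood:
  density: 1050             # kg/m3
  specific_heat: 3617       # J/kg/K

boundary:
  floor_h: 5                # W/m2/K
  floor_T_env: 20           # degC
  sock_resistance: 0.02     # m2K/W
  sock: [true, false]

lesion:
  depths: [1.6, 2.6, 3.4, 5.9, 8.4, 9.7]   # mm below the skin surface
  types: [inflammation, ischemia]
  height: 2.5               # mm
  volume: 1.5e-6            # m3

sensors:
  threshold: 0.1            # degC
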