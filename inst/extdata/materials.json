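{
  "LiNbO3_36YX_isotropic": {
    "kind": "rigid_solid",
    "density": 4650,
    "shear_modulus": 86.3e9,
    "comment": "Lithium niobate 36Y-X substrate, isotropic shear-equivalent constants"
  },
  "Cr": {
    "kind": "rigid_solid",
    "density": 7190,
    "shear_modulus": 115e9,
    "comment": "Chromium adhesion layer (10 nm in the reference device)"
  },
  "Au": {
    "kind": "rigid_solid",
    "density": 19300,
    "shear_modulus": 28.5e9,
    "comment": "Gold metallization (165 nm in the reference device)"
  },
  "SU8": {
    "kind": "viscoelastic_solid",
    "density": 1100,
    "shear_modulus": 1.21e9,
    "viscosity": 0.12,
    "comment": "SU-8 polymer guiding layer; viscosity at 30 MHz is an approximation (little literature data), treat as a default"
  },
  "SU8_elastic": {
    "kind": "rigid_solid",
    "density": 1100,
    "shear_modulus": 1.21e9,
    "comment": "Lossless SU-8 variant for lossless dispersion scans"
  },
  "water_25C": {
    "kind": "newtonian_liquid",
    "density": 997,
    "viscosity": 0.893e-3,
    "comment": "Deionized water at 25 degC (0.893 cP)"
  },
  "glycerol_1.8cP": {
    "kind": "newtonian_liquid",
    "density": 1058.2,
    "viscosity": 1.8e-3,
    "comment": "25.2% w/w glycerol-water at 25 degC"
  },
  "glycerol_2.5cP": {
    "kind": "newtonian_liquid",
    "density": 1082,
    "viscosity": 2.5e-3,
    "comment": "34.4% w/w glycerol-water at 25 degC"
  },
  "glycerol_3.3cP": {
    "kind": "newtonian_liquid",
    "density": 1100,
    "viscosity": 3.3e-3,
    "comment": "41.2% w/w glycerol-water at 25 degC"
  },
  "glycerol_4cP": {
    "kind": "newtonian_liquid",
    "density": 1111.4,
    "viscosity": 4e-3,
    "comment": "45.44% w/w glycerol-water at 25 degC"
  },
  "vacuum": {
    "kind": "vacuum",
    "comment": "Zero-impedance top termination (air baseline)"
  }
}
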