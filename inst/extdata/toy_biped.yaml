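taxon: toy_biped
body_mass: 68.33
gravity: 9.81
sim:
  dt: 0.001
  integrator: semi_implicit
  record_dt: 0.002
muscle_defaults:
  se_strain_at_fmax: 0.08
segments:
- name: hat
  shape:
    type: cuboid
    length: 0.9
    width: 0.3
    depth: 0.20186379085
  density: 850.0
  com_offset: 0.45
- name: thigh
  shape:
    type: cylinder
    length: 0.4
    radius: 0.10428354262
  density: 1000.0
- name: shank
  shape:
    type: cylinder
    length: 0.4
    radius: 0.071111895113
  density: 1000.0
- name: foot
  shape:
    type: cuboid
    length: 0.25
    width: 0.132
    depth: 0.060047575758
  density: 1000.0
joints:
- name: hip
  parent: hat
  child: thigh
  anchor:
  - 0.0
  - 0.0
  offset_deg: 180.0
  angle_lo: -25.0
  angle_hi: 135.0
  soft_limit_stiffness: 300.0
  soft_limit_damping: 10.0
  extension_sign: -1.0
- name: knee
  parent: thigh
  child: shank
  anchor:
  - 0.4
  - 0.0
  offset_deg: 0.0
  angle_lo: -150.0
  angle_hi: 3.0
  soft_limit_stiffness: 300.0
  soft_limit_damping: 10.0
  extension_sign: 1.0
- name: ankle
  parent: shank
  child: foot
  anchor:
  - 0.4
  - 0.0
  offset_deg: 90.0
  angle_lo: -50.0
  angle_hi: 35.0
  soft_limit_stiffness: 200.0
  soft_limit_damping: 5.0
  extension_sign: -1.0
actuators:
- name: hip ext
  path:
    anchors:
    - segment: hat
      pos:
      - 0.05
      - 0.055
    - segment: thigh
      pos:
      - 0.12
      - -0.035
    wraps:
    - after: 1.0
      segment: thigh
      centre:
      - 0.0
      - 0.0
      radius: 0.062
      direction: 1.0
  fl: 100.0
  pcsa: 1000.0
  vmax: 8.4
  region: proximal
  actions:
  - joint: hip
    role: extensor
- name: hip flx
  path:
    anchors:
    - segment: hat
      pos:
      - 0.06
      - -0.05
    - segment: thigh
      pos:
      - 0.1
      - 0.025
    wraps:
    - after: 1.0
      segment: thigh
      centre:
      - 0.0
      - 0.0
      radius: 0.04
      direction: 1.0
  fl: 100.0
  pcsa: 1000.0
  vmax: 8.4
  region: proximal
  actions:
  - joint: hip
    role: flexor
- name: knee ext
  path:
    anchors:
    - segment: thigh
      pos:
      - 0.12
      - 0.03
    - segment: thigh
      pos:
      - 0.33
      - 0.045
    - segment: shank
      pos:
      - 0.07
      - 0.025
    wraps:
    - after: 2.0
      segment: shank
      centre:
      - 0.0
      - 0.0
      radius: 0.045
      direction: -1.0
  fl: 100.0
  pcsa: 1000.0
  vmax: 8.4
  region: proximal
  actions:
  - joint: knee
    role: extensor
- name: knee flx
  path:
    anchors:
    - segment: thigh
      pos:
      - 0.12
      - -0.03
    - segment: thigh
      pos:
      - 0.33
      - -0.04
    - segment: shank
      pos:
      - 0.08
      - -0.02
    wraps:
    - after: 2.0
      segment: shank
      centre:
      - 0.0
      - 0.0
      radius: 0.035
      direction: 1.0
  fl: 100.0
  pcsa: 1000.0
  vmax: 8.4
  region: proximal
  actions:
  - joint: knee
    role: flexor
- name: ankle ext
  path:
    anchors:
    - segment: shank
      pos:
      - 0.11
      - -0.03
    - segment: shank
      pos:
      - 0.37
      - -0.035
    - segment: foot
      pos:
      - -0.07
      - -0.03
    wraps:
    - after: 2.0
      segment: foot
      centre:
      - 0.0
      - 0.0
      radius: 0.05
      direction: 1.0
  fl: 100.0
  pcsa: 1000.0
  vmax: 8.4
  region: proximal
  actions:
  - joint: ankle
    role: extensor
- name: ankle flx
  path:
    anchors:
    - segment: shank
      pos:
      - 0.11
      - 0.03
    - segment: shank
      pos:
      - 0.37
      - 0.033
    - segment: foot
      pos:
      - 0.07
      - 0.02
    wraps:
    - after: 2.0
      segment: foot
      centre:
      - 0.0
      - 0.0
      radius: 0.035
      direction: 1.0
  fl: 100.0
  pcsa: 1000.0
  vmax: 8.4
  region: proximal
  actions:
  - joint: ankle
    role: flexor
contacts:
- segment: foot
  local_pos:
  - -0.12
  - -0.08
  stiffness: 30000.0
  damping: 1200.0
  friction_mu: 1.0
- segment: foot
  local_pos:
  - 0.18
  - -0.08
  stiffness: 30000.0
  damping: 1200.0
  friction_mu: 1.0
bone_sections:
- segment: thigh
  pos: 0.5
  area: 0.001061858317
  second_moment: 4.486351388959e-08
  c: 0.013
  failure_stress: 300000000.0
- segment: shank
  pos: 0.5
  area: 0.000904778684
  second_moment: 3.257203263242e-08
  c: 0.012
  failure_stress: 300000000.0
starting_pose:
  hip: 114.0
  knee: -95.0
  ankle: 11.0
tendon_reference_pose:
  hip: 67.0
  knee: -58.0
  ankle: 6.0
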