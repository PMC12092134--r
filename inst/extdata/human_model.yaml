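taxon: human
body_mass: 68.33
gravity: 9.81
sim:
  dt: 0.0001
  integrator: semi_implicit
  record_dt: 0.001
segments:
- name: hat
  shape:
    type: cuboid
    length: 0.9
    width: 0.3
    depth: 0.20186379085
  density: 850.0
  com_offset: 0.42
- name: thigh
  shape:
    type: cylinder
    length: 0.43
    radius: 0.100579979798
  density: 1000.0
- name: shank
  shape:
    type: cylinder
    length: 0.43
    radius: 0.068586401979
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
  - 0.43
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
  - 0.43
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
  fl: 172.295
  pcsa: 11069.165999999999
  vmax: 8.4
  region: proximal
  actions:
  - joint: hip
    role: extensor
- name: hip ext knee flx
  path:
    anchors:
    - segment: hat
      pos:
      - 0.08
      - 0.07
    - segment: thigh
      pos:
      - 0.06
      - -0.04
    - segment: thigh
      pos:
      - 0.36
      - -0.045
    - segment: shank
      pos:
      - 0.07
      - -0.02
    wraps:
    - after: 1.0
      segment: thigh
      centre:
      - 0.0
      - 0.0
      radius: 0.055
      direction: 1.0
    - after: 3.0
      segment: shank
      centre:
      - 0.0
      - 0.0
      radius: 0.035
      direction: 1.0
  fl: 123.632
  pcsa: 12889.441999999999
  vmax: 8.4
  region: proximal
  actions:
  - joint: hip
    role: extensor
  - joint: knee
    role: flexor
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
  fl: 45.389
  pcsa: 66870.271999999997
  vmax: 8.4
  region: proximal
  actions:
  - joint: hip
    role: flexor
- name: hip flx knee ext
  path:
    anchors:
    - segment: hat
      pos:
      - 0.06
      - -0.05
    - segment: thigh
      pos:
      - 0.06
      - 0.035
    - segment: thigh
      pos:
      - 0.36
      - 0.045
    - segment: shank
      pos:
      - 0.07
      - 0.025
    wraps:
    - after: 1.0
      segment: thigh
      centre:
      - 0.0
      - 0.0
      radius: 0.04
      direction: 1.0
    - after: 3.0
      segment: shank
      centre:
      - 0.0
      - 0.0
      radius: 0.045
      direction: -1.0
  fl: 138.213
  pcsa: 3827.462
  vmax: 8.4
  region: proximal
  actions:
  - joint: hip
    role: flexor
  - joint: knee
    role: extensor
- name: knee ext
  path:
    anchors:
    - segment: thigh
      pos:
      - 0.12
      - 0.03
    - segment: thigh
      pos:
      - 0.36
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
  fl: 129.079
  pcsa: 27844.450000000001
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
      - 0.36
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
  fl: 108.875
  pcsa: 2908.142
  vmax: 8.4
  region: proximal
  actions:
  - joint: knee
    role: flexor
- name: knee flx ankle ext
  path:
    anchors:
    - segment: thigh
      pos:
      - 0.38
      - -0.035
    - segment: shank
      pos:
      - 0.05
      - -0.03
    - segment: shank
      pos:
      - 0.4
      - -0.035
    - segment: foot
      pos:
      - -0.07
      - -0.03
    wraps:
    - after: 1.0
      segment: shank
      centre:
      - 0.0
      - 0.0
      radius: 0.035
      direction: 1.0
    - after: 3.0
      segment: foot
      centre:
      - 0.0
      - 0.0
      radius: 0.05
      direction: 1.0
  fl: 59.142
  pcsa: 15783.505999999999
  vmax: 8.4
  region: distal
  actions:
  - joint: knee
    role: flexor
  - joint: ankle
    role: extensor
- name: ankle ext
  path:
    anchors:
    - segment: shank
      pos:
      - 0.12
      - -0.03
    - segment: shank
      pos:
      - 0.4
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
  fl: 50.426
  pcsa: 33356.034
  vmax: 8.4
  region: distal
  actions:
  - joint: ankle
    role: extensor
- name: ankle flx
  path:
    anchors:
    - segment: shank
      pos:
      - 0.12
      - 0.03
    - segment: shank
      pos:
      - 0.4
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
  fl: 28.742
  pcsa: 13195.838
  vmax: 8.4
  region: distal
  actions:
  - joint: ankle
    role: flexor
contacts:
- segment: foot
  local_pos:
  - -0.1
  - -0.08
  stiffness: 60000.0
  damping: 2000.0
  friction_mu: 1.0
- segment: foot
  local_pos:
  - 0.18
  - -0.08
  stiffness: 60000.0
  damping: 2000.0
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
  hip: 10.0
  knee: 0.0
  ankle: -5.0
tendon_reference_pose:
  hip: 67.0
  knee: -58.0
  ankle: 6.0
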