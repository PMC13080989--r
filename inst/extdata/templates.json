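[
  {
    "name": "linear_1",
    "arrangement": "two_linear",
    "symmetric_required": false,
    "slots": [
      {"position": 0, "accepts": "binding_group", "constraints": {}},
      {"position": 1, "accepts": "linker", "constraints": {"linear": true, "cyclic": true}},
      {"position": 2, "accepts": "binding_group", "constraints": {}}
    ]
  },
  {
    "name": "linear_2",
    "arrangement": "two_linear",
    "symmetric_required": false,
    "slots": [
      {"position": 0, "accepts": "binding_group", "constraints": {}},
      {"position": 1, "accepts": "linker", "constraints": {"linear": true}},
      {"position": 2, "accepts": "linker", "constraints": {"linear": true}},
      {"position": 3, "accepts": "binding_group", "constraints": {}}
    ]
  },
  {
    "name": "linear_3",
    "arrangement": "two_linear",
    "symmetric_required": false,
    "slots": [
      {"position": 0, "accepts": "binding_group", "constraints": {}},
      {"position": 1, "accepts": "linker", "constraints": {"linear": true, "cyclic": true}},
      {"position": 2, "accepts": "linker", "constraints": {"linear": true, "max_atoms": 12}},
      {"position": 3, "accepts": "linker", "constraints": {"linear": true, "cyclic": true}},
      {"position": 4, "accepts": "binding_group", "constraints": {}}
    ]
  },
  {
    "name": "linear_2_acyclic_core",
    "arrangement": "two_linear",
    "symmetric_required": false,
    "slots": [
      {"position": 0, "accepts": "binding_group", "constraints": {}},
      {"position": 1, "accepts": "linker", "constraints": {"linear": true, "cyclic": true}},
      {"position": 2, "accepts": "linker", "constraints": {"linear": true, "cyclic": false}},
      {"position": 3, "accepts": "binding_group", "constraints": {}}
    ]
  },
  {
    "name": "bent_1",
    "arrangement": "two_bent",
    "symmetric_required": false,
    "slots": [
      {"position": 0, "accepts": "binding_group", "constraints": {}},
      {"position": 1, "accepts": "linker", "constraints": {"linear": false}},
      {"position": 2, "accepts": "binding_group", "constraints": {}}
    ]
  },
  {
    "name": "bent_3",
    "arrangement": "two_bent",
    "symmetric_required": false,
    "slots": [
      {"position": 0, "accepts": "binding_group", "constraints": {}},
      {"position": 1, "accepts": "linker", "constraints": {"linear": true, "cyclic": true}},
      {"position": 2, "accepts": "linker", "constraints": {"linear": false}},
      {"position": 3, "accepts": "linker", "constraints": {"linear": true, "cyclic": true}},
      {"position": 4, "accepts": "binding_group", "constraints": {}}
    ]
  },
  {
    "name": "planar_0",
    "arrangement": "three_planar",
    "symmetric_required": false,
    "slots": [
      {"position": 0, "accepts": "binding_group", "constraints": {}},
      {"position": 1, "accepts": "node", "constraints": {}}
    ]
  },
  {
    "name": "planar_1",
    "arrangement": "three_planar",
    "symmetric_required": false,
    "slots": [
      {"position": 0, "accepts": "binding_group", "constraints": {}},
      {"position": 1, "accepts": "linker", "constraints": {"linear": true, "cyclic": true}},
      {"position": 2, "accepts": "node", "constraints": {}}
    ]
  }
]
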