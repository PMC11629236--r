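{
  "id": "toy_chain",
  "reactions": [
    {
      "id": "step1",
      "metabolites": {
        "A_e": -1,
        "t1": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "objective_coefficient": 0,
      "notes": {
        "origin": "annotation"
      }
    },
    {
      "id": "step3",
      "metabolites": {
        "t2": -1,
        "t3": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "objective_coefficient": 0,
      "notes": {
        "origin": "annotation"
      }
    },
    {
      "id": "step4",
      "metabolites": {
        "t3": -1,
        "t4": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "objective_coefficient": 0,
      "notes": {
        "origin": "annotation"
      }
    },
    {
      "id": "EX_A",
      "metabolites": {
        "A_e": -1
      },
      "lower_bound": -10,
      "upper_bound": 1000,
      "objective_coefficient": 0,
      "notes": {
        "origin": "annotation"
      }
    },
    {
      "id": "bio1",
      "metabolites": {
        "t4": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "objective_coefficient": 1,
      "notes": {
        "origin": "annotation"
      }
    }
  ],
  "metabolites": [
    {
      "id": "A_e",
      "compartment": "c"
    },
    {
      "id": "t1",
      "compartment": "c"
    },
    {
      "id": "t2",
      "compartment": "c"
    },
    {
      "id": "t3",
      "compartment": "c"
    },
    {
      "id": "t4",
      "compartment": "c"
    }
  ]
}
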