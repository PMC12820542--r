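{
  "TAM": {
    "label": "Technology Acceptance Model",
    "edges": [
      ["performance expectancy", "attitude"],
      ["effort expectancy", "attitude"],
      ["attitude", "behavioral intention"],
      ["performance expectancy", "behavioral intention"],
      ["behavioral intention", "actual behavior"],
      ["effort expectancy", "performance expectancy"]
    ]
  },
  "UTAUT": {
    "label": "Unified Theory of Acceptance and Use of Technology",
    "edges": [
      ["performance expectancy", "behavioral intention"],
      ["effort expectancy", "behavioral intention"],
      ["social influence", "behavioral intention"],
      ["facilitating conditions", "behavioral intention"],
      ["hedonic motivation", "behavioral intention"],
      ["habit", "behavioral intention"],
      ["financial cost", "behavioral intention"],
      ["facilitating conditions", "actual behavior"],
      ["social influence", "actual behavior"],
      ["behavioral intention", "actual behavior"]
    ]
  },
  "HBM+PMT": {
    "label": "Health Belief Model and Protection Motivation Theory",
    "edges": [
      ["perceived severity", "behavioral intention"],
      ["perceived vulnerability", "behavioral intention"],
      ["benefits", "behavioral intention"],
      ["barriers", "behavioral intention"],
      ["self-efficacy", "behavioral intention"],
      ["performance expectancy", "behavioral intention"],
      ["health", "behavioral intention"],
      ["health consciousness", "behavioral intention"],
      ["health consciousness", "actual behavior"]
    ]
  },
  "TTF": {
    "label": "Task-Technology Fit",
    "edges": [
      ["task characteristics", "task-technology fit"],
      ["technology characteristics", "task-technology fit"],
      ["task-technology fit", "performance expectancy"]
    ]
  },
  "PCT": {
    "label": "Privacy Calculus Theory",
    "edges": [
      ["trust", "behavioral intention"],
      ["privacy and security", "behavioral intention"]
    ]
  },
  "TPB": {
    "label": "Theory of Planned Behavior",
    "edges": [
      ["attitude", "behavioral intention"],
      ["social influence", "behavioral intention"],
      ["self-efficacy", "behavioral intention"],
      ["behavioral intention", "actual behavior"]
    ]
  },
  "DOI": {
    "label": "Diffusion of Innovation",
    "edges": [
      ["performance expectancy", "behavioral intention"],
      ["effort expectancy", "behavioral intention"],
      ["compatibility", "behavioral intention"],
      ["image", "behavioral intention"],
      ["trialability", "behavioral intention"],
      ["observability", "behavioral intention"]
    ]
  }
}
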