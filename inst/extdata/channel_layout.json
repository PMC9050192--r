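{
  "description": "Channel layout of population-coded gridworld observations.",
  "grid_size": 7,
  "features_per_cell": 12,
  "total_channels": 588,
  "index_formula": "((row - 1) * 7 + (col - 1)) * 12 + feature, 1-based",
  "cell_features": {
    "1": "wall present in this cell (absolute)",
    "2": "observer's own goal is in this cell (absolute)",
    "3": "cell is occluded from the observer's viewpoint (absolute)",
    "4": "egocentric marker: goal bearing (goal offset from self, clipped, centre 4,4) in observations; blocked-move flag at the centre in egocentric state encodings",
    "5": "agent slot 1: the observing agent itself (absolute)",
    "6": "agent slot 2: first other agent, ascending id (absolute)",
    "7": "agent slot 3: second other agent (absolute)",
    "8": "agent slot 4 (absolute)",
    "9": "agent slot 5 (absolute)",
    "10": "agent slot 6 (absolute)",
    "11": "first other agent, offset relative to self (clipped, centre 4,4)",
    "12": "second other agent, offset relative to self (clipped, centre 4,4)"
  },
  "style_channels": {
    "length": 18,
    "populations": {
      "reckless": "1-6",
      "experienced": "7-12",
      "cautious": "13-18"
    }
  },
  "action_populations": {
    "order": [
      "up",
      "down",
      "left",
      "right",
      "stay"
    ],
    "neurons_per_population": 6
  },
  "policy_inference_input": {
    "length": 14,
    "1-2": "previous style estimate: reckless",
    "3-4": "previous style estimate: experienced",
    "5-6": "previous style estimate: cautious",
    "7": "moved toward goal",
    "8": "deviated from the shortest-path step",
    "9": "moved away from nearest wall",
    "10": "within one cell of a wall",
    "11": "avoided goal-ward occupied cell",
    "12": "stayed in place",
    "13": "last safety estimate: unsafe",
    "14": "last safety estimate: safe"
  },
  "egocentric_state_encoding": {
    "note": "Same 7x7x12 layout, but cells are relative offsets -3..+3 around the focal agent (centre cell 4,4); out-of-window agents are dropped and out-of-grid cells are marked as walls."
  }
}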