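{
  "nodes": ["humidity", "laryngeal_desiccation", "production_cost",
            "token_frequency", "cultural_diffusion", "tone_inventory"],
  "edges": [["humidity", "laryngeal_desiccation"],
            ["laryngeal_desiccation", "production_cost"],
            ["production_cost", "token_frequency"],
            ["token_frequency", "cultural_diffusion"],
            ["cultural_diffusion", "tone_inventory"]]
}
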