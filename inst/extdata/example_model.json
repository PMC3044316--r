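{
  "model_id": "case1_original",
  "entities": [
    {
      "id": "raf1",
      "class": "Protein",
      "displayName": "Raf1",
      "featureTypes": [],
      "xrefs": ["TRANSPATH:MO_RAF1"],
      "components": []
    },
    {
      "id": "raf1_active",
      "class": "Protein",
      "displayName": "Raf1{active}",
      "featureTypes": ["FT_Active"],
      "xrefs": ["TRANSPATH:MO_RAF1"],
      "components": []
    },
    {
      "id": "ras_active",
      "class": "Protein",
      "displayName": "Ras{active}",
      "featureTypes": ["FT_Active"],
      "xrefs": ["TRANSPATH:MO_RAS"],
      "components": []
    }
  ],
  "processes": [
    {
      "id": "p_activation",
      "biologicalEvent": "ME_UnknownActivation",
      "displayName": "Raf1 activation"
    }
  ],
  "connectors": [
    {
      "id": "c_raf1_in",
      "role": "InputProcessBiological",
      "process": "p_activation",
      "entity": "raf1",
      "stoichiometry": 1
    },
    {
      "id": "c_raf1_out",
      "role": "OutputProcessBiological",
      "process": "p_activation",
      "entity": "raf1_active",
      "stoichiometry": 1
    },
    {
      "id": "c_ras_in",
      "role": "InputProcessBiological",
      "process": "p_activation",
      "entity": "ras_active",
      "stoichiometry": 1
    }
  ]
}
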