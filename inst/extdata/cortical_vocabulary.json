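{
  "comment": "Controlled vocabulary for cortical aligned aliases. Editable: the naming convention is a starting point, not a closed standard.",
  "layers": ["L1", "L2", "L3", "L4", "L5", "L6", "L6b",
             "L2/3", "L3/4", "L4/5", "L5/6", "L6/6b"],
  "projections": ["IT", "ET", "CT", "NP"],
  "projection_aliases": {"CF": "ET", "PT": "ET"},
  "genes": ["Pvalb", "Sst", "Vip", "Sncg", "Lamp5", "Chodl", "Calb2",
            "Chat", "Ndnf", "Pax6", "Meis2", "Serpinf1", "Th"],
  "classes": ["Microglia", "Astrocyte", "Astro", "Oligodendrocyte", "Oligo",
              "OPC", "Endothelial", "Endo", "VLMC", "Pericyte", "Peri",
              "SMC", "PVM", "Glutamatergic", "GABAergic", "Non-neuronal"],
  "historical": ["Chandelier", "Rosehip", "Martinotti", "Basket",
                 "Neurogliaform", "Pyramidal", "Double bouquet",
                 "Von Economo", "Meyer"]
}
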