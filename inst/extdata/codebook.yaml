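# Example codebook: maps observed survey-export spellings to the
# canonical vocabulary. Top-level keys are field names.
group:
  "Sahouè": Sahoue
  "Wémé": Weme
  "Ga Adangbe": Ga-adangbe
category:
  "Magico-spiritual": magico_spiritual
  "Medicines": medicinal
plant_part:
  "Fruits": fruit
  "Leaves": leaf
  "Twigs": twig
schooling:
  "No-schooling": none
  ">Bac": university
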