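# Gestation lengths (days) from standard comparative references; override
# any entry by supplying your own config to species_config().
gestation_days:
  human: 270
  chimpanzee: 228
  bonobo: 230
  gorilla: 257
  orangutan: 245
  gibbon: 210
  siamang: 232
  rhesus_macaque: 165
  marmoset: 144
organoid_offset_days: 0
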