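# Neurotransmitter-type neuron markers (teleost brain), paralogs listed
# as separate gene ids within one type.
panel_name: neurotransmitter_neurons
entries:
  glutamatergic: [slc17a6a, slc17a6b]
  GABAergic: [gad1, gad2]
  glycinergic: [slc6a5]
  dopaminergic: [th, th2]
  serotonergic: [tph2]
  noradrenergic: [dbh, dbh-like]
  cholinergic: [chata, chata-like]
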