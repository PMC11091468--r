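# Non-neuronal cell-type markers; "-1"/"-2" distinguish duplicate
# annotations carrying the same name.
panel_name: nonneuronal_cells
entries:
  oligodendrocytes: [olig2, sox10-1, sox10-2]
  microglia: [apoeb, mpeg1-1, mpeg1-2]
  endothelial: [rbp4]
  radial_astrocytes: [cx43]
  neuroprogenitors: [pcna-1, pcna-2]
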