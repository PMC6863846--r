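parameter,brazil,study_area,nbz,bz5
area_km2,8515767,4893045,318126,541533
n_records,1502484,1170795,111108,209174
n_taxa,34388,28818,9592,13174
n_endemics,18639,17610,468,1098
max_cell_richness,5182,5108,1783,3115
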