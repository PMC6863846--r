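dataset,total_names,backbone,synonymous,shared,not_found
bien_v3.4.5,34388,WC,5708,26916,1732
bien_v3.4.5,34388,FB2020,5004,24797,4380
bien_v4,52526,WC,10914,36478,5063
bien_v4,52526,FB2020,8642,29962,13523
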