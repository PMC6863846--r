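keyword,class
calcario,carbonate
calcário,carbonate
calcaria,carbonate
calcária,carbonate
calcareo,carbonate
calcáreo,carbonate
calcarea,carbonate
calcárea,carbonate
calcareous,carbonate
caliza,carbonate
limestone,carbonate
dolomito,carbonate
dolomite,carbonate
carste,carbonate
karst,carbonate
carstica,carbonate
cárstica,carbonate
carstico,carbonate
cárstico,carbonate
dolina,doline
doline,doline
cave,cave
caverna,cave
gruta,cave
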