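token,expansion,source_note
Ant.,Antarctic or Subantarctic,abbreviation list
Atl.,Atlantic,abbreviation list
IP,Indo Pacific,abbreviation list
IWP,Indo-West Pacific,abbreviation list
Pac.,Pacific,abbreviation list
SubAnt,Subantarctic,abbreviation list
Cosmopolitan,All three oceans as well as Subantarctic and/or Antarctic,abbreviation list
N. Atl.,North Atlantic,compass prefix + Atl.
E. Atl.,Eastern Atlantic,compass prefix + Atl.
W. Atl.,Western Atlantic,compass prefix + Atl.
SE Atl.,Southeastern Atlantic,compass prefix + Atl.
SW Atl.,Southwestern Atlantic,compass prefix + Atl.
E. Pac.,Eastern Pacific,compass prefix + Pac.
W. Pac.,Western Pacific,compass prefix + Pac.
SW Pac.,Southwestern Pacific,compass prefix + Pac.
New Zealand,New Zealand,place name printed in key
Indian,Indian Ocean,place name printed in key
S. Africa,South Africa,place name printed in key
Galapagos,Galapagos Islands,place name printed in bibliography
I–P,Indo Pacific,variant of IP
IWP.,Indo-West Pacific,variant of IWP
Subant.,Subantarctic,variant of SubAnt
SW. Pac.,Southwestern Pacific,variant of SW Pac.
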