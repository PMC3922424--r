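name,hemisphere,x,y,z,network,is_language
Br,L,-27,15,3,left-lateralized,TRUE
We,L,-27,-21,6,left-lateralized,TRUE
PC,L,-9,-27,12,left-lateralized,FALSE
MP,L,-9,27,9,left-lateralized,FALSE
TP,L,-33,-33,9,left-lateralized,FALSE
LP,L,-21,9,18,left-lateralized,FALSE
l-S,L,-9,3,21,left-lateralized,FALSE
MT,L,-33,-9,-6,left-lateralized,FALSE
SF,L,-9,15,18,left-lateralized,FALSE
AI,R,27,9,0,right-lateralized,FALSE
Bh,R,27,15,3,right-lateralized,FALSE
DL,R,21,21,12,right-lateralized,FALSE
DP,R,27,27,6,right-lateralized,FALSE
FE,R,15,3,18,right-lateralized,FALSE
IP,R,9,-33,15,right-lateralized,FALSE
LI,R,21,-27,12,right-lateralized,FALSE
MC,R,3,3,15,right-lateralized,FALSE
MI,R,21,-3,3,right-lateralized,FALSE
PO,R,9,-27,-9,right-lateralized,FALSE
r-S,R,9,3,21,right-lateralized,FALSE
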