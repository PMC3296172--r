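strain_id	species	role
3146.1	D. lini	focal
DHS315	D. lini	focal
DHS410	D. lini	focal
DHS501	D. lini	focal
NKS9212	D. lini	focal
NKS9231	D. lini	focal
NK9242	D. lini	focal
MMY309	D. ohnishii	focal
MMY326	D. ohnishii	focal
MLN24	D. ohnishii	focal
MLN45	D. ohnishii	focal
RGN3	D. ogumai	focal
RGN206	D. ogumai	focal
MEL1	D. melanogaster	outgroup
SIM1	D. simulans	outgroup
MAU1	D. mauritiana	outgroup
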