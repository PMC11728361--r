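feature,top_r1,top_r2,bottom_r1,bottom_r2,k
echointensity,10,10,0,0,10
variance,8,10,7,8,10
sd,9,10,7,7,10
echovariation,0,0,10,10,10
skew,2,3,10,10,10
kurtosis,0,0,10,10,10
correlation,8,8,4,3,10
dissimilarity,1,1,5,5,10
contrast,3,4,5,5,10
homogeneity,2,2,5,5,10
asm,3,4,7,9,10
energy,0,0,5,7,10
max_probability,0,0,7,8,10
entropy,7,7,8,8,10
cluster_shade,8,10,2,2,10
cluster_prominence,7,10,1,1,10
sre,8,9,7,8,10
lre,3,3,7,9,10
glu,8,8,10,10,10
rlu,10,10,10,10,10
rpc,10,10,9,9,10
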