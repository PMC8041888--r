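size_class,n_patches
<=1 ha,454846
1-5 ha,177909
5-10 ha,29928
10-100 ha,29154
100-1000 ha,1904
1000-10000 ha,119
10000-100000 ha,8
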