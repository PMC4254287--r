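ecosystem,season,n_clusters
TME,wet,858
TME,dry,438
SNE,wet,2324
SNE,dry,1783
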