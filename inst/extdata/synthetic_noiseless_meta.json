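{"rate":600,"start":0,"stop":0.25,"n_samples":150,"channels":["c1","c2","c3","c4"],"conditions":["early","late"],"covariates":[0,1]}
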