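{"theta":{"a_f[rTPJ->lFEF]":0,"a_f[rTPJ->rFEF]":0,"a_f[lIPS->lFEF]":0,"a_f[rIPS->rFEF]":0,"a_b[lFEF->rTPJ]":0,"a_b[rFEF->rTPJ]":0,"a_b[lFEF->lIPS]":0,"a_b[rFEF->rIPS]":0,"b1":0,"b2":0.1,"b3":-0.4,"b4":-0.4,"g_self":0,"g_exc":0,"g_inh":0,"c[rTPJ]":0,"c[lIPS]":0,"c[rIPS]":0,"kappa_ss":0,"kappa_sp":0,"kappa_ii":0,"kappa_dp":0,"log_amp":0,"lead[c1,lFEF]":1,"lead[c2,lFEF]":0.3,"lead[c3,lFEF]":0.5,"lead[c4,lFEF]":0.1,"lead[c1,rFEF]":0.3,"lead[c2,rFEF]":1,"lead[c3,rFEF]":0.1,"lead[c4,rFEF]":0.5,"lead[c1,lIPS]":0.5,"lead[c2,lIPS]":0.1,"lead[c3,lIPS]":0.8,"lead[c4,lIPS]":0.2,"lead[c1,rIPS]":0.1,"lead[c2,rIPS]":0.5,"lead[c3,rIPS]":0.2,"lead[c4,rIPS]":0.8,"lead[c1,rTPJ]":0.4,"lead[c2,rTPJ]":0.4,"lead[c3,rTPJ]":-0.6,"lead[c4,rTPJ]":-0.6},"input_amplitude":5,"input_onset":0.06,"input_dispersion":0.016,"firing_gain":50,"snr_db":10,"seed":12,"noise_sd":5.48162889612923e-05,"channel_cor":0,"design":{"condition":["early","late"],"covariate":[0,1]}}
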