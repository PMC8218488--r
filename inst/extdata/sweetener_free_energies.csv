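name,log_rs,ddF,ddF_err
Sucrose,0,-6.9,0.7
4R-Cl-sucrose,0.70,-10.2,0.8
Sucralose,2.78,-11.7,0.8
Dulcin,2.40,-10.6,0.4
Isovanillyl,2.60,-11.1,0.8
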