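wavelength_nm,mua_per_vf_percent
400,6.40
440,6.00
460,5.80
480,5.65
503,5.50
527,5.30
560,5.10
600,4.92
630,4.80
658,4.62
675,4.50
700,4.38
750,4.15
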