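model,emotion,epc,epoa,epfa,pct_common,pct_original_alone,pct_fake_alone
dynamic,Sadness,6047,15099,11827,28.60,71.40,55.93
dynamic,Fear,46,295,171,13.49,86.51,50.15
dynamic,Happiness,190312,94701,61022,66.77,33.23,21.41
dynamic,Anger,431,3029,2808,12.46,87.54,81.16
dynamic,Surprise,13378,14196,12078,48.52,51.48,43.80
dynamic,Disgust,13106,12685,12583,50.82,49.18,48.79
dynamic,Neutral,36971,61327,64760,37.61,62.39,65.88
static,Sadness,242246,166103,150972,59.32,40.68,36.97
static,Fear,349,2513,2232,12.19,87.81,77.99
static,Happiness,190312,94701,61022,66.77,33.23,21.41
static,Anger,431,3029,2808,12.46,87.54,81.16
static,Surprise,77445,87270,64647,47.02,52.98,39.25
static,Disgust,181323,163951,115179,52.52,47.48,33.36
static,Neutral,197,1973,2031,9.08,90.92,93.59
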