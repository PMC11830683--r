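trait,average,maximum,minimum,sd,z_max,z_min
External rectangular length,60.1,69.24,52.86,4.65,1.98,-1.55
External rectangular width,60.02,66.86,53.57,3.89,1.76,-1.66
Roundness,0.81,0.9,0.57,0.069,1.34,-3.38
Area,208.32,244.58,182.93,16.54,2.19,-1.54
Perimeter,2782.4,3351.2,2215.15,343.02,1.66,-1.65
Long axis,39.75,43.15,32.17,3.51,0.97,-2.16
Short axis,34.38,40.38,24.83,4.2,1.43,-2.27
Red mean,103.42,161.97,51.16,27.48,2.13,-1.90
Green mean,68.64,113.6,30.161,22.40,2.01,-1.72
Blue mean,41.91,74.33,19.13,15.37,2.11,-1.48
Greyscale mean,70.99,114.18,33.15,21.52,2.01,-1.76
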