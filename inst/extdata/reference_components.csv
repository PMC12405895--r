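population,trait,clone,site_clone,plot,residual,sigma2P,ratio,H2,rB,pct_clone,pct_site_clone,pct_plot,pct_residual
A-West,TH,813.8,246.1,962.6,4317.4,6339.8,0.30,0.13,0.77,12.8,3.9,15.2,68.1
A-West,DBH,33.6,2.8,27.0,166.7,230.1,0.08,0.15,0.92,14.6,1.2,11.8,72.4
A-West,Dpil,1.3824,0,NA,2.1848,3.5672,0,0.39,1,38.8,0,NA,61.2
A-West,Vdir,0.0415,0.0191,NA,0.0456,0.1063,0.46,0.39,0.69,39.1,18.0,NA,42.9
A-West,MoE,0.5184,0.2181,NA,0.5477,1.2843,0.42,0.40,0.70,40.4,17.0,NA,42.6
A-East,TH,950.5,837.8,1481.1,5078.4,8347.9,0.88,0.11,0.53,11.4,10.0,17.7,60.8
A-East,DBH,42.5,15.2,48.3,240.7,346.6,0.36,0.12,0.74,12.3,4.4,13.9,69.4
A-East,Dpil,2.2433,0.1215,NA,3.4697,5.8346,0.05,0.38,0.95,38.4,2.1,NA,59.5
A-East,Vdir,0.0423,0.0046,NA,0.0307,0.0776,0.11,0.54,0.90,54.5,5.9,NA,39.6
A-East,MoE,0.5330,0.0709,NA,0.4900,1.0939,0.13,0.49,0.88,48.7,6.5,NA,44.8
C,TH,1159.3,176.5,1232.7,3439.9,6008.4,0.15,0.19,0.87,19.3,2.9,20.5,57.3
C,DBH,23.0,0.6,41.8,103.2,168.6,0.03,0.14,0.97,13.6,0.4,24.8,61.2
C,Dpil,1.4628,0.1069,NA,1.5632,3.1328,0.07,0.47,0.93,46.7,3.4,NA,49.9
C,Vdir,0.0637,0.0019,NA,0.0336,0.0991,0.03,0.64,0.97,64.3,1.9,NA,33.9
C,MoE,1.5326,0,NA,0.9269,2.4595,0,0.62,1,62.3,0,NA,37.7
D,TH,1118.7,0,NA,3025.7,4144.3,0,0.27,1,27.0,0,NA,73.0
D,DBH,78.2,0,NA,181.3,259.5,0,0.30,1,30.1,0,NA,69.9
D,Dpil,1.1463,0,NA,2.7826,3.9289,0,0.29,1,29.2,0,NA,70.8
D,Vdir,0.0798,0.000003,NA,0.0347,0.1145,<0.01,0.70,0.99,69.7,<0.1,NA,30.3
D,MoE,1.1763,0.0948,NA,0.8021,2.0733,0.08,0.57,0.93,56.7,4.6,NA,38.7
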