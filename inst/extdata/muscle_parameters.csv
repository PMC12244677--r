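muscle,abbrev,max_force_N,gto_gain_printed_1e3_MVC_per_N,afferent_ms,efferent_ms
Anterior Deltoid,Delt Ant,1218.9,1.04,4.55,4.37
Posterior Deltoid,Delt Post,1103.5,1.15,4.55,4.37
Lateral Deltoid,Delt Lat,201.6,6.30,4.55,4.37
Pectoralis Major,Pec,658.3,1.93,4.57,8.05
Biceps,Bi,841.9,1.51,6.43,11.94
Triceps,Tri,1489.3,0.85,6.75,11.87
Brachialis,Bra,1177.4,1.08,6.20,11.13
Brachioradialis,Brd,276,4.60,6.09,13.63
Pronator Teres,PT,557.2,2.28,4.65,14.91
Extensor Carpi Radialis,ECR,407.9,2.15,8.89,16.98
Extensor Carpi Ulnaris,ECU,479.8,6.58,9.41,16.93
Flexor Carpi Radialis,FCR,589.8,3.11,9.25,14.95
Flexor Carpi Ulnaris,FCU,192.9,2.65,14.23,18.79
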