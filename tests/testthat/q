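"muscle","gain_1e3_MVC_per_N"
"Delt Ant",1.04192304536878
"Delt Lat",6.29960317460317
"Delt Post",1.15088355233348
"Pec",1.92921160565092
"Bi",1.50849269509443
"Tri",0.852749613912576
"Bra",1.07864786818413
"Brd",4.60144927536232
"PT",2.27925340990668
"ECR",3.11350821279725
"ECU",2.64693622342643
"FCR",2.15327229569346
"FCU",6.58372213582167
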