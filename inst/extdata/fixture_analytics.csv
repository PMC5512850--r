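"label","rho_eff_P","rho_eff_A","eta_crit_P","eta_crit_A","eta_max_P","eta_max_A"
"A",0.0484444309410661,0.0489035607364818,0.710587514606399,0.7085441247792,0.0829643969418323,0.14669521244534
"B",0.0498483853871309,0.0503987133225547,0.704369750994567,0.701957132631813,0.0898886979916551,0.139714734757817
"C",0.23024097661735,0.232675193067257,0.294736341538885,0.291899842105443,0.0387838662504733,0.0583990614852343
"D",0.229451738394731,0.231977619157062,0.295663973194335,0.292708932298559,0.0389779745067641,0.0580240455001624
"E",0.0498730644869473,0.0504218151530258,0.704261263605026,0.701856155493004,0.0898503712927368,0.139664676059983
"F",0.229417648204168,0.231941997000242,0.295704129736683,0.292750329947018,0.0389985214606565,0.0580248578968533
"G",0.0498730636080062,0.0504218129033913,0.704261267468287,0.701856165324887,0.0898503627787941,0.139664689366165
"H",0.229417667643795,0.23194200628512,0.295704106835677,0.29275031915574,0.0389985219822453,0.0580248579604752
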