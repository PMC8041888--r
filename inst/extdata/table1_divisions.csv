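division,tof_ha,ci95_ha,division_area_ha
Barisal,303220,25123,1329700
Chittagong,399331,37392,3377100
Dhaka,415544,29102,2059300
Khulna,293262,37441,2227200
Mymensingh,178410,15544,1058400
Rajshahi,267266,36763,1819700
Rangpur,233180,28632,1631700
Sylhet,143365,19365,1259600
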