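division,tof_ha,tof_gt5m_ha,cover_extent_ha,fnf_ha
Barisal,303220,213075,158773,331797
Chittagong,399331,277181,224110,463168
Dhaka,415544,265083,128682,327624
Khulna,293262,194372,149802,419290
Mymensingh,178410,143529,73514,202110
Rajshahi,267266,183087,51583,246310
Rangpur,233180,134708,61654,362804
Sylhet,143365,66532,104426,113985
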