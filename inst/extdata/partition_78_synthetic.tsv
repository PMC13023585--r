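region_label	network_label
LH_SMN_01	SMN
LH_SMN_02	SMN
LH_SMN_03	SMN
LH_SMN_04	SMN
LH_SMN_05	SMN
LH_SMN_06	SMN
LH_SMN_07	SMN
RH_SMN_01	SMN
RH_SMN_02	SMN
RH_SMN_03	SMN
RH_SMN_04	SMN
RH_SMN_05	SMN
RH_SMN_06	SMN
RH_SMN_07	SMN
LH_DAN_01	DAN
LH_DAN_02	DAN
LH_DAN_03	DAN
LH_DAN_04	DAN
LH_DAN_05	DAN
LH_DAN_06	DAN
LH_DAN_07	DAN
RH_DAN_01	DAN
RH_DAN_02	DAN
RH_DAN_03	DAN
RH_DAN_04	DAN
RH_DAN_05	DAN
RH_DAN_06	DAN
RH_DAN_07	DAN
LH_SN_01	SN
LH_SN_02	SN
LH_SN_03	SN
LH_SN_04	SN
LH_SN_05	SN
LH_SN_06	SN
RH_SN_01	SN
RH_SN_02	SN
RH_SN_03	SN
RH_SN_04	SN
RH_SN_05	SN
RH_SN_06	SN
LH_CEN_01	CEN
LH_CEN_02	CEN
LH_CEN_03	CEN
LH_CEN_04	CEN
LH_CEN_05	CEN
LH_CEN_06	CEN
LH_CEN_07	CEN
LH_CEN_08	CEN
RH_CEN_01	CEN
RH_CEN_02	CEN
RH_CEN_03	CEN
RH_CEN_04	CEN
RH_CEN_05	CEN
RH_CEN_06	CEN
RH_CEN_07	CEN
RH_CEN_08	CEN
LH_DMN_01	DMN
LH_DMN_02	DMN
LH_DMN_03	DMN
LH_DMN_04	DMN
LH_DMN_05	DMN
LH_DMN_06	DMN
LH_DMN_07	DMN
LH_DMN_08	DMN
LH_DMN_09	DMN
LH_DMN_10	DMN
LH_DMN_11	DMN
RH_DMN_01	DMN
RH_DMN_02	DMN
RH_DMN_03	DMN
RH_DMN_04	DMN
RH_DMN_05	DMN
RH_DMN_06	DMN
RH_DMN_07	DMN
RH_DMN_08	DMN
RH_DMN_09	DMN
RH_DMN_10	DMN
RH_DMN_11	DMN
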