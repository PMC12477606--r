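hAGO_consensus	eAgo
hAGO2	eAgo
hAGO2	AGO
hAGO2	mAGO
hAGO2	vAGO
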