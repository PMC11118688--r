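immune_exhaustion	.	CD274	CTLA4	HAVCR2	LAG3	TIGIT
complement_panel	.	C3	C1S	C1R	C4B	C7
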