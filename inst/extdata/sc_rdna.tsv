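name	start_bp	end_bp
chr12	451000	468900
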