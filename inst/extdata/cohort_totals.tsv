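quantity	n
screened	503935
after_exclusions	500539
reference	414869
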