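reference	target
197	189
225	217
268	260
284	276
376	372
434	430
574	570
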