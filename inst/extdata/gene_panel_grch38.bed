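chr10	87863112	87971930	PTEN
chr11	76444024	76553037	EMSY
chr19	29811897	29824312	CCNE1
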