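snp_id	reason
rs2068834	genome-wide significant association with obesity
rs429358	genome-wide significant association with obesity
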