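set_name	gene
t_cell_exhaustion	TIGIT
t_cell_exhaustion	CTLA4
t_cell_exhaustion	PDCD1
t_cell_exhaustion	HAVCR2
t_cell_exhaustion	LAG3
t_cell_exhaustion	LAYN
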