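name,platform,n_reads,n_cycles,list_price_eur
NovaSeq X 25B,NovaSeq X Plus,52e9,300,16480
NovaSeq X 10B,NovaSeq X Plus,20e9,300,12200
NovaSeq 6000 S4,NovaSeq 6000,20e9,300,16365
NovaSeq 6000 S2,NovaSeq 6000,8.2e9,300,10650
NextSeq 550 High Output,NextSeq 550,400e6,300,4175
NextSeq 550 Mid Output,NextSeq 550,130e6,300,1310
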