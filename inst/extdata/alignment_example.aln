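CLUSTAL W multiple sequence alignment

seqA            MKVCDHFRMYDFKVRRCARG
seqB            MKVCDHFRMYDFKV--CARG
seqC            MKVCEHFRMYDFKVRRCARG

seqA            RSHDWTECPYAH
seqB            RSHDWTECPYAH
seqC            RSHDWTECPYAH
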