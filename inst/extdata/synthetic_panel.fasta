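>SYN1 synthetic marker-like protein (not a UniProt sequence)
MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVANPDGDFRSTMQELNSRENAGEDPGLAR
GAVHDVKWEAEPVYVQRAKPLVSTQLLGGK
>SYN2 synthetic background-like protein (not a UniProt sequence)
MSLSERQGVDADINGLRTLLEGEESRLALDLEIATYRFSSSGGGGGGGRSISISVARKGF
PNRAEFQEEAKR
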