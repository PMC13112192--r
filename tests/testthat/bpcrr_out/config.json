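{"burnin":1000,"fixed":"","genotypes":"/nonexistent.csv","h2":0.3,"help":false,"id_col":"id","iter":4000,"k":"auto","out":"bpcrr_out","phenotypes":"/nonexistent2.csv","prior":"default","random":"","seed":1,"sigma_g2":"NA","trait":"y"}
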