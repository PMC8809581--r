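id,species,site
B001,CACH,synthetic
B002,CACH,synthetic
B003,TUTI,synthetic
B004,TUTI,synthetic
B005,CACH,synthetic
B006,TUTI,synthetic
B007,TUTI,synthetic
B008,TUTI,synthetic
B009,CACH,synthetic
B010,CACH,synthetic
B011,CACH,synthetic
B012,CACH,synthetic
B013,CACH,synthetic
B014,TUTI,synthetic
B015,CACH,synthetic
B016,CACH,synthetic
B017,TUTI,synthetic
B018,CACH,synthetic
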