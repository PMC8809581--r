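id,species,planted_community,secondary_community
B001,CACH,1,NA
B002,CACH,1,2
B003,TUTI,2,NA
B004,TUTI,1,NA
B005,CACH,1,2
B006,TUTI,3,NA
B007,TUTI,2,NA
B008,TUTI,3,NA
B009,CACH,1,NA
B010,CACH,3,NA
B011,CACH,1,2
B012,CACH,2,3
B013,CACH,3,NA
B014,TUTI,3,2
B015,CACH,2,1
B016,CACH,2,NA
B017,TUTI,3,NA
B018,CACH,2,NA
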