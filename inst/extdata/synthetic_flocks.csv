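flock_id,individual_id,site,date
F0001,B015,synthetic,NA
F0001,B018,synthetic,NA
F0001,B016,synthetic,NA
F0002,B012,synthetic,NA
F0002,B018,synthetic,NA
F0003,B009,synthetic,NA
F0003,B002,synthetic,NA
F0003,B011,synthetic,NA
F0003,B001,synthetic,NA
F0003,B004,synthetic,NA
F0003,B005,synthetic,NA
F0003,B015,synthetic,NA
F0004,B016,synthetic,NA
F0004,B007,synthetic,NA
F0005,B012,synthetic,NA
F0005,B016,synthetic,NA
F0005,B018,synthetic,NA
F0006,B007,synthetic,NA
F0006,B012,synthetic,NA
F0007,B007,synthetic,NA
F0007,B018,synthetic,NA
F0008,B011,synthetic,NA
F0008,B005,synthetic,NA
F0008,B009,synthetic,NA
F0008,B001,synthetic,NA
F0009,B014,synthetic,NA
F0009,B008,synthetic,NA
F0010,B001,synthetic,NA
F0010,B011,synthetic,NA
F0011,B005,synthetic,NA
F0011,B011,synthetic,NA
F0011,B001,synthetic,NA
F0011,B004,synthetic,NA
F0012,B016,synthetic,NA
F0012,B015,synthetic,NA
F0013,B002,synthetic,NA
F0013,B011,synthetic,NA
F0013,B005,synthetic,NA
F0013,B001,synthetic,NA
F0013,B009,synthetic,NA
F0014,B008,synthetic,NA
F0014,B010,synthetic,NA
F0014,B014,synthetic,NA
F0014,B017,synthetic,NA
F0014,B006,synthetic,NA
F0014,B013,synthetic,NA
F0015,B004,synthetic,NA
F0015,B001,synthetic,NA
F0015,B005,synthetic,NA
F0015,B009,synthetic,NA
F0016,B008,synthetic,NA
F0016,B013,synthetic,NA
F0016,B010,synthetic,NA
F0016,B006,synthetic,NA
F0016,B014,synthetic,NA
F0016,B017,synthetic,NA
F0016,B012,synthetic,NA
F0017,B001,synthetic,NA
F0017,B009,synthetic,NA
F0017,B005,synthetic,NA
F0018,B001,synthetic,NA
F0018,B005,synthetic,NA
F0018,B002,synthetic,NA
F0019,B009,synthetic,NA
F0019,B002,synthetic,NA
F0019,B004,synthetic,NA
F0019,B015,synthetic,NA
F0019,B001,synthetic,NA
F0020,B011,synthetic,NA
F0020,B009,synthetic,NA
F0020,B005,synthetic,NA
F0021,B016,synthetic,NA
F0021,B003,synthetic,NA
F0021,B007,synthetic,NA
F0021,B018,synthetic,NA
F0021,B015,synthetic,NA
F0022,B001,synthetic,NA
F0022,B015,synthetic,NA
F0022,B005,synthetic,NA
F0022,B004,synthetic,NA
F0023,B007,synthetic,NA
F0023,B015,synthetic,NA
F0023,B016,synthetic,NA
F0023,B002,synthetic,NA
F0024,B015,synthetic,NA
F0024,B005,synthetic,NA
F0024,B016,synthetic,NA
F0025,B016,synthetic,NA
F0025,B007,synthetic,NA
F0025,B014,synthetic,NA
F0026,B015,synthetic,NA
F0026,B018,synthetic,NA
F0027,B001,synthetic,NA
F0027,B002,synthetic,NA
F0027,B011,synthetic,NA
F0027,B004,synthetic,NA
F0027,B005,synthetic,NA
F0028,B014,synthetic,NA
F0028,B010,synthetic,NA
F0028,B013,synthetic,NA
F0028,B008,synthetic,NA
F0029,B017,synthetic,NA
F0029,B006,synthetic,NA
F0030,B015,synthetic,NA
F0030,B018,synthetic,NA
F0030,B016,synthetic,NA
F0031,B011,synthetic,NA
F0031,B002,synthetic,NA
F0031,B009,synthetic,NA
F0031,B005,synthetic,NA
F0031,B004,synthetic,NA
F0031,B001,synthetic,NA
F0031,B015,synthetic,NA
F0032,B013,synthetic,NA
F0032,B017,synthetic,NA
F0032,B014,synthetic,NA
F0032,B008,synthetic,NA
F0032,B012,synthetic,NA
F0033,B007,synthetic,NA
F0033,B016,synthetic,NA
F0033,B012,synthetic,NA
F0033,B005,synthetic,NA
F0033,B015,synthetic,NA
F0034,B015,synthetic,NA
F0034,B003,synthetic,NA
F0035,B011,synthetic,NA
F0035,B005,synthetic,NA
F0035,B004,synthetic,NA
F0036,B009,synthetic,NA
F0036,B002,synthetic,NA
F0036,B011,synthetic,NA
F0036,B001,synthetic,NA
F0036,B005,synthetic,NA
F0037,B004,synthetic,NA
F0037,B002,synthetic,NA
F0037,B011,synthetic,NA
F0038,B001,synthetic,NA
F0038,B004,synthetic,NA
F0039,B003,synthetic,NA
F0039,B007,synthetic,NA
F0039,B016,synthetic,NA
F0039,B015,synthetic,NA
F0039,B012,synthetic,NA
F0039,B011,synthetic,NA
F0040,B018,synthetic,NA
F0040,B002,synthetic,NA
F0040,B016,synthetic,NA
F0040,B007,synthetic,NA
F0041,B003,synthetic,NA
F0042,B010,synthetic,NA
F0042,B014,synthetic,NA
F0042,B013,synthetic,NA
F0042,B017,synthetic,NA
F0042,B008,synthetic,NA
F0042,B006,synthetic,NA
F0043,B012,synthetic,NA
F0043,B016,synthetic,NA
F0043,B003,synthetic,NA
F0044,B009,synthetic,NA
F0044,B005,synthetic,NA
F0044,B011,synthetic,NA
F0044,B004,synthetic,NA
F0044,B002,synthetic,NA
F0045,B009,synthetic,NA
F0046,B001,synthetic,NA
F0047,B003,synthetic,NA
F0047,B007,synthetic,NA
F0047,B014,synthetic,NA
F0047,B016,synthetic,NA
F0048,B015,synthetic,NA
F0049,B005,synthetic,NA
F0049,B011,synthetic,NA
F0049,B015,synthetic,NA
F0049,B009,synthetic,NA
F0050,B006,synthetic,NA
F0050,B010,synthetic,NA
F0051,B018,synthetic,NA
F0051,B015,synthetic,NA
F0052,B016,synthetic,NA
F0052,B018,synthetic,NA
F0053,B008,synthetic,NA
F0053,B012,synthetic,NA
F0053,B006,synthetic,NA
F0054,B015,synthetic,NA
F0054,B012,synthetic,NA
F0054,B003,synthetic,NA
F0054,B018,synthetic,NA
F0055,B009,synthetic,NA
F0055,B004,synthetic,NA
F0056,B015,synthetic,NA
F0056,B003,synthetic,NA
F0056,B007,synthetic,NA
F0056,B012,synthetic,NA
F0057,B001,synthetic,NA
F0057,B002,synthetic,NA
F0058,B013,synthetic,NA
F0058,B006,synthetic,NA
F0059,B017,synthetic,NA
F0059,B010,synthetic,NA
F0059,B006,synthetic,NA
F0059,B008,synthetic,NA
F0059,B013,synthetic,NA
F0060,B004,synthetic,NA
F0060,B011,synthetic,NA
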