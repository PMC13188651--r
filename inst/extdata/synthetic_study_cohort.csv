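participant_id,time_minutes,eti_prior_year,dlt_prior_year,completed
S001,1.9298999999999999,30,5,TRUE
S002,2.5194000000000001,49,2,TRUE
S003,2.8565999999999998,32,0,TRUE
S004,2.2189999999999999,51,0,TRUE
S005,1.8083000000000000,162,0,TRUE
S006,1.7568999999999999,542,1,TRUE
S007,1.6003000000000001,25,2,TRUE
S008,1.3160000000000001,47,0,TRUE
S009,2.8376999999999999,21,0,TRUE
S010,1.8500000000000001,20,5,TRUE
S011,2.0911000000000000,83,0,TRUE
S012,1.7887999999999999,74,0,TRUE
S013,2.1993000000000000,86,0,TRUE
S014,2.2905000000000002,76,11,TRUE
S015,1.8393999999999999,388,0,TRUE
S016,2.1648999999999998,435,5,TRUE
S017,2.3778000000000001,77,2,TRUE
S018,2.9436000000000000,97,0,TRUE
S019,2.0621999999999998,175,2,TRUE
S020,1.9987999999999999,5,0,TRUE
S021,3.1286000000000000,15,11,TRUE
S022,1.7264999999999999,93,0,TRUE
S023,2.1528000000000000,82,0,TRUE
S024,1.6917000000000000,208,0,TRUE
S025,2.6061000000000001,26,0,TRUE
S026,2.8079000000000001,75,14,TRUE
S027,2.7685000000000000,37,0,TRUE
S028,2.8517000000000001,5,0,TRUE
S029,2.1793000000000000,75,20,TRUE
S030,2.1086999999999998,70,0,TRUE
S031,2.0792999999999999,239,0,TRUE
S032,2.2934999999999999,64,9,TRUE
S033,3.3513000000000002,108,4,TRUE
S034,2.2467999999999999,326,15,TRUE
S035,1.7926000000000000,95,4,TRUE
S036,2.3666999999999998,5,0,TRUE
S037,2.1373000000000002,87,9,TRUE
S038,2.7599000000000000,86,0,TRUE
S039,2.3841999999999999,33,0,TRUE
S040,2.7907999999999999,435,0,TRUE
S041,2.1858000000000000,15,0,TRUE
S042,2.4083000000000001,33,0,TRUE
S043,2.6273000000000000,113,0,TRUE
S044,1.7927000000000000,258,0,TRUE
S045,2.0981999999999998,24,32,TRUE
S046,2.1728999999999998,128,8,TRUE
S047,4.9500000000000002,4,2,TRUE
S048,4.7999999999999998,4,0,TRUE
S049,4.6500000000000004,3,6,TRUE
S050,4.5000000000000000,2,2,TRUE
S051,4.3499999999999996,1,0,TRUE
S052,4.2000000000000002,0,6,TRUE
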