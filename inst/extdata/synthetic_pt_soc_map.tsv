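pt	soc
pt_001	Psychiatric disorders
pt_002	Nervous system disorders
pt_003	General disorders and administration site conditions
pt_004	Gastrointestinal disorders
pt_005	Injury, poisoning and procedural complications
pt_006	Psychiatric disorders
pt_007	Nervous system disorders
pt_008	General disorders and administration site conditions
pt_009	Gastrointestinal disorders
pt_010	Injury, poisoning and procedural complications
pt_011	Psychiatric disorders
pt_012	Nervous system disorders
pt_013	General disorders and administration site conditions
pt_014	Gastrointestinal disorders
pt_015	Injury, poisoning and procedural complications
pt_016	Psychiatric disorders
pt_017	Nervous system disorders
pt_018	General disorders and administration site conditions
pt_019	Gastrointestinal disorders
pt_020	Injury, poisoning and procedural complications
pt_021	Psychiatric disorders
pt_022	Nervous system disorders
pt_023	General disorders and administration site conditions
pt_024	Gastrointestinal disorders
pt_025	Injury, poisoning and procedural complications
pt_026	Psychiatric disorders
pt_027	Nervous system disorders
pt_028	General disorders and administration site conditions
pt_029	Gastrointestinal disorders
pt_030	Injury, poisoning and procedural complications
pt_031	Psychiatric disorders
pt_032	Nervous system disorders
pt_033	General disorders and administration site conditions
pt_034	Gastrointestinal disorders
pt_035	Injury, poisoning and procedural complications
pt_036	Psychiatric disorders
pt_037	Nervous system disorders
pt_038	General disorders and administration site conditions
pt_039	Gastrointestinal disorders
pt_040	Injury, poisoning and procedural complications
pt_041	Psychiatric disorders
pt_042	Nervous system disorders
pt_043	General disorders and administration site conditions
pt_044	Gastrointestinal disorders
pt_045	Injury, poisoning and procedural complications
pt_046	Psychiatric disorders
pt_047	Nervous system disorders
pt_048	General disorders and administration site conditions
pt_049	Gastrointestinal disorders
pt_050	Injury, poisoning and procedural complications
pt_051	Psychiatric disorders
pt_052	Nervous system disorders
pt_053	General disorders and administration site conditions
pt_054	Gastrointestinal disorders
pt_055	Injury, poisoning and procedural complications
pt_056	Psychiatric disorders
pt_057	Nervous system disorders
pt_058	General disorders and administration site conditions
pt_059	Gastrointestinal disorders
pt_060	Injury, poisoning and procedural complications
pt_061	Psychiatric disorders
pt_062	Nervous system disorders
pt_063	General disorders and administration site conditions
pt_064	Gastrointestinal disorders
pt_065	Injury, poisoning and procedural complications
pt_066	Psychiatric disorders
pt_067	Nervous system disorders
pt_068	General disorders and administration site conditions
pt_069	Gastrointestinal disorders
pt_070	Injury, poisoning and procedural complications
pt_071	Psychiatric disorders
pt_072	Nervous system disorders
pt_073	General disorders and administration site conditions
pt_074	Gastrointestinal disorders
pt_075	Injury, poisoning and procedural complications
pt_076	Psychiatric disorders
pt_077	Nervous system disorders
pt_078	General disorders and administration site conditions
pt_079	Gastrointestinal disorders
pt_080	Injury, poisoning and procedural complications
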