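sample_id	group	subject	timepoint	housing
s001	+/+	s001	0	sh
s002	+/+	s002	0	sh
s003	+/+	s003	0	sh
s004	+/+	s004	0	sh
s005	+/+	s005	0	sh
s006	+/+	s006	0	sh
s007	+/+	s007	0	sh
s008	+/+	s008	0	sh
s009	+/+	s009	0	sh
s010	+/+	s010	0	sh
s011	+/R258W	s011	0	sh
s012	+/R258W	s012	0	sh
s013	+/R258W	s013	0	sh
s014	+/R258W	s014	0	sh
s015	+/R258W	s015	0	sh
s016	+/R258W	s016	0	sh
s017	+/R258W	s017	0	sh
s018	+/R258W	s018	0	sh
s019	+/R258W	s019	0	sh
s020	+/R258W	s020	0	sh
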