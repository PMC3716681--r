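id	breed	group	sex	coverage	mcr_count	mcr_mb
AsWB01	Japanese WB	AsianWild	M	11	3764	48.9
AsWB02	N. Chinese WB	AsianWild	F	10	3832	49.75
AsWB03	S. Chinese WB	AsianWild	M	10.1	3953	51.23
AsD01	Meishan	AsianDomestic	F	9	3926	50.89
AsD02	Meishan	AsianDomestic	M	9.1	3854	49.89
AsD03	Xiang	AsianDomestic	F	8.1	3858	49.74
AsD04	Xiang	AsianDomestic	M	8	3861	50.19
AsD05	Jianquhai	AsianDomestic	F	10.5	3750	47.99
EuWB01	Dutch WB	EuropeanWild	M	9	3768	48.79
EuWB02	Dutch WB	EuropeanWild	F	8	3816	49.2
EuWB03	Italian WB	EuropeanWild	M	10	3984	51.47
EuD01	Large white	EuropeanDomestic	F	8	3909	50.59
EuD02	Large white	EuropeanDomestic	M	8	3929	50.9
EuD03	Landrace	EuropeanDomestic	F	8	3800	48.85
EuD04	Duroc	EuropeanDomestic	M	7.1	3814	49.54
EuD05	Pietrain	EuropeanDomestic	F	11	3943	51.14
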