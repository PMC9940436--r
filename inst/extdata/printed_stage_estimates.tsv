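stage	description	scale	estimate	ciLow	ciHigh
theta1	direct effect of NAFLD on PCOS (MVMR, obesity SNPs excluded)	or	1.11	1.05	1.17
theta2	direct effect of fasting insulin on PCOS (MVMR)	or	3.11	1.68	5.76
theta3	direct effect of bioavailable testosterone on PCOS (MVMR)	or	1.90	1.27	2.85
theta4	direct effect of SHBG on bioavailable testosterone (MVMR)	beta	-0.929	-0.969	-0.888
theta5	direct effect of fasting insulin on SHBG (MVMR)	beta	-0.280	-0.424	-0.135
theta6	effect of NAFLD on fasting insulin (IVW, obesity SNP excluded)	beta	0.0152	0.0087	0.0216
total	total effect of NAFLD on PCOS (IVW, all instruments)	or	1.10	1.02	1.18
total_filtered	total effect of NAFLD on PCOS (IVW, obesity SNP excluded)	or	1.12	1.02	1.24
total_replication	total effect of NAFLD on PCOS (replication, obesity SNP excluded)	or	1.08	1.01	1.15
null_fg	direct effect of fasting glucose on PCOS (MVMR)	or	0.89	0.61	1.31
null_shbg	direct effect of SHBG on PCOS (MVMR)	or	1.21	0.72	2.04
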