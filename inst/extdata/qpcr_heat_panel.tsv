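# Reference qPCR fold-change panel: 18 differentially expressed wheat
# AP2/ERF genes measured in contrasting (heat-tolerant vs heat-susceptible)
# genotypes after 3 days of heat stress, normalised to beta-actin and the
# 25 C control (2^-ddCt).  fc_* are mean linear fold changes, log2fc_* mean
# per-replicate log2 ratios.  trait and published_group are the published calls
# used to validate the package's categorisation rules.
gene	family	fc_tolerant	fc_susceptible	log2fc_tolerant	log2fc_susceptible	trait	published_group
TraesCS4D02G298600	TaERF	6.29	0.51	2.62	-1.20	highly heat-tolerant	1
TraesCS5D02G317100	TaDREB	5.94	0.74	1.84	-0.52	moderately highly heat-tolerant	1
TraesCS1A02G221900	TaDREB	2.11	0.58	1.08	-0.78	moderately highly heat-tolerant	1
TraesCS2D02G515900	TaDREB	4.03	1.21	1.86	0.15	heat-tolerant	2
TraesCS5A02G468800	TaERF	3.81	1.23	1.41	0.27	heat-tolerant	2
TraesCS6B02G375400	TaERF	4.34	1.27	1.34	0.18	heat-tolerant	2
TraesCS1A02G058400	TaAP2	1.05	0.22	0.07	-2.42	heat-tolerant	1
TraesCS5B02G214400	TaERF	1.09	0.42	-0.25	-1.29	heat-tolerant	4
TraesCS4B02G268100	TaDREB	0.65	4.60	-1.02	2.20	highly heat-susceptible	3
TraesCS5B02G193200	TaDREB	0.44	3.33	-2.08	1.71	highly heat-susceptible	3
TraesCS3B02G293000	TaRAV	0.50	2.18	-1.02	0.94	moderately highly heat-susceptible	3
TraesCS5A02G215900	TaERF	0.52	5.44	-1.79	0.74	moderately highly heat-susceptible	3
TraesCS6B02G331000	TaDREB	1.69	6.72	0.04	2.74	heat-susceptible	2
TraesCS1B02G235100	TaDREB	1.83	2.36	0.86	1.23	heat-susceptible	2
TraesCS2B02G448100	TaERF	1.61	2.86	0.26	1.01	heat-susceptible	2
TraesCS2D02G425700	TaERF	3.93	2.51	1.91	1.20	neutral	2
TraesCS2D02G515800	TaAP2	9.98	3.17	1.79	1.56	neutral	2
TraesCS4B02G299600	TaERF	0.54	0.41	-1.15	-1.45	neutral	4
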