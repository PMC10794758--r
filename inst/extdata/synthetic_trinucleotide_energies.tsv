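kmer	solvation	stacking	hbond
AAA	5.067	-7.427	-15.344
AAC	6.893	-9.385	-18.313
AAG	6.62	-8.393	-17.772
AAT	4.75	-6.936	-15.613
ACA	6.609	-9.709	-18.055
ACC	8.39	-10.311	-21.024
ACG	8.749	-10.37	-20.465
ACT	6.733	-7.791	-18.743
AGA	6.888	-8.764	-18.465
AGC	9.016	-10.323	-20.714
AGG	9.413	-10.476	-20.579
AGT	6.869	-8.719	-17.825
ATA	5.012	-7.268	-16.216
ATC	6.837	-8.817	-17.869
ATG	6.467	-8.376	-18.232
ATT	4.982	-6.473	-16.303
CAA	6.708	-9.274	-17.632
CAC	8.183	-10.312	-20.756
CAG	8.833	-11.198	-21.477
CAT	6.403	-8.255	-17.884
CCA	9.005	-10.555	-21.008
CCC	10.571	-12.249	-22.932
CCG	10.391	-11.726	-24.081
CCT	8.354	-10.172	-21.138
CGA	8.724	-10.115	-20.858
CGC	10.162	-12.84	-23.948
CGG	10.007	-11.529	-23.966
CGT	8.656	-10.656	-21.113
CTA	6.53	-8.973	-18.037
CTC	8.81	-10.54	-21.125
CTG	8.308	-10.416	-21.15
CTT	6.61	-9.279	-17.977
GAA	7.039	-9.089	-18.004
GAC	8.891	-10.814	-20.543
GAG	9	-10.886	-20.924
GAT	7.226	-9.203	-18.689
GCA	8.334	-11.43	-20.481
GCC	10.545	-12.004	-23.935
GCG	10.489	-11.813	-23.326
GCT	8.042	-10.345	-21.009
GGA	8.138	-10.105	-20.794
GGC	10.523	-12.124	-23.622
GGG	10.331	-12.597	-23.734
GGT	8.605	-10.203	-21.505
GTA	7.178	-8.217	-18.271
GTC	8.223	-10.072	-21.388
GTG	8.408	-10.884	-20.564
GTT	6.93	-8.387	-17.785
TAA	4.952	-6.977	-15.465
TAC	7.029	-8.594	-17.685
TAG	6.98	-8.512	-17.941
TAT	5.166	-6.94	-15.532
TCA	6.839	-8.973	-18.443
TCC	8.664	-11.108	-21.405
TCG	8.662	-10.219	-21.504
TCT	6.893	-8.88	-18.313
TGA	6.733	-8.751	-18.608
TGC	8.525	-9.971	-20.92
TGG	8.125	-10.725	-21.149
TGT	6.715	-9.118	-17.374
TTA	4.926	-7.957	-15.679
TTC	6.956	-8.839	-17.997
TTG	6.784	-8.931	-18.771
TTT	4.726	-6.757	-15.713
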