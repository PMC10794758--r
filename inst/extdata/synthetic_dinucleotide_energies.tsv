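kmer	solvation	stacking	hbond
AA	5.887	-8.1135	-16.685875
AC	7.684625	-9.66075	-19.448
AG	7.952375	-9.658875	-19.462125
AT	5.855375	-7.7835	-17.04225
CA	7.61425	-9.96325	-19.467
CC	9.561375	-11.29675	-22.306875
CG	9.48	-11.1585	-22.407625
CT	7.535	-9.5495	-19.6865
GA	7.829875	-9.715875	-19.610625
GC	9.4545	-11.35625	-22.244375
GG	9.434125	-11.2945	-22.385375
GT	7.698	-9.532	-19.478125
TA	5.971625	-7.92975	-16.85325
TC	7.7355	-9.681	-19.7555
TG	7.508125	-9.6465	-19.596
TT	5.83	-7.9225	-16.99225
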