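name	length_bp	centromere_bp
chr1	230218	151465
chr2	813184	238207
chr3	316620	114385
chr4	1531933	449711
chr5	576874	151987
chr6	270161	148510
chr7	1090940	496920
chr8	562643	105586
chr9	439888	355629
chr10	745751	436307
chr11	666816	440129
chr12	1078177	150828
chr13	924431	268031
chr14	784333	628758
chr15	1091291	326584
chr16	948066	555957
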