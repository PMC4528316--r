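# 1.5-LOD support intervals from linkage mapping of flowering time (FT) and
# plant height (PH) in 224 intermated B73 x Mo17 recombinant inbred lines,
# grown at two planting densities (plants per hectare).
# Coordinates are 1-based physical bp.
trait	chrom	left	right	peak_pos	length_kb	density
FT	1	11100000	21850000	13450000	10750	49000
FT	1	15150000	19050000	15950000	3900	16500
FT	2	233150000	234950000	234650000	1800	16500
FT	4	216050000	225100000	223100000	9050	49000
FT	5	212950000	214450000	214150000	1500	49000
FT	8	124350000	134700000	131250000	10350	49000
FT	8	127700000	133050000	131250000	5350	16500
FT	8	143700000	144300000	144050000	600	16500
FT	9	3750000	6400000	5250000	2650	16500
FT	9	17650000	24350000	22600000	6700	49000
FT	9	18650000	24250000	20550000	5600	16500
FT	9	152250000	153550000	152750000	1300	49000
FT	10	87300000	94200000	92600000	6900	16500
FT	10	144950000	146250000	146050000	1300	16500
PH	1	202350000	207100000	206250000	4750	16500
PH	3	124500000	149550000	129050000	25050	49000
PH	4	5650000	10550000	9850000	4900	16500
PH	9	4950000	5650000	5250000	700	49000
PH	9	96000000	105050000	99050000	9050	16500
PH	9	96450000	105050000	99050000	8600	49000
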