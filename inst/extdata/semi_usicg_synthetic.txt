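# Synthetic stand-in list of 72 semi-universal single-copy marker KO identifiers.
# Emulates a curated semi-USiCG set; supply a curated list for real KEGG-annotated data.
K52001
K52002
K52003
K52004
K52005
K52006
K52007
K52008
K52009
K52010
K52011
K52012
K52013
K52014
K52015
K52016
K52017
K52018
K52019
K52020
K52021
K52022
K52023
K52024
K52025
K52026
K52027
K52028
K52029
K52030
K52031
K52032
K52033
K52034
K52035
K52036
K52037
K52038
K52039
K52040
K52041
K52042
K52043
K52044
K52045
K52046
K52047
K52048
K52049
K52050
K52051
K52052
K52053
K52054
K52055
K52056
K52057
K52058
K52059
K52060
K52061
K52062
K52063
K52064
K52065
K52066
K52067
K52068
K52069
K52070
K52071
K52072
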