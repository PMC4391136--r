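# Synthetic stand-in list of 76 universal single-copy marker KO identifiers.
# Emulates a curated USiCG set; supply a curated list for real KEGG-annotated data.
K50001
K50002
K50003
K50004
K50005
K50006
K50007
K50008
K50009
K50010
K50011
K50012
K50013
K50014
K50015
K50016
K50017
K50018
K50019
K50020
K50021
K50022
K50023
K50024
K50025
K50026
K50027
K50028
K50029
K50030
K50031
K50032
K50033
K50034
K50035
K50036
K50037
K50038
K50039
K50040
K50041
K50042
K50043
K50044
K50045
K50046
K50047
K50048
K50049
K50050
K50051
K50052
K50053
K50054
K50055
K50056
K50057
K50058
K50059
K50060
K50061
K50062
K50063
K50064
K50065
K50066
K50067
K50068
K50069
K50070
K50071
K50072
K50073
K50074
K50075
K50076
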