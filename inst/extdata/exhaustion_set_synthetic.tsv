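exhaustion	G1094
exhaustion	G1095
exhaustion	G1096
exhaustion	G1097
exhaustion	G1098
exhaustion	G1099
exhaustion	G1100
exhaustion	G1101
exhaustion	G1102
exhaustion	G1103
exhaustion	G1104
exhaustion	G1105
exhaustion	G1106
exhaustion	G1107
exhaustion	G1108
exhaustion	G1109
exhaustion	G1110
exhaustion	G1111
exhaustion	G1112
exhaustion	G1113
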