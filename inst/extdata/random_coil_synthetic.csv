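"resName","nucleus","ppm"
"ALA","CA",59.06
"ALA","CB",29.96
"ALA","C",176.06
"ALA","N",118.37
"ALA","HN",8.26
"ALA","HA",3.95
"ARG","CA",57.25
"ARG","CB",40.34
"ARG","C",176.99
"ARG","N",120.24
"ARG","HN",8.4
"ARG","HA",4.17
"ASN","CA",59.07
"ASN","CB",29.03
"ASN","C",175.44
"ASN","N",118.57
"ASN","HN",8.29
"ASN","HA",4.38
"ASP","CA",52.09
"ASP","CB",31.99
"ASP","C",176.24
"ASP","N",117.99
"ASP","HN",8.31
"ASP","HA",4.54
"CYS","CA",56.14
"CYS","CB",41.41
"CYS","C",173.56
"CYS","N",119.61
"CYS","HN",8.35
"CYS","HA",4.52
"GLN","CA",59.26
"GLN","CB",29.82
"GLN","C",178.76
"GLN","N",121.04
"GLN","HN",8.32
"GLN","HA",4.23
"GLU","CA",56.27
"GLU","CB",32.24
"GLU","C",176.03
"GLU","N",119.2
"GLU","HN",8.47
"GLU","HA",4.59
"GLY","CA",55.17
"GLY","C",173.18
"GLY","N",125.5
"GLY","HN",8.45
"GLY","HA",4.3
"HIS","CA",57.59
"HIS","CB",25.76
"HIS","C",175.45
"HIS","N",117.91
"HIS","HN",7.82
"HIS","HA",4.63
"ILE","CA",60.06
"ILE","CB",41.47
"ILE","C",177.5
"ILE","N",120.52
"ILE","HN",8.35
"ILE","HA",4.12
"LEU","CA",55.41
"LEU","CB",32
"LEU","C",178.89
"LEU","N",120.43
"LEU","HN",8.12
"LEU","HA",4.47
"LYS","CA",60.06
"LYS","CB",28.32
"LYS","C",176.1
"LYS","N",119.01
"LYS","HN",8.28
"LYS","HA",4.36
"MET","CA",58.09
"MET","CB",37.25
"MET","C",175.21
"MET","N",117.05
"MET","HN",8.19
"MET","HA",4.54
"PHE","CA",57.92
"PHE","CB",33.11
"PHE","C",174.23
"PHE","N",117.3
"PHE","HN",8.31
"PHE","HA",4.34
"PRO","CA",55.65
"PRO","CB",30.78
"PRO","C",174
"PRO","N",117.45
"PRO","HN",8.36
"PRO","HA",4.38
"SER","CA",53.12
"SER","CB",40.86
"SER","C",171.79
"SER","N",119.45
"SER","HN",7.97
"SER","HA",4.81
"THR","CA",56.34
"THR","CB",26.63
"THR","C",176.85
"THR","N",121.89
"THR","HN",8.37
"THR","HA",4.25
"TRP","CA",62.42
"TRP","CB",26.02
"TRP","C",174.59
"TRP","N",118.47
"TRP","HN",8.4
"TRP","HA",4.28
"TYR","CA",56.33
"TYR","CB",39.57
"TYR","C",176.24
"TYR","N",118.19
"TYR","HN",8.43
"TYR","HA",4.6
"VAL","CA",58.28
"VAL","CB",30.91
"VAL","C",177.49
"VAL","N",121.97
"VAL","HN",8.42
"VAL","HA",4.14
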