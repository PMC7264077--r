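"subject_id","group","f1","f2","f3","f4"
"t01","A",0.215,0.463,0.676,0.307
"t02","A",0.087,0.529,0.565,0.326
"t03","A",0.317,0.548,0.388,0.222
"t04","A",0.251,0.42,0.658,0.206
"t05","B",0.452,0.003,0.32,0.092
"t06","B",0.419,0.027,0.403,0.348
"t07","B",0.511,0.187,0.334,0.073
"t08","B",0.491,0.126,0.199,0.359
"t09","C",0.268,0.174,-0.123,0.144
"t10","C",0.355,0.232,0.132,0.196
"t11","C",0.263,0.307,-0.077,0.203
"t12","C",0.302,0.132,-0.032,0.226
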