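"subject_id","f1","f2","f3","v1","v2"
"b01",1.015,-2.517,-0.489,-2.517,-0.775
"b02",1.782,0.244,0.792,0.244,0.065
"b03",-0.308,-0.403,2.344,-0.403,-0.149
"b04",1.355,0.259,-1.558,0.259,1.178
"b05",0.239,-1.855,-1.551,-1.855,-0.123
"b06",0.538,-1.207,1.122,-1.207,0.732
"b07",-0.02,1.826,-0.194,1.826,-0.275
"b08",1.058,0.062,0.538,0.062,-0.435
"b09",-0.347,0.535,0.494,0.535,-2.166
"b10",-0.124,-0.961,-2.001,-0.961,2.131
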