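id	fstar
s1	0.55083149489739702
s2	0.1254882788688568
s3	0.12276576401137938
s4	0.067560220023249032
s5	0.058137875929780237
s6	0.059303919878825537
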