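id	s1	s2	s3	s4	s5	s6
s1	                 0	0.34436392457560372	0.33034125205325882	0.11380056727115367	0.085244459201705092	0.088534354168011212
s2	0.34436392457560372	                 0	0.32371031539402273	0.13485427371082861	0.10426555849658042	0.10753008728116011
s3	0.33034125205325882	0.32371031539402273	                 0	0.14002189228499276	0.10979566171006712	0.11979166980252749
s4	0.11380056727115367	0.13485427371082861	0.14002189228499276	                 0	0.33167225803029965	0.3210623786383397
s5	0.085244459201705092	0.10426555849658042	0.10979566171006712	0.33167225803029965	                 0	0.34313607773655103
s6	0.088534354168011212	0.10753008728116011	0.11979166980252749	0.3210623786383397	0.34313607773655103	                 0
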