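id	s1	s2	s3	s4	s5	s6
s1	                 0	0.98906345976311405	0.95528398066965181	0.33297815780158257	0.23710337106312782	0.24733009484290999
s2	0.98906345976311405	                 0	0.97352463143514933	0.41035218897716436	0.30160126823287003	0.31240347748198194
s3	0.95528398066965181	0.97352463143514933	                 0	0.42899394094775456	0.31977215646121676	0.35040932551779386
s4	0.33297815780158257	0.41035218897716436	0.42899394094775456	                 0	0.97738630063534848	0.95025484070535637
s5	0.23710337106312782	0.30160126823287003	0.31977215646121676	0.97738630063534848	                 0	0.96542225030214346
s6	0.24733009484290999	0.31240347748198194	0.35040932551779386	0.95025484070535637	0.96542225030214346	                 0
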