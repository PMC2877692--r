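id	s1	s2	s3	s4	s5	s6
s1	                 0	               0.5	 1.019803902718557	                 5	5.7201398584300369	5.6356011214421482
s2	               0.5	                 0	0.78102496759066542	               4.5	5.2201532544552744	5.1429563482495162
s3	 1.019803902718557	0.78102496759066542	                 0	4.3863424398922621	5.0911688245431419	4.8826222462934812
s4	                 5	               4.5	4.3863424398922621	                 0	0.72111025509279758	1.0770329614269007
s5	5.7201398584300369	5.2201532544552744	5.0911688245431419	0.72111025509279758	                 0	0.89442719099991586
s6	5.6356011214421482	5.1429563482495162	4.8826222462934812	1.0770329614269007	0.89442719099991586	                 0
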