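phage_pattern	lifestyle	provenance
c2	lytic	c2 group; strictly virulent prolate-headed dairy phage (Jarvis et al. 1991 lactococcal phage taxonomy)
bIL67	lytic	c2 group member; strictly virulent (Schouler et al. 1994)
936	lytic	936 group; strictly virulent small isometric-headed dairy phage (Deveau et al. 2006)
sk1	lytic	936 group member; strictly virulent (Chandry et al. 1997)
bIL170	lytic	936 group member; strictly virulent (Crutz-Le Coq et al. 2002)
phi7	lytic	936-type dairy isolate; strictly virulent
CB13	lytic	936-type dairy isolate; strictly virulent
jj50	lytic	936 group member; strictly virulent (Mahony et al. 2006)
645	lytic	936-type dairy isolate; strictly virulent
P335	temperate	P335 group contains temperate and related virulent members; group default temperate (Deveau et al. 2006)
TP901-1	temperate	P335 group temperate phage (Brondsted et al. 2001)
Tuc2009	temperate	P335 group temperate phage (Seegers et al. 2004)
bIL285	temperate	P335-like temperate prophage of L. lactis IL1403 (Chopin et al. 2001)
bIL286	temperate	P335-like temperate prophage of L. lactis IL1403 (Chopin et al. 2001)
bIL309	temperate	P335-like temperate prophage of L. lactis IL1403 (Chopin et al. 2001)
r1t	temperate	P335 group temperate phage (van Sinderen et al. 1996)
ul36	temperate	P335 group temperate phage (Labrie & Moineau 2002)
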