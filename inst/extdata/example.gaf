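!gaf-version: 2.1
UniProtKB	A0AQW4	TCP12		GO:2000032	PMID:17307924	IMP		P			protein	taxon:3702	2010/08/23	UniProt		
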