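[Term]
GO_id: GO:2000032
name: regulation of secondary shoot formation
namespace: biological_process
def: 'Any process that modulates the frequency, rate or extent of secondary shoot formation.'
synonym: 'regulation of auxiliary shoot formation' [EXACT]
synonym: 'regulation of auxillary shoot formation' [EXACT]
is_a: GO:0022603 ! regulation of anatomical structure morphogenesis
is_a: GO:0048831 ! regulation of shoot development
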